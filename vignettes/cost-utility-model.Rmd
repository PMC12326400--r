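---
title: "Methods: the Markov cost-utility model behind pdcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Markov cost-utility model behind pdcea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdcea)
```

`pdcea` compares seven device-aided strategies for advanced Parkinson's
disease — two continuous subcutaneous apomorphine infusions (Apo-Go,
Dacepton), two deep-brain-stimulation systems (Percept PC and the
rechargeable Percept RC), two intestinal gels delivered via PEG (Duodopa,
Lecigon) and subcutaneous foslevodopa-foscarbidopa — on cost per life-year
(ACE) and cost per QALY (ACU), from the Spanish National Health System
perspective in 2023 euros. This vignette records the modelling choices,
their rationale, and what the validation machinery does and does not show.

## The cohort model and its assumptions

The engine is a standard discrete-time Markov cohort model. A state space
couples a clinical description (Hoehn & Yahr stage, proportion of waking
time in OFF) to a utility weight and a per-cycle cost; a row-stochastic
transition matrix with an absorbing death state moves the cohort forward;
discounted life-years and QALYs are occupancy-weighted sums.

Assumptions inherited from this model class: transitions are memoryless
and time-homogeneous (no age-dependent mortality, no duration-of-stay
effects); the cohort is homogeneous at baseline; utilities combine
additively across the cohort. None of these is innocuous for a
progressive disease over a 20-year horizon, which is one reason the
calibrated scenarios (below) should be read as stand-ins reproducing
aggregate totals, not as clinical reconstructions.

### The 12-state default template

The source model is described only by its ingredients — twelve states
built from H&Y stage, OFF time, complications (surgery, PEG),
adverse-event discontinuation, switching and death — without an explicit
enumeration. `default_state_template()` therefore fixes one concrete
reading: pooled severity {H&Y 2–3, H&Y 4, H&Y 5} crossed with OFF stratum
{< 50%, ≥ 50% of waking hours} gives six on-treatment states; surgical
complication, PEG complication, adverse-event discontinuation, switched
and second-line therapy give five event states; plus absorbing death.
This is a configurable default (`build_state_space()` accepts any
template, including from YAML/JSON), not a claim about the original
model. Whether the original allowed re-entry from the discontinuation or
switch states is unknown; the default matrix treats event states as
persistent apart from mortality.

### Baseline distribution

Half of the cohort starts in the high-OFF stratum (> 14 h/day in OFF at
treatment start), matching the source description, and the halves are
split uniformly across the three severity strata because no baseline
severity distribution is stated. Event states and death start empty.

### Discounting and horizons

* **Discount rate** 3.5 %/year on costs and effects alike (the stated
  study convention).
* **Cycle length** 1 year by default (no cycle length is stated anywhere
  in the source; one year matches annual discounting and the 5-year cost
  horizon), configurable down to monthly; discounting uses elapsed years
  `t × cycle_length`, so sub-annual cycles discount correctly.
* **Effect accumulation** starts at cycle 1; the cycle-0 occupancy is the
  baseline and carries no elapsed time. A half-cycle correction
  (averaging adjacent occupancies) is available and off by default, since
  only the rate is stated. On a constant-alive chain the default
  convention reproduces the annuity sum exactly, which the tests exploit.
* **Horizons.** Costs run over 5 years; effects over a 20-year default
  horizon. These are deliberately different: the published life-year
  totals (6.385–8.151) exceed 5, so the effect horizon cannot be the cost
  horizon. Twenty years absorbs essentially all survival mass at the
  calibrated mortality rates.

## Calibration: reconstructing what was not printed

The source reports, per therapy, discounted life-years (6.385 for both
apomorphine infusions, 7.055 for both intestinal gels, 8.151 for
foslevodopa, 6.495 for DBS) and QALYs (2.885, 3.120, 3.605, 2.800
respectively) — printed without decimal separators and interpreted here at
the thousandth scale, since thousands of life-years are impossible and the
same tables use Spanish decimal commas elsewhere. Whether these totals are
discounted is not stated; because the study says 3.5% applies to costs
and utilities alike, calibration treats them as discounted at 3.5%.

`calibrate()` recovers a scenario from two free parameters, solved in a
nested, fully deterministic way:

1. **Mortality.** Every alive state carries the same per-cycle death
   probability, so survival is exactly `(1 − p)^t` and discounted
   life-years are strictly decreasing in `p`. One-dimensional
   root-finding (`stats::uniroot`, tolerance 1e-12, bracket [0, 0.999])
   matches the life-year target. Structural nuisance parameters
   (progression 0.10/cycle along the severity chain, total event-state
   entry 0.02/cycle) are held fixed; they shape occupancy, not survival.
2. **Utilities.** QALYs are linear in the utility map, so the template's
   utility profile is rescaled by a single factor to hit the QALY target
   exactly, subject to all utilities staying ≤ 1. Infeasible targets
   (QALYs exceeding life-years, life-years exceeding the zero-mortality
   annuity, or a required scale pushing utilities past 1) raise errors
   naming the binding bound.

Because the mapping is monotone in each stage, no seed is involved and
calibration is exactly reproducible. Parameter-recovery tests (simulate
effects from a known mortality, calibrate on them) recover the hazard
within 2% across 20 random draws — this, not clinical fidelity, is the
property the calibration layer guarantees.

## Costing conventions

* Pathway totals are `Σ count × unit cost` over the 5-year pathway,
  rounded to cents; annual drug costs are `PVL unit cost × standard
  units/day × 365`, rounded to whole euros — each matching the printed
  precision of its source table. The packaged CSVs transcribe the
  tables verbatim, Spanish number formatting included; `parse_money()`
  handles the locale.
* Recurring drug costs are discounted as an annuity due (payments at the
  start of each year) because treatment starts immediately; pathway costs
  fall at t = 0 by default, with an optional `pathway_followup` portion
  spread uniformly over the horizon, since the source defines a
  pre-treatment/procedure/follow-up split without dates.
* The source's printed *average annual* costs (e.g. 13,421 € for Apo-Go)
  are not derivable from the stated 5-year/3.5% inputs under any single
  timing convention we tried; `pdcea` computes and documents its own
  `average_annual_cost` (discounted total / horizon) and never hard-codes
  the printed averages. Under the package's conventions Apo-Go comes to
  13,809 €/year and Dacepton to 10,398 €/year — close to, but not
  identical with, the printed figures.

## CEA conventions and tie rules

* **Cost basis.** The printed ratio table is reconciled with the effect
  totals through *implied totals* `ACU × QALYs` (e.g. Dacepton
  20,782 × 2.885 = 59,956 €). The printed ACE and ACU columns are
  mutually inconsistent at the 0.03–0.1% level (rounding in the source),
  so ratio cross-checks use a 0.5% relative tolerance; ACU values
  themselves are reproduced exactly by construction. A `computed` basis
  (totals rebuilt from the cost tables) is available in the pipeline.
* **Reference strategy**: the lowest-ACU therapy (Dacepton), matching the
  source's anchoring; configurable.
* **Dominance.** An equal-effect, higher-cost option counts as strictly
  dominated (this is how Apo-Go falls to Dacepton). Anchored on the
  reference, the dominated set is {Apo-Go, Percept PC, Percept RC} — the
  published statement. The full pairwise comparison is stronger: on the
  implied totals Foslevodopa (217,450 €, 3.605 QALYs) strictly dominates
  both Duodopa (218,116 €, 3.120) and Lecigon (324,480 €, 3.120), a
  consequence of the source's own numbers that its reference-anchored
  analysis does not surface. `dominance_classify()` reports the pairwise
  labels; `dominated_by_reference()` reproduces the anchored statement.
* **Extended dominance** is removed iteratively on the effect-sorted
  non-dominated set; exactly collinear points are kept (ties break toward
  retention), and identical cost/effect pairs dominate nothing and warn.
  The resulting frontier is checked against an exhaustive segment oracle.
* **Willingness to pay.** Band edges 22,000 / 25,000 / 60,000 €/QALY;
  values on an edge classify into the lower category. Note the source
  prose says only Lecigon exceeded the thresholds, but by its own ACU
  column Duodopa (69,909) and Foslevodopa (60,319) also exceed the
  60,000 ceiling; the classifier follows the numbers.

## What the synthetic scenarios do and do not emulate

`generate_scenario()` draws random dead-absorbing chains (random
utilities, Dirichlet-style rows, scalable mortality, optional progression
bias) for property testing: mass conservation, monotone death occupancy,
QALY ≤ LY, validator acceptance, and frontier/oracle agreement. These
scenarios emulate the *structure* of disease-progression models, not
their epidemiology: transition rates are arbitrary, states carry no
clinical meaning, and costs are uniform draws. Tests passing on them
certify the algebra of the engine and analytics — they say nothing about
how faithfully any calibrated scenario tracks real advanced-PD cohorts.

## Numerical choices

Row-stochasticity tolerance 1e-9; engine-vs-matrix-power agreement
asserted at 1e-12; `uniroot` tolerance 1e-12; calibration acceptance 1%
relative (printed targets carry four significant figures);
microsimulation cross-checks at 3 standard errors with an explicit,
restored seed. Validation sweep sizes — 200 random frontier instances of
up to 8 therapies against the exhaustive oracle, 1,000 random chains for
the conservation properties, 20 calibration recoveries, 10^5
microsimulation walkers — were chosen so the full suite completes in
well under a minute while keeping Monte-Carlo bounds meaningful.

## Known limitations

* Calibrated matrices are stand-ins matching two aggregate totals; many
  matrices satisfy the same targets, and no attempt is made to recover
  the original trial-derived transition probabilities.
* No probabilistic sensitivity analysis or acceptability curves (the
  source reports none); no societal or informal-care costs (SNS
  perspective); device replacement beyond the single listed exchange is
  not extrapolated; currency conversion (1 € = 1.0815 USD) is
  presentation-only.
* Time-homogeneity means background mortality does not age with the
  cohort; over-20-year extrapolations should be read accordingly.
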