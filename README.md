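# pdcea

Cost-utility analysis of device-aided therapies for advanced Parkinson's
disease, from the perspective of the Spanish National Health System (SNS).

When oral/transdermal therapy no longer controls motor fluctuations,
advanced Parkinson's disease can be managed with device-aided strategies:
continuous subcutaneous apomorphine infusion (Apo-Go, Dacepton), deep brain
stimulation (Percept PC, Percept RC), levodopa-carbidopa intestinal gel
(Duodopa), levodopa-carbidopa-entacapone intestinal gel (Lecigon) and
subcutaneous foslevodopa-foscarbidopa (Foslevodopa). These strategies differ
sharply in acquisition cost, clinical pathway (neurosurgery for DBS, PEG
placement for the intestinal gels) and in the life-years (LY) and
quality-adjusted life-years (QALYs) they deliver. `pdcea` implements the
full pharmacoeconomic comparison for health economists and HTA analysts:
resource-based costing, a Markov cohort model, and incremental
cost-utility analytics.

## The model

**Markov cohort engine.** Health is discretised into a 12-state space
combining pooled Hoehn & Yahr stage (2–3, 4, 5) with OFF-time stratum
(< 50% vs ≥ 50% of waking hours in OFF), event states (surgical
complication, PEG complication, adverse-event discontinuation, switch,
second-line therapy) and absorbing death. With occupancy row-vector
$\pi_t$ and transition matrix $P$, the cohort evolves as
$\pi_{t+1} = \pi_t P$, and discounted effects over horizon $T$ are

$$\mathrm{LY} = \sum_{t=1}^{T} (1+r)^{-t c}\, c \,(1 - \pi_t(\mathrm{dead})),
\qquad
\mathrm{QALY} = \sum_{t=1}^{T} (1+r)^{-t c}\, c \sum_s \pi_t(s)\, u(s),$$

with cycle length $c$ (default 1 year), discount rate $r = 3.5\%$ applied
to costs and effects alike, and state utilities $u(s) \le 1$. A half-cycle
correction and an individual-level microsimulation cross-check are
provided.

**Calibration.** Published totals give per-therapy discounted LY and QALYs
but no transition probabilities. `calibrate()` recovers a scenario by
deterministic nested root-finding: a uniform per-cycle mortality hazard is
solved so discounted LY match (survival is independent of utilities), then
the utility profile is rescaled by one factor so QALYs match exactly.

**Costing.** Pathway cost = Σ count × unit cost over the 5-year clinical
pathway (euros 2023, SNS tariffs); drug cost = PVL unit cost × standard
units/day × 365; totals discounted at 3.5%/year (annuity due for
recurring drug costs, pathway up front).

**CEA.** Average ratios ACE = cost/LY and ACU = cost/QALY; incremental
ratios ICER/ICUR = ΔC/ΔE with dominance sentinels; strict and extended
dominance; the efficiency frontier with stepwise ICURs; willingness-to-pay
classification against the Spanish 22,000–25,000 €/QALY band (60,000
€/QALY in special situations); optional net monetary benefit.

## Worked example

```r
library(pdcea)

fx <- pd_therapy_fixture()                 # packaged therapy tables
results <- average_ratios(implied_totals(fx))
results[results$therapy_id == "dacepton", c("total_cost", "acur_qaly")]
#>   total_cost acur_qaly
#> 2   59956.07     20782

dominated_by_reference(results, "dacepton")
#> [1] "apo_go"     "percept_pc" "percept_rc"

icer(results[results$therapy_id == "lecigon", ],
     results[results$therapy_id == "dacepton", ], measure = "qalys")$value
#> [1] 1125634
```

Dacepton is the most efficient option at 20,782 €/QALY. It strictly
dominates Apo-Go (same QALYs, higher cost) and both DBS strategies (fewer
QALYs, higher cost). Moving from Dacepton to any more effective strategy
costs 218,742–1,125,634 € per QALY gained — far beyond accepted
willingness-to-pay. The full pairwise comparison additionally shows Duodopa
and Lecigon strictly dominated by Foslevodopa, leaving a two-point
efficiency frontier (Dacepton → Foslevodopa).

The complete workflow lives in `analysis/` as numbered scripts:
`01_costing.R` (pathway and drug costs), `02_calibrate_model.R` (Markov
calibration per therapy), `03_cea.R` (ratios, dominance, frontier,
willingness-to-pay); each prints its findings and writes tables under
`results/`.

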