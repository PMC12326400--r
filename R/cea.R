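#' Assemble per-therapy results for cost-effectiveness analysis
#'
#' @param therapy_id Character vector of unique therapy labels.
#' @param total_cost Total (discounted) cost per therapy, euros.
#' @param life_years Discounted life-years gained (the AVG measure).
#' @param qalys Discounted quality-adjusted life-years (the AVAC measure).
#' @return A `therapy_results` data frame.
#' @export
therapy_results <- function(therapy_id, total_cost, life_years, qalys) {
  if (anyDuplicated(therapy_id)) {
    stop("duplicate therapy ids: ",
         paste(unique(therapy_id[duplicated(therapy_id)]), collapse = ", "))
  }
  stopifnot(all(total_cost >= 0), all(life_years > 0), all(qalys >= 0))
  out <- data.frame(
    therapy_id = as.character(therapy_id),
    total_cost = as.numeric(total_cost),
    life_years = as.numeric(life_years),
    qalys = as.numeric(qalys),
    stringsAsFactors = FALSE
  )
  class(out) <- c("therapy_results", "data.frame")
  out
}

effect_col <- function(measure = c("qalys", "life_years")) match.arg(measure)

#' Average cost-effectiveness and cost-utility ratios
#'
#' ACE (average cost-effectiveness ratio) = total cost / life-years;
#' ACU (average cost-utility ratio) = total cost / QALYs. Ratios are exact
#' divisions, unrounded; presentation rounding belongs to
#' [report_tables()].
#'
#' @param results A `therapy_results` data frame.
#' @return The input with `acer_ly` and `acur_qaly` columns added.
#' @export
average_ratios <- function(results) {
  stopifnot(all(results$life_years > 0), all(results$qalys > 0))
  results$acer_ly <- results$total_cost / results$life_years
  results$acur_qaly <- results$total_cost / results$qalys
  results
}

#' Incremental cost-effectiveness/cost-utility ratio between two therapies
#'
#' `ICER = (cost_a - cost_b) / (effect_a - effect_b)` with effects in
#' life-years (ICER proper) or QALYs (ICUR). Degenerate comparisons return
#' a sentinel instead of a number: when one option costs no more and yields
#' no less than the other (with at least one strict inequality) the ratio
#' is meaningless and the dominating side is reported; equal cost and equal
#' effect reports `"cost_comparison"`.
#'
#' @param a,b Single rows of a `therapy_results` data frame (or lists with
#'   `total_cost` and the effect field).
#' @param measure `"qalys"` (default) or `"life_years"`.
#' @return List with `value` (numeric, `NA` when a sentinel applies) and
#'   `sentinel` (`NA`, `"a_dominates"`, `"b_dominates"`, or
#'   `"cost_comparison"`).
#' @export
icer <- function(a, b, measure = c("qalys", "life_years")) {
  measure <- effect_col(measure)
  dc <- a$total_cost - b$total_cost
  de <- a[[measure]] - b[[measure]]
  sentinel <- NA_character_
  value <- NA_real_
  if (dc <= 0 && de >= 0 && (dc < 0 || de > 0)) {
    sentinel <- "a_dominates"
  } else if (dc >= 0 && de <= 0 && (dc > 0 || de < 0)) {
    sentinel <- "b_dominates"
  } else if (dc == 0 && de == 0) {
    sentinel <- "cost_comparison"
  } else {
    value <- dc / de
  }
  list(value = value, sentinel = sentinel)
}

strictly_dominates <- function(cost_a, eff_a, cost_b, eff_b) {
  # a dominates b: no more costly, no less effective, at least one strict;
  # equal-effect-higher-cost counts as dominated
  cost_a <= cost_b && eff_a >= eff_b && (cost_a < cost_b || eff_a > eff_b)
}

#' Classify therapies by strict and extended dominance
#'
#' A therapy is strictly dominated when some other therapy costs no more
#' and yields no less effect, with at least one strict inequality (so an
#' equal-effect, higher-cost option is dominated). Among the remainder,
#' extended dominance is removed iteratively: on the effect-sorted list, a
#' therapy whose incremental ratio against its predecessor exceeds that of
#' its successor is bypassed by a linear combination of its neighbours.
#' Exactly collinear points (equal boundary ratios) are kept; exactly
#' identical cost/effect pairs dominate nothing and are reported
#' nondominated with a warning.
#'
#' @param results A `therapy_results` data frame (>= 2 rows).
#' @param measure Effect measure, `"qalys"` or `"life_years"`.
#' @return The input with columns `dominance` (`"nondominated"`,
#'   `"dominated"`, `"extended_dominated"`) and `dominated_by` (the id of a
#'   strictly dominating therapy, else `NA`).
#' @export
dominance_classify <- function(results, measure = c("qalys", "life_years")) {
  measure <- effect_col(measure)
  if (anyDuplicated(results$therapy_id)) {
    stop("duplicate therapy ids")
  }
  if (nrow(results) < 2L) stop("need at least 2 therapies")
  n <- nrow(results)
  cost <- results$total_cost
  eff <- results[[measure]]

  dominated_by <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (strictly_dominates(cost[j], eff[j], cost[i], eff[i])) {
        dominated_by[i] <- results$therapy_id[j]
        break
      }
    }
  }
  dup <- duplicated(data.frame(cost, eff)) |
    duplicated(data.frame(cost, eff), fromLast = TRUE)
  if (any(dup)) {
    warning("therapies with identical cost and effect: ",
            paste(results$therapy_id[dup], collapse = ", "),
            " (tie rule: reported nondominated)")
  }
  label <- ifelse(is.na(dominated_by), "nondominated", "dominated")

  # extended dominance on the survivors
  surv <- which(label == "nondominated")
  surv <- surv[!duplicated(data.frame(cost[surv], eff[surv]))]
  repeat {
    if (length(surv) < 3L) break
    ord <- surv[order(eff[surv], cost[surv])]
    ic <- diff(cost[ord]) / diff(eff[ord])
    # interior point whose incoming ratio strictly exceeds its outgoing one
    viol <- which(ic[-length(ic)] > ic[-1] &
                    is.finite(ic[-length(ic)]) & is.finite(ic[-1]))
    if (!length(viol)) break
    drop_idx <- ord[viol[1] + 1L]
    label[drop_idx] <- "extended_dominated"
    surv <- setdiff(surv, drop_idx)
  }
  results$dominance <- label
  results$dominated_by <- dominated_by
  results
}

#' Therapies strictly dominated by a designated reference
#'
#' The published comparison anchors dominance on the most efficient
#' (lowest-ACU) option and asks which alternatives it dominates outright.
#'
#' @param results A `therapy_results` data frame.
#' @param reference_id Therapy id of the reference strategy.
#' @param measure Effect measure.
#' @return Character vector of dominated therapy ids (sorted).
#' @export
dominated_by_reference <- function(results, reference_id,
                                   measure = c("qalys", "life_years")) {
  measure <- effect_col(measure)
  r <- match(reference_id, results$therapy_id)
  if (is.na(r)) stop("reference therapy not found: ", reference_id)
  cost <- results$total_cost
  eff <- results[[measure]]
  dom <- vapply(seq_len(nrow(results)), function(i) {
    i != r && strictly_dominates(cost[r], eff[r], cost[i], eff[i])
  }, logical(1))
  sort(results$therapy_id[dom])
}

#' Efficiency frontier with stepwise incremental ratios
#'
#' Orders the non-dominated therapies by increasing effect and reports the
#' stepwise incremental ratio of each against its predecessor on the
#' frontier; the least effective frontier therapy is the reference and
#' carries no ratio. Stepwise ratios are non-decreasing by construction
#' (strictly increasing unless collinear points were kept).
#'
#' @param results A `therapy_results` data frame.
#' @param measure Effect measure.
#' @return Data frame with `therapy_id`, `total_cost`, `effect`, and
#'   `icer_stepwise` (NA for the reference), ordered along the frontier.
#' @export
efficiency_frontier <- function(results, measure = c("qalys", "life_years")) {
  measure <- effect_col(measure)
  if (nrow(results) == 1L) {
    return(data.frame(therapy_id = results$therapy_id,
                      total_cost = results$total_cost,
                      effect = results[[measure]],
                      icer_stepwise = NA_real_,
                      stringsAsFactors = FALSE))
  }
  cls <- dominance_classify(results, measure)
  keep <- cls[cls$dominance == "nondominated", , drop = FALSE]
  keep <- keep[!duplicated(keep[, c("total_cost", measure)]), , drop = FALSE]
  keep <- keep[order(keep[[measure]], keep$total_cost), , drop = FALSE]
  out <- data.frame(
    therapy_id = keep$therapy_id,
    total_cost = keep$total_cost,
    effect = keep[[measure]],
    icer_stepwise = c(NA_real_, diff(keep$total_cost) / diff(keep[[measure]])),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Willingness-to-pay band
#'
#' Spanish cost-utility practice works with an accepted range of 22,000 to
#' 25,000 euros per QALY, extensible to 60,000 euros per QALY in special
#' situations.
#'
#' @param lower,upper Standard band edges, euros/QALY.
#' @param special_upper Upper edge for special situations, euros/QALY.
#' @return A `wtp_band` list.
#' @export
wtp_band <- function(lower = 22000, upper = 25000, special_upper = 60000) {
  if (!(lower <= upper && upper <= special_upper)) {
    stop("willingness-to-pay band must satisfy lower <= upper <= special_upper")
  }
  structure(list(lower = lower, upper = upper, special_upper = special_upper),
            class = "wtp_band")
}

#' Classify a cost-per-QALY value against a willingness-to-pay band
#'
#' Values on a band edge classify into the lower category.
#'
#' @param value Numeric vector of euros/QALY ratios (ACU or ICUR).
#' @param band A [wtp_band()].
#' @return Factor with levels `below_lower`, `within_band`,
#'   `above_band_below_special`, `above_special`.
#' @export
wtp_classify <- function(value, band = wtp_band()) {
  stopifnot(inherits(band, "wtp_band"))
  lv <- c("below_lower", "within_band", "above_band_below_special",
          "above_special")
  out <- ifelse(value <= band$lower, lv[1],
                ifelse(value <= band$upper, lv[2],
                       ifelse(value <= band$special_upper, lv[3], lv[4])))
  factor(out, levels = lv)
}

#' Incremental cost-utility plane coordinates
#'
#' Per-therapy incremental effect and cost against a reference strategy,
#' for plotting on the cost-utility plane; the reference maps to (0, 0).
#'
#' @param results A `therapy_results` data frame.
#' @param reference_id Reference therapy id.
#' @param measure Effect measure.
#' @return Data frame with `therapy_id`, `delta_effect`, `delta_cost`.
#' @export
ce_plane_coordinates <- function(results, reference_id,
                                 measure = c("qalys", "life_years")) {
  measure <- effect_col(measure)
  r <- match(reference_id, results$therapy_id)
  if (is.na(r)) stop("reference therapy not found: ", reference_id)
  data.frame(
    therapy_id = results$therapy_id,
    delta_effect = results[[measure]] - results[[measure]][r],
    delta_cost = results$total_cost - results$total_cost[r],
    stringsAsFactors = FALSE
  )
}

#' Net monetary benefit
#'
#' `NMB = lambda x QALYs - cost` at willingness-to-pay `lambda`. Auxiliary
#' output; not part of the main reported tables.
#'
#' @param results A `therapy_results` data frame.
#' @param lambda Willingness-to-pay, euros/QALY.
#' @return Named numeric vector of NMB per therapy.
#' @export
net_monetary_benefit <- function(results, lambda) {
  stats::setNames(lambda * results$qalys - results$total_cost,
                  results$therapy_id)
}
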