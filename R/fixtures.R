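#' Packaged input bundle for the seven device-aided therapies
#'
#' Loads the transcribed source tables shipped with the package: unit costs
#' and per-therapy resource use for the 5-year clinical pathway (euros,
#' 2023), drug regimens at ex-factory price with mean standard daily doses,
#' the published discounted effect totals (life-years and QALYs per
#' therapy), and the published average cost-effectiveness (ACE) and
#' cost-utility (ACU) ratios. Monetary fields in the raw CSVs use Spanish
#' number formatting and are parsed on load.
#'
#' The seven strategies are continuous subcutaneous apomorphine infusion
#' (Apo-Go, Dacepton), deep brain stimulation (Percept PC, Percept RC),
#' levodopa-carbidopa intestinal gel (Duodopa),
#' levodopa-carbidopa-entacapone intestinal gel (Lecigon) and subcutaneous
#' foslevodopa-foscarbidopa (Foslevodopa). The DBS strategies have no drug
#' acquisition cost in the regimen table.
#'
#' @param locale Decimal convention of the packaged tables (`"es_ES"`).
#' @return A list with data frames `unit_costs`, `resource_use`,
#'   `regimens`, `effects`, `printed_ratios`, the character vector
#'   `therapies`, and the default `wtp_band`.
#' @export
pd_therapy_fixture <- function(locale = "es_ES") {
  path <- function(f) system.file("extdata", f, package = "pdcea",
                                  mustWork = TRUE)
  unit_costs <- read_cost_table(path("unit_costs.csv"),
                                numeric_cols = "unit_cost", locale = locale)
  unit_costs$source_year <- as.integer(unit_costs$source_year)
  resource_use <- utils::read.csv(path("resource_use.csv"),
                                  stringsAsFactors = FALSE)
  regimens <- read_cost_table(
    path("drug_regimens.csv"),
    numeric_cols = c("pack_price", "dose_per_standard_unit_mg",
                     "cost_per_standard_unit", "daily_dose_mg",
                     "standard_units_per_day", "annual_cost_printed"),
    locale = locale
  )
  effects <- utils::read.csv(path("effects.csv"), stringsAsFactors = FALSE)
  printed_ratios <- read_cost_table(
    path("ratios_printed.csv"),
    numeric_cols = c("ace_printed", "acu_printed"), locale = locale
  )
  list(
    unit_costs = unit_costs,
    resource_use = resource_use,
    regimens = regimens,
    effects = effects,
    printed_ratios = printed_ratios,
    therapies = effects$therapy_id,
    wtp_band = wtp_band()
  )
}

#' Calibration targets from the fixture effect totals
#'
#' @param fixture A fixture bundle from [pd_therapy_fixture()].
#' @param tolerance Relative calibration tolerance (default 0.01).
#' @return A list of [calibration_target()] objects, one per therapy.
#' @export
fixture_targets <- function(fixture = pd_therapy_fixture(),
                            tolerance = 0.01) {
  lapply(seq_len(nrow(fixture$effects)), function(i) {
    calibration_target(
      therapy_id = fixture$effects$therapy_id[i],
      life_years = fixture$effects$life_years[i],
      qalys = fixture$effects$qalys[i],
      tolerance = tolerance
    )
  })
}

#' Total costs implied by the published ratio table
#'
#' The source analysis prints average cost-utility ratios (ACU) and the
#' effect totals but not the total costs themselves; the implied total per
#' therapy is `ACU x QALYs`. These implied totals are the cost basis used
#' to reproduce the published dominance and incremental results.
#'
#' @param fixture A fixture bundle.
#' @return A `therapy_results` data frame with implied total costs.
#' @export
implied_totals <- function(fixture = pd_therapy_fixture()) {
  pr <- fixture$printed_ratios
  eff <- fixture$effects
  idx <- match(pr$therapy_id, eff$therapy_id)
  stopifnot(!anyNA(idx))
  therapy_results(
    therapy_id = pr$therapy_id,
    total_cost = pr$acu_printed * eff$qalys[idx],
    life_years = eff$life_years[idx],
    qalys = eff$qalys[idx]
  )
}

#' Pathway and drug costs recomputed from the fixture tables
#'
#' Re-derives every pathway total from `count x unit cost` and every annual
#' drug cost from `unit cost x units/day x 365`, then combines them into a
#' discounted 5-year total per therapy via [total_cost()].
#'
#' @param fixture A fixture bundle.
#' @param horizon_years Costing horizon (default 5).
#' @param rate Annual discount rate (default 0.035).
#' @param timing Recurring-payment timing, see [total_cost()].
#' @return Data frame with one row per therapy: `pathway_cost_5y`,
#'   `drug_cost_annual`, `total_cost`, `average_annual_cost`.
#' @export
fixture_costs <- function(fixture = pd_therapy_fixture(), horizon_years = 5L,
                          rate = 0.035,
                          timing = c("start_of_year", "end_of_year")) {
  timing <- match.arg(timing)
  rows <- lapply(fixture$therapies, function(th) {
    uses <- fixture$resource_use[fixture$resource_use$therapy_id == th, ]
    pw <- pathway_cost(uses, fixture$unit_costs)
    reg <- fixture$regimens[fixture$regimens$therapy_id == th, ]
    drug <- if (nrow(reg)) annual_drug_cost(reg) else 0
    cb <- total_cost(pw, drug, horizon_years = horizon_years, rate = rate,
                     timing = timing, therapy_id = th)
    data.frame(
      therapy_id = th,
      pathway_cost_5y = cb$pathway_cost_5y,
      drug_cost_annual = cb$drug_cost_annual,
      total_cost = cb$total_cost,
      average_annual_cost = cb$average_annual_cost,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
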