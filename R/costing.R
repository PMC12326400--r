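#' Parse a locale-formatted monetary or numeric string
#'
#' Spanish source tables use `.` as thousands separator and `,` as decimal
#' mark (`"86.423,86"`); `en_US` is the reverse. A trailing euro sign and
#' surrounding whitespace are tolerated.
#'
#' @param text Character vector of numerals.
#' @param locale `"es_ES"` (default) or `"en_US"`.
#' @return Numeric vector.
#' @export
parse_money <- function(text, locale = c("es_ES", "en_US")) {
  locale <- match.arg(locale)
  raw <- trimws(gsub("€", "", text))
  if (any(!nzchar(raw))) stop("empty numeral")
  if (locale == "es_ES") {
    ok <- grepl("^-?(\\d{1,3}(\\.\\d{3})+|\\d+)(,\\d+)?$", raw)
  } else {
    ok <- grepl("^-?(\\d{1,3}(,\\d{3})+|\\d+)(\\.\\d+)?$", raw)
  }
  if (any(!ok)) {
    stop("malformed ", locale, " numeral: ",
         paste(unique(raw[!ok]), collapse = ", "))
  }
  norm <- if (locale == "es_ES") {
    gsub(",", ".", gsub("\\.", "", raw), fixed = FALSE)
  } else {
    gsub(",", "", raw, fixed = TRUE)
  }
  as.numeric(norm)
}

#' Format an amount in a locale's numeric convention
#'
#' Inverse of [parse_money()] for cent-precision values.
#'
#' @param x Numeric vector (euros).
#' @param locale `"es_ES"` or `"en_US"`.
#' @param digits Decimal places (default 2).
#' @return Character vector.
#' @export
format_money <- function(x, locale = c("es_ES", "en_US"), digits = 2) {
  locale <- match.arg(locale)
  if (locale == "es_ES") {
    formatC(x, format = "f", digits = digits, big.mark = ".",
            decimal.mark = ",")
  } else {
    formatC(x, format = "f", digits = digits, big.mark = ",",
            decimal.mark = ".")
  }
}

#' Total clinical-pathway cost from resource use and unit costs
#'
#' Sums `count x unit_cost` over all resource items used by a therapy over
#' the costing horizon (pre-treatment work-up, procedure and 5 years of
#' follow-up in the packaged tables), rounded to cents.
#'
#' @param uses Data frame with columns `item_id`, `count` (and optionally
#'   `therapy_id`); counts are uses over the horizon.
#' @param costs Data frame with columns `item_id`, `unit_cost` (euros).
#' @return Total cost in euros, rounded to cents.
#' @export
pathway_cost <- function(uses, costs) {
  stopifnot(is.data.frame(uses), is.data.frame(costs))
  if (nrow(uses) == 0L) return(0)
  if (anyDuplicated(costs$item_id)) {
    stop("duplicate unit-cost entries for item(s): ",
         paste(unique(costs$item_id[duplicated(costs$item_id)]),
               collapse = ", "))
  }
  idx <- match(uses$item_id, costs$item_id)
  if (anyNA(idx)) {
    stop("no unit cost for item(s): ",
         paste(unique(uses$item_id[is.na(idx)]), collapse = ", "))
  }
  if (any(uses$count < 0)) stop("negative resource-use count")
  round(sum(uses$count * costs$unit_cost[idx]), 2)
}

#' Annual drug acquisition cost of a regimen
#'
#' Annual cost at ex-factory price (PVL) for the mean standard dose:
#' `cost_per_standard_unit x standard_units_per_day x days_per_year`,
#' rounded to whole euros (the precision of the source regimen table).
#'
#' @param regimen One-row data frame or list with `cost_per_standard_unit`
#'   and `standard_units_per_day`.
#' @param days_per_year Days per year (default 365).
#' @return Annual cost in whole euros.
#' @export
annual_drug_cost <- function(regimen, days_per_year = 365L) {
  cpu <- regimen$cost_per_standard_unit
  upd <- regimen$standard_units_per_day
  if (is.null(cpu) || is.null(upd)) {
    stop("regimen needs cost_per_standard_unit and standard_units_per_day")
  }
  if (any(upd <= 0)) stop("standard_units_per_day must be positive")
  if (any(cpu < 0)) stop("cost_per_standard_unit must be non-negative")
  round(cpu * upd * days_per_year)
}

#' Discounted total and average annual cost of a therapy
#'
#' Combines a one-off clinical-pathway cost with an annually recurring drug
#' cost over the costing horizon, discounting at `rate` per year. By
#' default the pathway cost falls entirely at the start of year 0
#' (undiscounted) and the drug cost is an annuity due (payments at the
#' start of each year, `t = 0 .. horizon - 1`). An optional
#' `pathway_followup` portion of the pathway cost is instead spread
#' uniformly over the horizon and discounted on the same schedule as the
#' drug cost.
#'
#' @param pathway_5y Pathway cost over the horizon, euros.
#' @param drug_annual Annual drug cost, euros.
#' @param horizon_years Costing horizon in whole years (default 5).
#' @param rate Annual discount rate (default 0.035).
#' @param timing `"start_of_year"` (annuity due, default) or
#'   `"end_of_year"` (ordinary annuity) for recurring payments.
#' @param pathway_followup Portion of `pathway_5y` spread uniformly over
#'   the horizon rather than paid up front (default 0).
#' @param therapy_id Optional label.
#' @return A `cost_breakdown`: list with the inputs plus `total_cost`
#'   (discounted), `total_cost_undiscounted` and `average_annual_cost`
#'   (= total_cost / horizon).
#' @export
total_cost <- function(pathway_5y, drug_annual, horizon_years = 5L,
                       rate = 0.035, timing = c("start_of_year", "end_of_year"),
                       pathway_followup = 0, therapy_id = NA_character_) {
  timing <- match.arg(timing)
  stopifnot(horizon_years >= 1, rate >= 0,
            pathway_5y >= 0, drug_annual >= 0,
            pathway_followup >= 0, pathway_followup <= pathway_5y)
  years <- if (timing == "start_of_year") 0:(horizon_years - 1) else seq_len(horizon_years)
  annuity <- sum((1 + rate)^(-years))
  upfront <- pathway_5y - pathway_followup
  pathway_disc <- upfront + (pathway_followup / horizon_years) * annuity
  drug_disc <- drug_annual * annuity
  total <- pathway_disc + drug_disc
  structure(
    list(
      therapy_id = therapy_id,
      pathway_cost_5y = pathway_5y,
      drug_cost_annual = drug_annual,
      horizon_years = horizon_years,
      discount_rate = rate,
      timing = timing,
      pathway_component = pathway_disc,
      drug_component = drug_disc,
      total_cost = total,
      total_cost_undiscounted = pathway_5y + drug_annual * horizon_years,
      average_annual_cost = total / horizon_years
    ),
    class = "cost_breakdown"
  )
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat(sprintf(
    "Cost breakdown%s: pathway %.2f + drug %.0f/yr over %d yrs @ %.1f%% -> total %.2f (avg %.2f/yr)\n",
    if (is.na(x$therapy_id)) "" else paste0(" [", x$therapy_id, "]"),
    x$pathway_cost_5y, x$drug_cost_annual, x$horizon_years,
    100 * x$discount_rate, x$total_cost, x$average_annual_cost))
  invisible(x)
}

#' Read a locale-formatted cost table
#'
#' Reads a CSV whose monetary/numeric columns use the given locale's
#' separators and converts them to numeric.
#'
#' @param path CSV path.
#' @param numeric_cols Character vector of column names to parse with
#'   [parse_money()].
#' @param locale Decimal convention of the file.
#' @return A data frame with parsed numeric columns.
#' @export
read_cost_table <- function(path, numeric_cols, locale = c("es_ES", "en_US")) {
  locale <- match.arg(locale)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  for (col in intersect(numeric_cols, names(df))) {
    df[[col]] <- parse_money(df[[col]], locale)
  }
  df
}
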