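#' Health-state flags recognised by the model
#'
#' The advanced-Parkinson state space combines Hoehn & Yahr (H&Y) severity
#' stages and OFF-time strata for patients on device therapy with a set of
#' event states (surgical or PEG complications, adverse-event
#' discontinuation, treatment switch, second-line therapy) and an absorbing
#' death state.
#'
#' @keywords internal
STATE_FLAGS <- c(
  "on_treatment", "surgery_complication", "peg_complication",
  "ae_discontinued", "switched", "second_line", "dead"
)

#' Define a single health state
#'
#' @param id Short unique label for the state.
#' @param flag One of the recognised state flags (see [STATE_FLAGS]).
#' @param utility Health-state utility weight in `[-0.5, 1]`; must be 0 for
#'   the dead state.
#' @param cost_per_cycle Per-cycle state cost in euros (>= 0).
#' @param hy_stage Hoehn & Yahr stage (2--5) or `NA` for event states.
#' @param off_stratum `"low_off"` (< 50% of waking time in OFF),
#'   `"high_off"` (>= 50%), or `NA`.
#'
#' @return A one-row data frame describing the state.
#' @export
health_state <- function(id, flag = "on_treatment", utility,
                         cost_per_cycle = 0, hy_stage = NA,
                         off_stratum = NA) {
  flag <- match.arg(flag, STATE_FLAGS)
  if (!is.na(off_stratum)) {
    off_stratum <- match.arg(off_stratum, c("low_off", "high_off"))
  }
  data.frame(
    id = as.character(id),
    hy_stage = as.integer(hy_stage),
    off_stratum = as.character(off_stratum),
    flag = flag,
    utility = as.numeric(utility),
    cost_per_cycle = as.numeric(cost_per_cycle),
    stringsAsFactors = FALSE
  )
}

#' Default 12-state template for advanced Parkinson's disease
#'
#' Six on-treatment states crossing pooled H&Y severity ({2--3, 4, 5}) with
#' OFF-time stratum ({low, high}), four event states (surgical complication,
#' PEG complication, adverse-event discontinuation, treatment switch), a
#' second-line therapy state and death. The published model is described
#' only by its ingredients (12 states built from H&Y stage, OFF time,
#' complications, adverse events, switching and death), so this enumeration
#' is a configurable default, not a claim about the original state list.
#'
#' Utilities are plausible advanced-PD values on the EQ-5D scale; during
#' calibration they act as a relative profile that is rescaled to match
#' target QALY totals, so only their ratios matter.
#'
#' @return A data frame of 12 health states.
#' @export
default_state_template <- function() {
  rbind(
    health_state("hy23_low",  "on_treatment", 0.75, hy_stage = 2, off_stratum = "low_off"),
    health_state("hy23_high", "on_treatment", 0.60, hy_stage = 2, off_stratum = "high_off"),
    health_state("hy4_low",   "on_treatment", 0.55, hy_stage = 4, off_stratum = "low_off"),
    health_state("hy4_high",  "on_treatment", 0.40, hy_stage = 4, off_stratum = "high_off"),
    health_state("hy5_low",   "on_treatment", 0.30, hy_stage = 5, off_stratum = "low_off"),
    health_state("hy5_high",  "on_treatment", 0.20, hy_stage = 5, off_stratum = "high_off"),
    health_state("surgery_complication", "surgery_complication", 0.45),
    health_state("peg_complication",     "peg_complication",     0.45),
    health_state("ae_discontinued",      "ae_discontinued",      0.40),
    health_state("switched",             "switched",             0.50),
    health_state("second_line",          "second_line",          0.45),
    health_state("dead",                 "dead",                 0.00)
  )
}

#' Build and validate a Markov state space
#'
#' @param template Data frame of health states (one row per state, as
#'   produced by [health_state()] or [default_state_template()]), or a named
#'   list convertible to one (e.g. parsed from YAML/JSON via
#'   [read_state_space()]).
#' @param cycle_length Cycle length in years, in `(0, 1]`. Default 1 year.
#'
#' @return An object of class `state_space` with elements `states` (data
#'   frame) and `cycle_length`.
#' @export
build_state_space <- function(template = default_state_template(),
                              cycle_length = 1) {
  if (is.list(template) && !is.data.frame(template)) {
    template <- do.call(rbind, lapply(template, function(s) {
      do.call(health_state, s)
    }))
  }
  stopifnot(is.data.frame(template))
  needed <- c("id", "flag", "utility", "cost_per_cycle")
  missing_cols <- setdiff(needed, names(template))
  if (length(missing_cols)) {
    stop("state template lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(template$id)) {
    stop("duplicate state ids: ",
         paste(unique(template$id[duplicated(template$id)]), collapse = ", "))
  }
  bad_flag <- setdiff(template$flag, STATE_FLAGS)
  if (length(bad_flag)) {
    stop("unknown state flag(s): ", paste(bad_flag, collapse = ", "))
  }
  dead <- which(template$flag == "dead")
  if (length(dead) != 1L) {
    stop("state space must contain exactly one dead state (found ",
         length(dead), ")")
  }
  if (template$utility[dead] != 0 || template$cost_per_cycle[dead] != 0) {
    stop("dead state '", template$id[dead],
         "' must have utility 0 and cost_per_cycle 0")
  }
  too_high <- template$id[template$utility > 1]
  if (length(too_high)) {
    stop("utility > 1 for state(s): ", paste(too_high, collapse = ", "))
  }
  too_low <- template$id[template$utility < -0.5]
  if (length(too_low)) {
    stop("utility < -0.5 for state(s): ", paste(too_low, collapse = ", "))
  }
  neg_cost <- template$id[template$cost_per_cycle < 0]
  if (length(neg_cost)) {
    stop("negative cost_per_cycle for state(s): ",
         paste(neg_cost, collapse = ", "))
  }
  if (!is.numeric(cycle_length) || length(cycle_length) != 1 ||
      cycle_length <= 0 || cycle_length > 1) {
    stop("cycle_length must be a single value in (0, 1]")
  }
  structure(
    list(states = template, cycle_length = cycle_length),
    class = "state_space"
  )
}

#' Read a state space from a YAML or JSON configuration file
#'
#' The file must contain a `states` list (each entry with at least `id`,
#' `flag`, `utility`) and optionally `cycle_length`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `state_space`.
#' @export
read_state_space <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    stop("unsupported config format (expected .yaml/.yml/.json): ", path)
  }
  if (is.null(cfg$states)) stop("config has no 'states' entry: ", path)
  cycle_length <- if (is.null(cfg$cycle_length)) 1 else cfg$cycle_length
  build_state_space(cfg$states, cycle_length = cycle_length)
}

#' @export
print.state_space <- function(x, ...) {
  cat("Markov state space:", nrow(x$states), "states, cycle length",
      x$cycle_length, "years\n")
  print(x$states, row.names = FALSE)
  invisible(x)
}

n_states <- function(space) nrow(space$states)

dead_index <- function(space) which(space$states$flag == "dead")

alive_indices <- function(space) which(space$states$flag != "dead")

on_treatment_indices <- function(space) {
  which(space$states$flag == "on_treatment")
}

#' Default initial cohort distribution
#'
#' Half of the cohort starts in high-OFF states (> 14 h/day in OFF at
#' treatment start) and half in low-OFF states, each half split uniformly
#' across the H&Y severity strata; event states and death start empty.
#'
#' @param space A `state_space`.
#' @return A named occupancy vector summing to 1.
#' @export
default_initial_distribution <- function(space) {
  st <- space$states
  init <- stats::setNames(numeric(nrow(st)), st$id)
  on <- st$flag == "on_treatment"
  for (stratum in c("low_off", "high_off")) {
    idx <- which(on & st$off_stratum == stratum)
    if (!length(idx)) stop("no on-treatment states in stratum ", stratum)
    init[idx] <- 0.5 / length(idx)
  }
  init
}
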