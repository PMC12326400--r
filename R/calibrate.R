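#' Calibration target for one therapy
#'
#' @param therapy_id Therapy label.
#' @param life_years Target discounted life-years (> 0).
#' @param qalys Target discounted QALYs (> 0).
#' @param tolerance Relative tolerance in `(0, 0.05]` (default 0.01;
#'   the published targets carry four significant figures).
#' @return A `calibration_target` list.
#' @export
calibration_target <- function(therapy_id, life_years, qalys,
                               tolerance = 0.01) {
  stopifnot(life_years > 0, qalys > 0,
            tolerance > 0, tolerance <= 0.05)
  structure(
    list(therapy_id = therapy_id, life_years = life_years, qalys = qalys,
         tolerance = tolerance),
    class = "calibration_target"
  )
}

#' Parameterised therapy transition matrix
#'
#' Builds a row-stochastic, dead-absorbing transition matrix for a state
#' space from three parameters. Every alive state carries the same
#' per-cycle mortality probability, so cohort survival is exactly
#' `(1 - mortality)^t` and discounted life-years are a strictly decreasing
#' function of mortality — the property the calibration root-finder relies
#' on. Conditional on survival, on-treatment states progress along the
#' severity chain (low-OFF to high-OFF within a pooled H&Y stratum, then to
#' the next stratum) with probability `progression`, move to one of the
#' event states (complications, adverse-event discontinuation, switch,
#' second line) with total probability `event_rate`, and otherwise stay;
#' the last chain state progresses into the second-line state when present.
#' Event states are persistent apart from mortality.
#'
#' @param space A `state_space`.
#' @param mortality Per-cycle death probability from every alive state,
#'   in `[0, 1)`.
#' @param progression Per-cycle conditional progression probability.
#' @param event_rate Total per-cycle conditional probability of entering an
#'   event state.
#' @return A validated transition matrix.
#' @export
build_therapy_matrix <- function(space, mortality, progression = 0.10,
                                 event_rate = 0.02) {
  stopifnot(mortality >= 0, mortality < 1,
            progression >= 0, event_rate >= 0,
            progression + event_rate <= 1)
  st <- space$states
  k <- nrow(st)
  ids <- st$id
  d <- dead_index(space)
  on <- on_treatment_indices(space)
  events <- which(!st$flag %in% c("on_treatment", "dead"))
  second <- which(st$flag == "second_line")

  m <- matrix(0, k, k, dimnames = list(ids, ids))
  m[d, d] <- 1
  surv <- 1 - mortality
  for (pos in seq_along(on)) {
    i <- on[pos]
    m[i, d] <- mortality
    nxt <- if (pos < length(on)) on[pos + 1L] else if (length(second)) second[1] else i
    if (length(events)) {
      m[i, events] <- m[i, events] + surv * event_rate / length(events)
    }
    m[i, nxt] <- m[i, nxt] + surv * progression
    m[i, i] <- m[i, i] + surv * (1 - progression -
                                   if (length(events)) event_rate else 0)
    if (!length(events)) m[i, i] <- m[i, i] + surv * event_rate
  }
  for (i in events) {
    m[i, d] <- mortality
    m[i, i] <- surv
  }
  validate_transitions(m, space)
}

#' Calibrate a therapy scenario to target effect totals
#'
#' Recovers a transition matrix and utility map whose discounted cohort
#' effects reproduce given life-year and QALY totals. Two free parameters
#' are solved in a nested, deterministic fashion: (1) the per-cycle
#' mortality probability is found by one-dimensional root-finding so that
#' discounted life-years match the target (survival is independent of the
#' utility map); (2) the state utility profile of the space is then
#' rescaled by a single factor so that discounted QALYs match exactly
#' (QALYs are linear in utilities). No random numbers are involved.
#'
#' @param target A [calibration_target()].
#' @param space A `state_space`; its utilities act as the relative profile
#'   to be rescaled.
#' @param rate Annual discount rate applied to effects (default 0.035).
#' @param horizon_years Effect horizon in years (default 20; this is
#'   deliberately longer than the 5-year costing horizon because the
#'   published life-year totals exceed 5).
#' @param init Initial distribution (default
#'   [default_initial_distribution()]).
#' @param progression,event_rate Structural nuisance parameters of
#'   [build_therapy_matrix()], held fixed during calibration.
#' @param correction Half-cycle correction flag for effect accumulation.
#'
#' @return A `calibrated_scenario`: list with `space` (utilities rescaled),
#'   `matrix`, `params` (mortality, utility_scale, progression,
#'   event_rate), `effects` (achieved `effect_summary`), and `target`.
#' @export
calibrate <- function(target, space = build_state_space(), rate = 0.035,
                      horizon_years = 20, init = default_initial_distribution(space),
                      progression = 0.10, event_rate = 0.02,
                      correction = c("none", "half_cycle")) {
  correction <- match.arg(correction)
  stopifnot(inherits(target, "calibration_target"), rate >= 0)
  cl <- space$cycle_length
  n_cycles <- as.integer(round(horizon_years / cl))

  ly_at <- function(mortality) {
    m <- build_therapy_matrix(space, mortality, progression, event_rate)
    tr <- run_cohort(space, m, init, n_cycles)
    discounted_effects(tr, rate, correction)$life_years
  }
  max_ly <- ly_at(0)
  if (target$life_years > max_ly) {
    stop("infeasible target: life-years ", target$life_years,
         " exceed the maximum ", round(max_ly, 4),
         " achievable at zero mortality over a ", horizon_years,
         "-year horizon at rate ", rate)
  }
  if (target$qalys > target$life_years * 1) {
    stop("infeasible target: QALYs ", target$qalys,
         " exceed life-years x maximum admissible utility (",
         target$life_years, " x 1)")
  }

  mortality <- if (abs(max_ly - target$life_years) < 1e-12) 0 else {
    stats::uniroot(function(p) ly_at(p) - target$life_years,
                   interval = c(0, 0.999), tol = 1e-12)$root
  }
  m <- build_therapy_matrix(space, mortality, progression, event_rate)
  trace <- run_cohort(space, m, init, n_cycles)
  base_eff <- discounted_effects(trace, rate, correction)
  if (base_eff$qalys <= 0) stop("degenerate utility profile: base QALYs are 0")
  utility_scale <- target$qalys / base_eff$qalys
  new_u <- space$states$utility * utility_scale
  if (max(new_u) > 1 + 1e-12) {
    stop("infeasible target: required utility scale ", round(utility_scale, 4),
         " pushes the maximum state utility to ", round(max(new_u), 4),
         " > 1 (binding bound: QALY/LY ratio too high for this profile)")
  }
  space2 <- space
  space2$states$utility <- new_u
  trace2 <- run_cohort(space2, m, init, n_cycles)
  eff <- discounted_effects(trace2, rate, correction,
                            therapy_id = target$therapy_id)
  rel <- function(x, y) abs(x - y) / y
  if (rel(eff$life_years, target$life_years) > target$tolerance ||
      rel(eff$qalys, target$qalys) > target$tolerance) {
    stop("calibration failed to reach targets within tolerance")
  }
  structure(
    list(space = space2, matrix = m,
         params = list(mortality = mortality, utility_scale = utility_scale,
                       progression = progression, event_rate = event_rate),
         effects = eff, target = target,
         rate = rate, horizon_years = horizon_years, init = init,
         correction = correction),
    class = "calibrated_scenario"
  )
}

#' @export
print.calibrated_scenario <- function(x, ...) {
  cat(sprintf(
    "Calibrated scenario [%s]: mortality %.5f/cycle, utility scale %.4f\n",
    x$target$therapy_id, x$params$mortality, x$params$utility_scale))
  cat(sprintf("  achieved %.4f LY (target %.3f), %.4f QALY (target %.3f)\n",
              x$effects$life_years, x$target$life_years,
              x$effects$qalys, x$target$qalys))
  invisible(x)
}

#' Specification for a randomised test scenario
#'
#' @param seed Integer seed (mandatory).
#' @param n_states Number of states including death (>= 2).
#' @param mortality_scale Scales per-state random death probabilities;
#'   0 means no state can die.
#' @param utility_range Interval within `[0, 1]` for alive-state utilities.
#' @param progression_bias Multiplier (> 0) applied to transition weights
#'   toward later (worse) states; 1 is unbiased.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(seed, n_states = 6L, mortality_scale = 0.1,
                          utility_range = c(0.2, 0.9),
                          progression_bias = 1) {
  stopifnot(n_states >= 2L, mortality_scale >= 0,
            length(utility_range) == 2,
            utility_range[1] >= 0, utility_range[2] <= 1,
            utility_range[1] <= utility_range[2],
            progression_bias > 0)
  structure(
    list(seed = as.integer(seed), n_states = as.integer(n_states),
         mortality_scale = mortality_scale, utility_range = utility_range,
         progression_bias = progression_bias),
    class = "scenario_spec"
  )
}

#' Generate a random Markov scenario for property testing
#'
#' Draws a state space with random utilities and per-cycle costs, a random
#' row-stochastic dead-absorbing transition matrix, and a random initial
#' distribution over the alive states. Fully reproducible from the seed;
#' the global RNG state is saved and restored.
#'
#' @param spec A [scenario_spec()].
#' @return List with `space`, `matrix`, `init`, and `spec`.
#' @export
generate_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(spec$seed)

  k <- spec$n_states
  n_alive <- k - 1L
  template <- do.call(rbind, c(
    lapply(seq_len(n_alive), function(i) {
      health_state(paste0("s", i), "on_treatment",
                   utility = stats::runif(1, spec$utility_range[1],
                                          spec$utility_range[2]),
                   cost_per_cycle = stats::runif(1, 0, 5000))
    }),
    list(health_state("dead", "dead", 0, 0))
  ))
  space <- build_state_space(template)

  m <- matrix(0, k, k, dimnames = list(space$states$id, space$states$id))
  m[k, k] <- 1
  for (i in seq_len(n_alive)) {
    p_death <- min(spec$mortality_scale * stats::runif(1), 0.8)
    if (spec$mortality_scale == 0) p_death <- 0
    w <- stats::rgamma(n_alive, shape = 1)
    if (spec$progression_bias != 1) {
      later <- seq_len(n_alive) > i
      w[later] <- w[later] * spec$progression_bias
    }
    m[i, seq_len(n_alive)] <- (1 - p_death) * w / sum(w)
    m[i, k] <- p_death
  }
  init <- stats::rgamma(n_alive, shape = 1)
  init <- c(init / sum(init), 0)

  list(space = space, matrix = validate_transitions(m, space),
       init = init, spec = spec)
}
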