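#' Validate a transition matrix against a state space
#'
#' Checks that the matrix is square with one row per state, has no negative
#' entries, that every row sums to 1 within `tol`, and that the dead row is
#' absorbing (a unit vector onto the dead state).
#'
#' @param m Numeric matrix of per-cycle transition probabilities,
#'   `m[i, j] = P(to state j | in state i)`. Row/column names, if present,
#'   must match the state ids in order.
#' @param space A `state_space`.
#' @param tol Row-sum tolerance (default `1e-9`).
#'
#' @return `m` (with state ids as dimnames), invisibly unchanged, if valid;
#'   otherwise an error.
#' @export
validate_transitions <- function(m, space, tol = 1e-9) {
  k <- n_states(space)
  if (!is.matrix(m) || !is.numeric(m)) stop("transition matrix must be a numeric matrix")
  if (nrow(m) != k || ncol(m) != k) {
    stop("transition matrix is ", nrow(m), "x", ncol(m),
         " but state space has ", k, " states")
  }
  ids <- space$states$id
  if (!is.null(rownames(m)) && !identical(rownames(m), ids)) {
    stop("transition matrix row names do not match state ids")
  }
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop("negative transition probability at (", ids[bad[1]], " -> ",
         ids[bad[2]], ")")
  }
  rs <- rowSums(m)
  off <- which(abs(rs - 1) > tol)
  if (length(off)) {
    stop("row(s) not summing to 1: ",
         paste0(ids[off], " (sum ", signif(rs[off], 12), ")", collapse = ", "))
  }
  d <- dead_index(space)
  unit <- numeric(k); unit[d] <- 1
  if (any(abs(m[d, ] - unit) > tol)) {
    stop("dead state row must be absorbing (unit vector onto '", ids[d], "')")
  }
  dimnames(m) <- list(ids, ids)
  m
}

#' Propagate a cohort through a Markov chain
#'
#' Deterministic cohort simulation: the occupancy row at cycle `t + 1` is
#' the occupancy at `t` multiplied by the transition matrix.
#'
#' @param space A `state_space`.
#' @param m Transition matrix (validated via [validate_transitions()]).
#' @param init Initial occupancy vector summing to 1; defaults to
#'   [default_initial_distribution()].
#' @param n_cycles Number of cycles to run (>= 1).
#'
#' @return A `cohort_trace`: list with `occupancy`
#'   (`(n_cycles + 1) x n_states` matrix, row 1 = cycle 0 = `init`),
#'   `n_cycles`, `initial_distribution`, and the `space` used.
#' @export
run_cohort <- function(space, m, init = default_initial_distribution(space),
                       n_cycles = 20L) {
  m <- validate_transitions(m, space)
  k <- n_states(space)
  init <- as.numeric(init)
  if (length(init) != k) {
    stop("initial distribution has length ", length(init),
         " but state space has ", k, " states")
  }
  if (any(init < 0) || abs(sum(init) - 1) > 1e-9) {
    stop("initial distribution must be non-negative and sum to 1")
  }
  n_cycles <- as.integer(n_cycles)
  if (n_cycles < 1L) stop("n_cycles must be >= 1")
  occ <- matrix(NA_real_, nrow = n_cycles + 1L, ncol = k,
                dimnames = list(0:n_cycles, space$states$id))
  occ[1L, ] <- init
  for (t in seq_len(n_cycles)) {
    occ[t + 1L, ] <- occ[t, , drop = FALSE] %*% m
  }
  structure(
    list(occupancy = occ, n_cycles = n_cycles,
         initial_distribution = init, space = space),
    class = "cohort_trace"
  )
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat("Cohort trace:", x$n_cycles, "cycles,", ncol(x$occupancy), "states\n")
  cat("Final occupancy:\n")
  print(round(x$occupancy[nrow(x$occupancy), ], 4))
  invisible(x)
}

#' Tidy a cohort trace
#'
#' @param x A `cohort_trace`.
#' @param ... Unused.
#' @return A data frame with columns `cycle`, `state_id`, `occupancy`.
#' @export
as.data.frame.cohort_trace <- function(x, ...) {
  occ <- x$occupancy
  data.frame(
    cycle = rep(0:x$n_cycles, times = ncol(occ)),
    state_id = rep(colnames(occ), each = nrow(occ)),
    occupancy = as.vector(occ),
    stringsAsFactors = FALSE
  )
}

#' Write a cohort trace as tidy CSV
#'
#' @param trace A `cohort_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' Discounted life-years and QALYs from a cohort trace
#'
#' Effects are accumulated from cycle 1 to the horizon (the cycle-0
#' occupancy is the starting distribution and carries no elapsed time), each
#' cycle discounted by `(1 + rate)^(-t * cycle_length)`. With the half-cycle
#' correction, the occupancy credited to cycle `t` is the mean of the
#' occupancies at `t - 1` and `t`, approximating mid-cycle event timing.
#'
#' @param trace A `cohort_trace`.
#' @param rate Annual discount rate (fraction per year, >= 0); the study
#'   perspective applies 3.5% to both costs and utilities.
#' @param correction `"none"` (default) or `"half_cycle"`.
#' @param therapy_id Optional label carried into the summary.
#'
#' @return An `effect_summary`: list with `therapy_id`, `life_years`,
#'   `qalys`, `state_costs` (discounted per-cycle state-cost total), `rate`,
#'   and `correction`.
#' @export
discounted_effects <- function(trace, rate = 0.035,
                               correction = c("none", "half_cycle"),
                               therapy_id = NA_character_) {
  correction <- match.arg(correction)
  stopifnot(inherits(trace, "cohort_trace"), rate >= 0)
  space <- trace$space
  cl <- space$cycle_length
  occ <- trace$occupancy
  nt <- trace$n_cycles
  if (correction == "half_cycle") {
    occ_t <- (occ[1:nt, , drop = FALSE] + occ[2:(nt + 1), , drop = FALSE]) / 2
  } else {
    occ_t <- occ[2:(nt + 1), , drop = FALSE]
  }
  disc <- (1 + rate)^(-(seq_len(nt)) * cl)
  alive <- 1 - occ_t[, dead_index(space)]
  u <- space$states$utility
  cc <- space$states$cost_per_cycle
  structure(
    list(
      therapy_id = therapy_id,
      life_years = sum(disc * cl * alive),
      qalys = sum(disc * cl * as.vector(occ_t %*% u)),
      state_costs = sum(disc * as.vector(occ_t %*% cc)),
      rate = rate,
      correction = correction
    ),
    class = "effect_summary"
  )
}

#' @export
print.effect_summary <- function(x, ...) {
  cat(sprintf("Effects%s: %.4f life-years, %.4f QALYs (rate %.1f%%)\n",
              if (is.na(x$therapy_id)) "" else paste0(" [", x$therapy_id, "]"),
              x$life_years, x$qalys, 100 * x$rate))
  invisible(x)
}

#' Individual-level microsimulation of the same Markov chain
#'
#' Monte-Carlo first-order walk of `n_individuals` through the chain,
#' returning mean discounted life-years and QALYs. Serves as a stochastic
#' cross-check of the deterministic cohort engine: means converge to the
#' cohort values as `n_individuals` grows.
#'
#' @param space A `state_space`.
#' @param m Transition matrix.
#' @param init Initial distribution (individuals are sampled from it).
#' @param n_individuals Number of simulated individuals (>= 1).
#' @param n_cycles Number of cycles.
#' @param seed Mandatory integer seed; the global RNG state is saved and
#'   restored.
#' @param rate Annual discount rate.
#' @param correction Half-cycle correction flag, as in
#'   [discounted_effects()].
#'
#' @return An `effect_summary` with additional elements `se_life_years` and
#'   `se_qalys` (standard errors of the means).
#' @export
microsimulate <- function(space, m, init = default_initial_distribution(space),
                          n_individuals = 1e4, n_cycles = 20L, seed,
                          rate = 0.035, correction = c("none", "half_cycle")) {
  correction <- match.arg(correction)
  if (missing(seed)) stop("an explicit seed is required")
  m <- validate_transitions(m, space)
  n_individuals <- as.integer(n_individuals)
  stopifnot(n_individuals >= 1L, n_cycles >= 1L)

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
  set.seed(seed)

  k <- n_states(space)
  cl <- space$cycle_length
  d <- dead_index(space)
  u <- space$states$utility
  disc <- (1 + rate)^(-(seq_len(n_cycles)) * cl)

  state <- sample.int(k, n_individuals, replace = TRUE, prob = init)
  ly <- numeric(n_individuals)
  qa <- numeric(n_individuals)
  for (t in seq_len(n_cycles)) {
    prev <- state
    nxt <- integer(n_individuals)
    for (s in unique(prev)) {
      idx <- which(prev == s)
      nxt[idx] <- sample.int(k, length(idx), replace = TRUE, prob = m[s, ])
    }
    state <- nxt
    if (correction == "half_cycle") {
      alive_t <- ((prev != d) + (state != d)) / 2
      u_t <- (u[prev] + u[state]) / 2
    } else {
      alive_t <- as.numeric(state != d)
      u_t <- u[state]
    }
    ly <- ly + disc[t] * cl * alive_t
    qa <- qa + disc[t] * cl * u_t
  }
  out <- structure(
    list(
      therapy_id = NA_character_,
      life_years = mean(ly),
      qalys = mean(qa),
      state_costs = NA_real_,
      rate = rate,
      correction = correction,
      se_life_years = stats::sd(ly) / sqrt(n_individuals),
      se_qalys = stats::sd(qa) / sqrt(n_individuals)
    ),
    class = "effect_summary"
  )
  out
}
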