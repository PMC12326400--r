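# Independent reference computations used to cross-check the package.

# Brute-force cohort trace: the occupancy at cycle t is init %*% m^t, with
# the matrix power rebuilt from scratch by repeated multiplication.
oracle_trace <- function(m, init, n_cycles) {
  k <- length(init)
  occ <- matrix(NA_real_, n_cycles + 1L, k)
  occ[1L, ] <- init
  for (t in seq_len(n_cycles)) {
    p <- diag(k)
    for (s in seq_len(t)) p <- p %*% m
    occ[t + 1L, ] <- as.vector(init %*% p)
  }
  occ
}

# Exhaustive frontier membership: a strategy is on the frontier iff no
# single alternative strictly dominates it and no convex combination of two
# alternatives yields its effect at strictly lower cost.
oracle_frontier_ids <- function(results, measure = "qalys") {
  cost <- results$total_cost
  eff <- results[[measure]]
  n <- length(cost)
  keep <- vapply(seq_len(n), function(i) {
    for (j in seq_len(n)) {
      if (j == i) next
      if (cost[j] <= cost[i] && eff[j] >= eff[i] &&
          (cost[j] < cost[i] || eff[j] > eff[i])) {
        return(FALSE)
      }
    }
    for (j in seq_len(n)) {
      for (k in seq_len(n)) {
        if (j == i || k == i || j == k) next
        if (eff[j] < eff[i] && eff[i] < eff[k]) {
          lam <- (eff[i] - eff[j]) / (eff[k] - eff[j])
          interp <- cost[j] + lam * (cost[k] - cost[j])
          if (interp < cost[i] - 1e-9) return(FALSE)
        }
      }
    }
    TRUE
  }, logical(1))
  sort(results$therapy_id[keep])
}

# Minimal two-state space (alive with utility u, dead) used across tests.
two_state_space <- function(u = 1, cost = 0) {
  build_state_space(rbind(
    health_state("alive", "on_treatment", u, cost),
    health_state("dead", "dead", 0, 0)
  ))
}

two_state_matrix <- function(p_death) {
  matrix(c(1 - p_death, p_death, 0, 1), nrow = 2, byrow = TRUE,
         dimnames = list(c("alive", "dead"), c("alive", "dead")))
}

# Random therapy_results cloud for dominance/frontier property tests.
random_results <- function(n, seed) {
  set.seed(seed)
  therapy_results(
    therapy_id = paste0("t", seq_len(n)),
    total_cost = runif(n, 1e3, 3e5),
    life_years = runif(n, 4, 10),
    qalys = runif(n, 1, 5)
  )
}
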