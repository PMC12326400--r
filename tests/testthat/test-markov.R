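test_that("transition validation accepts valid matrices and names each defect", {
  sp <- two_state_space()
  m <- two_state_matrix(0.5)
  expect_identical(validate_transitions(m, sp), m)

  id2 <- diag(2); dimnames(id2) <- dimnames(m)
  expect_identical(validate_transitions(id2, sp), id2)

  bad_sum <- matrix(c(0.6, 0.3, 0, 1), 2, byrow = TRUE)
  expect_error(validate_transitions(bad_sum, sp), "not summing to 1")

  neg <- matrix(c(1.1, -0.1, 0, 1), 2, byrow = TRUE)
  expect_error(validate_transitions(neg, sp), "negative")

  not_abs <- matrix(c(0.5, 0.5, 0.1, 0.9), 2, byrow = TRUE)
  expect_error(validate_transitions(not_abs, sp), "absorbing")

  expect_error(validate_transitions(diag(3), sp), "2 states")
})

test_that("cohort in the dead state stays there with zero life-years", {
  sp <- two_state_space()
  tr <- run_cohort(sp, two_state_matrix(0.3), init = c(0, 1), n_cycles = 10)
  expect_true(all(tr$occupancy[, "dead"] == 1))
  eff <- discounted_effects(tr, rate = 0)
  expect_equal(eff$life_years, 0)
  expect_equal(eff$qalys, 0)
})

test_that("alive occupancy decays geometrically under constant death probability", {
  sp <- two_state_space()
  tr <- run_cohort(sp, two_state_matrix(0.5), init = c(1, 0), n_cycles = 12)
  expect_equal(unname(tr$occupancy[, "alive"]), 0.5^(0:12), tolerance = 1e-12)
})

test_that("cohort engine equals the explicit matrix-power oracle", {
  # 3-state chain with a fully specified matrix, 4 cycles
  sp3 <- build_state_space(rbind(
    health_state("mild", "on_treatment", 0.8),
    health_state("severe", "on_treatment", 0.4),
    health_state("dead", "dead", 0, 0)
  ))
  m3 <- matrix(c(0.70, 0.20, 0.10,
                 0.05, 0.75, 0.20,
                 0.00, 0.00, 1.00), 3, byrow = TRUE)
  init3 <- c(0.9, 0.1, 0)
  tr <- run_cohort(sp3, m3, init3, n_cycles = 4)
  expect_equal(unname(tr$occupancy), oracle_trace(m3, init3, 4),
               tolerance = 1e-12)

  # random 5-state scenario
  sc <- generate_scenario(scenario_spec(seed = 42, n_states = 5))
  tr5 <- run_cohort(sc$space, sc$matrix, sc$init, n_cycles = 7)
  expect_equal(unname(tr5$occupancy), oracle_trace(sc$matrix, sc$init, 7),
               tolerance = 1e-12)
})

test_that("mass is conserved and death occupancy is monotone across random scenarios", {
  for (seed in 1:25) {
    sc <- generate_scenario(scenario_spec(seed = seed,
                                          n_states = 2 + seed %% 7))
    tr <- run_cohort(sc$space, sc$matrix, sc$init, n_cycles = 15)
    expect_true(all(abs(rowSums(tr$occupancy) - 1) < 1e-9))
    dead <- tr$occupancy[, ncol(tr$occupancy)]
    expect_true(all(diff(dead) >= -1e-12))
  }
})

test_that("constant-alive chain reproduces the annuity discount formula", {
  sp <- two_state_space(u = 1)
  id2 <- diag(2)
  tr <- run_cohort(sp, id2, init = c(1, 0), n_cycles = 5)
  eff0 <- discounted_effects(tr, rate = 0)
  expect_equal(eff0$life_years, 5)
  expect_equal(eff0$qalys, 5)

  eff <- discounted_effects(tr, rate = 0.035)
  annuity <- sum(1.035^-(1:5))
  expect_equal(eff$life_years, annuity, tolerance = 1e-12)
  expect_equal(eff$qalys, annuity, tolerance = 1e-12)
  expect_equal(annuity, 4.51505, tolerance = 1e-5)
})

test_that("effects decrease with the discount rate and QALYs never exceed life-years", {
  for (seed in c(3, 11, 27)) {
    sc <- generate_scenario(scenario_spec(seed = seed, n_states = 6))
    tr <- run_cohort(sc$space, sc$matrix, sc$init, n_cycles = 20)
    e0 <- discounted_effects(tr, rate = 0)
    e35 <- discounted_effects(tr, rate = 0.035)
    e60 <- discounted_effects(tr, rate = 0.06)
    expect_true(e0$life_years > e35$life_years)
    expect_true(e35$life_years > e60$life_years)
    expect_true(e0$qalys > e35$qalys)
    for (e in list(e0, e35, e60)) expect_lte(e$qalys, e$life_years)
  }
})

test_that("half-cycle correction averages adjacent occupancies", {
  sp <- two_state_space()
  tr <- run_cohort(sp, two_state_matrix(0.4), init = c(1, 0), n_cycles = 6)
  rate <- 0.035
  disc <- (1 + rate)^-(1:6)
  alive <- 0.6^(0:6)
  expected_none <- sum(disc * alive[2:7])
  expected_half <- sum(disc * (alive[1:6] + alive[2:7]) / 2)
  expect_equal(discounted_effects(tr, rate)$life_years, expected_none,
               tolerance = 1e-12)
  expect_equal(discounted_effects(tr, rate, "half_cycle")$life_years,
               expected_half, tolerance = 1e-12)
  expect_gt(expected_half, expected_none)
})

test_that("sub-annual cycles discount by elapsed years", {
  sp <- build_state_space(rbind(
    health_state("alive", "on_treatment", 1),
    health_state("dead", "dead", 0, 0)
  ), cycle_length = 1 / 12)
  tr <- run_cohort(sp, diag(2), init = c(1, 0), n_cycles = 24)
  eff <- discounted_effects(tr, rate = 0.035)
  expected <- sum(1.035^-((1:24) / 12) / 12)
  expect_equal(eff$life_years, expected, tolerance = 1e-12)
})

test_that("tidy trace export round-trips through CSV", {
  sp <- two_state_space()
  tr <- run_cohort(sp, two_state_matrix(0.5), init = c(1, 0), n_cycles = 3)
  df <- as.data.frame(tr)
  expect_named(df, c("cycle", "state_id", "occupancy"))
  expect_equal(nrow(df), 4 * 2)
  f <- tempfile(fileext = ".csv")
  write_trace_csv(tr, f)
  back <- read.csv(f, stringsAsFactors = FALSE)
  expect_equal(back$occupancy, df$occupancy)
})

test_that("microsimulation matches the cohort engine", {
  sp <- two_state_space()
  # deterministic chain: everyone dies at the first cycle
  ms <- microsimulate(sp, two_state_matrix(1), init = c(1, 0),
                      n_individuals = 50, n_cycles = 5, seed = 7, rate = 0.035)
  tr <- run_cohort(sp, two_state_matrix(1), init = c(1, 0), n_cycles = 5)
  expect_equal(ms$life_years, discounted_effects(tr, 0.035)$life_years,
               tolerance = 1e-12)

  # stochastic chain: mean within 3 standard errors of the cohort value
  m <- two_state_matrix(0.5)
  tr2 <- run_cohort(sp, m, init = c(1, 0), n_cycles = 30)
  cohort <- discounted_effects(tr2, rate = 0.035)
  ms2 <- microsimulate(sp, m, init = c(1, 0), n_individuals = 1e5,
                       n_cycles = 30, seed = 11, rate = 0.035)
  expect_lt(abs(ms2$life_years - cohort$life_years), 3 * ms2$se_life_years)

  # reproducibility and seed requirement
  ms3 <- microsimulate(sp, m, init = c(1, 0), n_individuals = 1000,
                       n_cycles = 10, seed = 99)
  ms4 <- microsimulate(sp, m, init = c(1, 0), n_individuals = 1000,
                       n_cycles = 10, seed = 99)
  expect_identical(ms3$life_years, ms4$life_years)
  expect_error(microsimulate(sp, m, n_individuals = 10, n_cycles = 2),
               "seed")
})

test_that("microsimulation leaves the global RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(microsimulate(two_state_space(), two_state_matrix(0.5),
                          init = c(1, 0), n_individuals = 100,
                          n_cycles = 5, seed = 1))
  expect_identical(.Random.seed, before)
})
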