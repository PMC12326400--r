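test_that("average ratios are exact divisions and reproduce the ratio identity", {
  r <- therapy_results("dacepton", 20782 * 2.885, 6.385, 2.885)
  ar <- average_ratios(r)
  expect_equal(ar$acur_qaly, 20782)
  expect_equal(ar$acer_ly * ar$life_years, ar$total_cost, tolerance = 1e-9)
  expect_equal(ar$acur_qaly * ar$qalys, ar$total_cost, tolerance = 1e-9)

  r2 <- therapy_results("lecigon", 324480, 7.055, 3.120)
  expect_equal(average_ratios(r2)$acur_qaly, 104000)

  r0 <- therapy_results("free", 0, 6.385, 2.885)
  ar0 <- average_ratios(r0)
  expect_equal(ar0$acer_ly, 0)
  expect_equal(ar0$acur_qaly, 0)
})

test_that("published ratio cells are internally consistent only to ~0.5%", {
  # ACE x LY and ACU x QALY imply the same total cost up to printed rounding
  fx <- pd_therapy_fixture()
  pr <- fx$printed_ratios
  eff <- fx$effects[match(pr$therapy_id, fx$effects$therapy_id), ]
  tot_ly <- pr$ace_printed * eff$life_years
  tot_q <- pr$acu_printed * eff$qalys
  rel <- abs(tot_ly - tot_q) / tot_q
  expect_true(all(rel < 0.005))
  expect_gt(max(rel), 1e-4)  # not exactly consistent
})

test_that("incremental ratio follows the incremental cost over incremental effect formula", {
  a <- therapy_results("a", 1100, 6, 3.5)
  b <- therapy_results("b", 1000, 5.5, 3.0)
  expect_equal(icer(a, b)$value, 100 / 0.5)
  expect_equal(icer(a, b, "life_years")$value, 100 / 0.5)
  # sign symmetry when defined
  expect_equal(icer(a, b)$value, icer(b, a)$value)
})

test_that("degenerate comparisons return dominance sentinels", {
  dac <- therapy_results("dacepton", 59956.07, 6.385, 2.885)
  apo <- therapy_results("apo_go", 79669.27, 6.385, 2.885)
  # equal QALYs, higher cost: the cheaper option dominates
  expect_equal(icer(apo, dac)$sentinel, "b_dominates")
  expect_equal(icer(dac, apo)$sentinel, "a_dominates")
  expect_true(is.na(icer(apo, dac)$value))
  # identical options
  expect_equal(icer(dac, dac)$sentinel, "cost_comparison")
  # strictly better on both axes
  good <- therapy_results("g", 100, 7, 3)
  bad <- therapy_results("h", 200, 6, 2)
  expect_equal(icer(good, bad)$sentinel, "a_dominates")
})

test_that("dominance on the seven-therapy bundle labels the reference-dominated trio and more", {
  it <- implied_totals()
  cls <- dominance_classify(it, measure = "qalys")
  lab <- setNames(cls$dominance, cls$therapy_id)

  # dominated by the reference (the published statement)
  expect_equal(dominated_by_reference(it, "dacepton"),
               c("apo_go", "percept_pc", "percept_rc"))

  # full pairwise dominance additionally exposes Duodopa and Lecigon as
  # strictly dominated by Foslevodopa (cheaper implied total, more QALYs)
  expect_equal(unname(lab["duodopa"]), "dominated")
  expect_equal(unname(lab["lecigon"]), "dominated")
  expect_equal(unname(lab[c("dacepton", "foslevodopa")]),
               c("nondominated", "nondominated"))
  expect_equal(unname(lab[c("apo_go", "percept_pc", "percept_rc")]),
               rep("dominated", 3))
})

test_that("dominance labels are invariant to input order and cost scaling", {
  it <- implied_totals()
  base <- dominance_classify(it)
  lab <- setNames(base$dominance, base$therapy_id)

  set.seed(1)
  perm <- sample(nrow(it))
  shuffled <- dominance_classify(it[perm, ])
  expect_equal(setNames(shuffled$dominance, shuffled$therapy_id)[names(lab)],
               lab)

  scaled <- it
  scaled$total_cost <- scaled$total_cost * 3.7
  rescaled <- dominance_classify(scaled)
  expect_equal(setNames(rescaled$dominance, rescaled$therapy_id)[names(lab)],
               lab)
})

test_that("identical therapies tie as nondominated with a warning", {
  twins <- therapy_results(c("a", "b"), c(100, 100), c(5, 5), c(2, 2))
  expect_warning(cls <- dominance_classify(twins), "identical")
  expect_equal(cls$dominance, c("nondominated", "nondominated"))
  expect_error(dominance_classify(therapy_results("a", 1, 1, 1)), "at least 2")
  dup <- rbind(twins, twins[1, ])
  expect_error(dominance_classify(dup), "duplicate")
})

test_that("collinear middle point is kept on the frontier", {
  col3 <- therapy_results(c("a", "b", "c"), c(100, 200, 300), c(4, 5, 6),
                          c(1, 2, 3))
  cls <- dominance_classify(col3)
  expect_equal(cls$dominance, rep("nondominated", 3))
  fr <- efficiency_frontier(col3)
  expect_equal(fr$therapy_id, c("a", "b", "c"))
  expect_equal(fr$icer_stepwise, c(NA, 100, 100))
})

test_that("extended dominance removes interior points above the hull", {
  # b's incremental ratio vs a (400) exceeds c's vs b (50): b is bypassed
  r <- therapy_results(c("a", "b", "c"), c(100, 500, 550), c(4, 5, 6),
                       c(1, 2, 3))
  cls <- dominance_classify(r)
  expect_equal(setNames(cls$dominance, cls$therapy_id)[["b"]],
               "extended_dominated")
  fr <- efficiency_frontier(r)
  expect_equal(fr$therapy_id, c("a", "c"))
  expect_equal(fr$icer_stepwise, c(NA, 450 / 2))
})

test_that("frontier matches the exhaustive oracle on random clouds", {
  for (seed in 1:30) {
    res <- random_results(n = 3 + seed %% 6, seed = seed)
    fr <- efficiency_frontier(res, "qalys")
    expect_equal(sort(fr$therapy_id), oracle_frontier_ids(res, "qalys"),
                 info = paste("seed", seed))
    steps <- fr$icer_stepwise[-1]
    expect_true(all(diff(steps) > 0 | length(steps) < 2))
  }
})

test_that("single therapy yields a frontier with no incremental ratio", {
  one <- therapy_results("only", 100, 5, 2)
  fr <- efficiency_frontier(one)
  expect_equal(fr$therapy_id, "only")
  expect_true(is.na(fr$icer_stepwise))
})

test_that("willingness-to-pay classification respects band edges and monotonicity", {
  band <- wtp_band(22000, 25000, 60000)
  expect_equal(as.character(wtp_classify(104000, band)), "above_special")
  expect_equal(as.character(wtp_classify(20782, band)), "below_lower")
  expect_equal(as.character(wtp_classify(25000, band)), "within_band")
  expect_equal(as.character(wtp_classify(22000, band)), "below_lower")
  expect_equal(as.character(wtp_classify(60000, band)),
               "above_band_below_special")

  vals <- sort(runif(50, 0, 2e5))
  cls <- wtp_classify(vals, band)
  expect_true(all(diff(as.integer(cls)) >= 0))

  expect_error(wtp_band(30000, 25000, 60000), "band")
})

test_that("cost-utility plane coordinates are anchored at the reference", {
  it <- implied_totals()
  pl <- ce_plane_coordinates(it, "dacepton")
  ref <- pl[pl$therapy_id == "dacepton", ]
  expect_equal(ref$delta_effect, 0)
  expect_equal(ref$delta_cost, 0)

  apo <- pl[pl$therapy_id == "apo_go", ]
  expect_equal(apo$delta_effect, 0)  # same utility, on the vertical axis
  expect_gt(apo$delta_cost, 0)

  # quadrant signs agree with the dominance labels vs the reference
  dominated <- dominated_by_reference(it, "dacepton")
  for (th in dominated) {
    row <- pl[pl$therapy_id == th, ]
    expect_true(row$delta_cost > 0 && row$delta_effect <= 0)
  }
  for (th in c("duodopa", "foslevodopa", "lecigon")) {
    row <- pl[pl$therapy_id == th, ]
    expect_true(row$delta_cost > 0 && row$delta_effect > 0)
  }
  expect_error(ce_plane_coordinates(it, "nope"), "not found")
})

test_that("net monetary benefit is linear in the threshold", {
  it <- implied_totals()
  nmb <- net_monetary_benefit(it, 25000)
  expect_equal(unname(nmb["dacepton"]), 25000 * 2.885 - 59956.07,
               tolerance = 1e-9)
  # at any threshold a strictly dominated option has lower NMB than its dominator
  for (lam in c(0, 25000, 60000)) {
    n <- net_monetary_benefit(it, lam)
    expect_gt(n[["dacepton"]], n[["apo_go"]])
    expect_gt(n[["foslevodopa"]], n[["duodopa"]])
  }
})
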