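#!/usr/bin/env Rscript

# Step 2 — Markov model calibration to the published effect totals.
#
# The source analysis reports discounted life-years and QALYs per therapy
# but no transition probabilities. For each therapy this step recovers a
# 12-state transition matrix (per-cycle mortality solved by root-finding)
# and a utility map (profile rescaled so QALYs match), then verifies the
# calibrated scenario by an independent seeded microsimulation.

suppressPackageStartupMessages(library(pdcea))
dir.create("results", showWarnings = FALSE)

fx <- pd_therapy_fixture()
rows <- lapply(fixture_targets(fx), function(tg) {
  cal <- calibrate(tg)
  ms <- microsimulate(cal$space, cal$matrix, cal$init,
                      n_individuals = 2e4, n_cycles = 20, seed = 1,
                      rate = cal$rate)
  data.frame(
    therapy_id = tg$therapy_id,
    target_life_years = tg$life_years,
    target_qalys = tg$qalys,
    mortality_per_cycle = cal$params$mortality,
    utility_scale = cal$params$utility_scale,
    achieved_life_years = cal$effects$life_years,
    achieved_qalys = cal$effects$qalys,
    microsim_life_years = ms$life_years,
    microsim_se = ms$se_life_years,
    stringsAsFactors = FALSE
  )
})
calib <- do.call(rbind, rows)

cat("Calibrated per-cycle mortality and utility scale per therapy:\n")
print(calib, row.names = FALSE, digits = 6)

stopifnot(abs(calib$achieved_life_years - calib$target_life_years) /
            calib$target_life_years < 0.01,
          abs(calib$microsim_life_years - calib$achieved_life_years) <
            4 * calib$microsim_se)
cat("\nAll therapies calibrated within 1% of their targets;",
    "microsimulation agrees with the cohort engine.\n")
cat(sprintf(
  "Foslevodopa needs the lowest mortality (%.4f/cycle) to reach %.3f LY;\n",
  calib$mortality_per_cycle[calib$therapy_id == "foslevodopa"],
  calib$target_life_years[calib$therapy_id == "foslevodopa"]))
cat(sprintf(
  "the DBS strategies pair longer survival (%.3f LY) with lower utility (%.3f QALY).\n",
  calib$target_life_years[calib$therapy_id == "percept_pc"],
  calib$target_qalys[calib$therapy_id == "percept_pc"]))

utils::write.csv(calib, "results/calibration.csv", row.names = FALSE)
cat("Wrote results/calibration.csv\n")
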