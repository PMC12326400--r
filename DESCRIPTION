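Package: pdcea
Title: Cost-Utility Analysis of Device-Aided Therapies in Advanced Parkinson's
    Disease
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Markov cohort cost-utility modelling for device-aided therapies
    in advanced Parkinson's disease from the perspective of the Spanish
    National Health System. Provides a validated cohort state-transition
    engine with discounted accumulation of life-years and QALYs,
    resource-based costing of clinical pathways and drug regimens,
    incremental cost-effectiveness and cost-utility ratios, dominance and
    efficiency-frontier analysis, willingness-to-pay classification, and a
    calibration module that reconstructs per-therapy transition matrices and
    utility maps from published aggregate effect totals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
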