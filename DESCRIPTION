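Package: ovatriage
Title: Cost-Effectiveness Modelling of Risk-Based Ovarian Cancer Triage in Primary Care
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic evaluation of primary-care triage pathways for
    suspected ovarian cancer. A diagnostic decision tree combines CA125-based
    tests (single cut-off, Ovatools risk thresholds, or age-adjusted CA125
    equivalents) with pelvic ultrasound, sequentially or concurrently, and
    feeds a five-state lifetime Markov cohort model of survival, quality of
    life and hospital costs. The package computes detection and referral
    rates, discounted QALYs and costs per 1000 women, incremental
    cost-effectiveness ratios with (extended) dominance pruning,
    probabilistic sensitivity analyses with cost-effectiveness acceptability
    curves, and two-way sweeps over Ovatools risk thresholds via a binormal
    ROC interpolation. Ships a calibrated synthetic parametrization
    (survival, life table, cost curves, utility model) so the full pipeline
    runs without access to the source registry data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
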