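Package: strabnet
Title: Multi-Task Learning Planner for Horizontal Strabismus Surgery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint prediction of which horizontal extra-ocular muscles to
    operate (8-label muscle-procedure selection) and the recession/resection
    dose for each (8-output regression, mm) from routine pre-operative
    measurements, via a shared-trunk multi-task neural network. Includes a
    synthetic cohort simulator calibrated to published baseline statistics of
    a 634-patient strabismus surgery cohort, leakage-free winsorisation and
    standardisation, multilabel-stratified k-fold cross-validation with a
    prevalence-tolerance certificate, temperature and beta probability
    calibration with expected-calibration-error diagnostics, MCC-optimal
    per-label decision thresholds with feasibility conflict resolution, and a
    full evaluation suite (discrimination, dose accuracy, Bland-Altman
    agreement, plan-agreement tiers, decision-curve analysis, subgroup
    fairness, permutation feature importance) with bootstrap confidence
    intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
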