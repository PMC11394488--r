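Package: damil
Title: Dual-Attention Multiple-Instance Learning for Whole-Slide Recurrence Prediction
Version: 0.1.0
Authors@R:
    person("Damil", "Maintainers", email = "maintainers@damil.dev", role = c("aut", "cre"))
Description: Weakly supervised pipeline for predicting five-year cancer
    recurrence from whole-slide images. Provides tissue detection and patch-grid
    enumeration, tumor-bulk mask refinement, leverage-score key-set construction,
    a dual-attention (cross-attention plus gated-attention) multiple-instance
    aggregator with its training protocol, patient-level stratified
    cross-validation, and Cox proportional-hazards / Kaplan-Meier risk
    stratification. Ships a synthetic-data module (embedding bags, survival
    outcomes, toy slides with ground truth) so the full pipeline runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
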