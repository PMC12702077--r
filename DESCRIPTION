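Package: glycalibr
Title: Validation and Recalibration of Glycaemic Treatment Selection Models
    Across Ethnicity Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to externally validate a two-drug (SGLT2-inhibitor versus
    DPP4-inhibitor) glycaemic treatment selection model in observational
    cohorts, stratified by ethnicity group. Implements the closed testing
    procedure for model updating (no update, intercept recalibration, or
    intercept-and-slope recalibration), decile-level calibration of predicted
    differential treatment effects using covariate-adjusted arm contrasts with
    restricted cubic splines, and clinical-threshold subgroup summaries of
    glycaemic response, weight change and treatment discontinuation. Includes
    a synthetic observational cohort generator with planted ground truth
    (confounding by indication, per-group intercept shifts, outcome-window
    decoy records) so every stage of the pipeline can be checked against a
    known answer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
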