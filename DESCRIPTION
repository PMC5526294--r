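Package: seropanel
Title: Discovery and Validation of Blood Protein Panel Classifiers for
    Symptomatic Colorectal Cancer Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for developing and validating
    blood-based diagnostic classifiers from multiplexed immunoassay
    panels in an intent-to-test symptomatic population. Provides a
    synthetic cohort and plate generator with AUC-calibrated effect
    sizes, plate- and sample-level immunoassay quality control
    (four-parameter logistic standard curves with 1/y^2 weighting,
    Hill-slope and R^2 acceptance, duplicate-CV filtering, limits of
    quantitation), feature engineering with concentration ratios,
    grid-search classifier discovery under repeated stratified
    cross-validation, exhaustive optimization of indeterminate
    (gray-zone) score ranges, and locked-model validation statistics
    (ROC/AUC with DeLong inference, Clopper-Pearson intervals,
    Fisher's exact test, prevalence-adjusted predictive values, and
    stage-stratified sensitivity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    glmnet,
    ranger,
    e1071,
    xgboost,
    class,
    minpack.lm,
    MASS,
    jsonlite,
    yaml,
    readr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
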