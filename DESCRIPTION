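Package: scancombat
Title: ComBat Harmonization and Travelling-Subject Validation for
    Multi-Scanner Imaging Feature Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Feature-level harmonization of multi-scanner MRI-derived
    measurements (regional volumes, cortical thickness, diffusion metrics)
    using the ComBat family of empirical-Bayes location-scale models:
    cross-sectional ComBat, longitudinal ComBat with subject-level random
    effects, and a variant with penalized-spline covariate adjustment.
    Includes a travelling-subject cohort simulator with known ground truth,
    scanner-effect quantification via scan-rescan coefficients of variation,
    intra-class correlation agreement of annualized rates of change, and a
    false-positive-rate engine based on repeated random group assignment
    with mixed-model tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    mgcv,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
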