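Package: wristmets
Title: Energy Expenditure Prediction from Wrist-Worn Tri-Axial Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Estimates physical-activity energy expenditure (METs) from raw
    wrist-worn tri-axial accelerometer recordings. Implements the full
    treadmill-validated pipeline: Kalman smoothing, trailing-window gravity
    detrending and vector-magnitude computation; fixed-window summary-feature
    extraction with min-max normalization; closed-form Mean-to-METs regression
    predictors (linear, logarithmic, cubic) with published reference
    coefficients; a single-hidden-layer neural-network regressor with weight
    decay; and a two-stage model that first classifies each window as walking
    or running by a ROC/Youden cut-point on the window Mean and then applies a
    gait-specific network. Includes RMSE, Bias and Bland-Altman agreement
    evaluation with per-gait and per-speed breakdowns, and a synthetic
    treadmill-protocol data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    withr
Suggests:
    nnet,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
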