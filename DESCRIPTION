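Package: panicledyn
Title: Panicle Coverage Dynamics and Yield Prediction from Canopy Image Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying rice reproductive development from nadir
    RGB canopy imagery. Generates synthetic canopy images, panicle masks,
    coverage time series and yield-component tables for testing; prepares
    labeled image datasets (tiling, photometric and scale augmentation,
    source-level train/validation/test splits); scores binary panicle
    segmentations (pixel accuracy, precision, recall, F1, IoU, mIoU);
    extracts per-plot panicle-coverage fractions through a pluggable
    segmenter with nine-tile averaging; fits a piecewise
    sigmoid-growth/quadratic-decline model to coverage time series by
    bounded nonlinear least squares to obtain five dynamic parameters
    (K, g, d0, a, d1); and relates those parameters to yield components
    via Pearson correlation screens, leave-one-out cross-validated
    regression (PLSR, random forest, gradient boosting, XGBoost) and
    exact Shapley feature attribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    minpack.lm,
    mixOmics,
    png,
    purrr,
    randomForest,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
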