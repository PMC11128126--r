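Package: nircal
Title: Near-Infrared Calibration Pipeline for Rubber Content in Dandelion Roots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A chemometric workflow for predicting natural-rubber content in
    dried Taraxacum kok-saghyz (rubber dandelion) roots from near-infrared
    diffuse-reflectance spectra (850-2500 nm). Provides Monte-Carlo-subsampling
    outlier screening, SPXY/Kennard-Stone sample-set partitioning, spectral
    pretreatments (moving-window smoothing, standard normal variate,
    multiplicative scatter correction, first derivative), competitive adaptive
    reweighted sampling (CARS) wavelength selection, calibration by partial
    least squares, random forest, leaf-wise gradient-boosted trees and a
    one-dimensional convolutional network, and stratified evaluation
    (R2, RMSE, RPD, high-content RMSEP). Includes a synthetic-spectra
    generator emulating the statistical structure of dried-root NIR data so
    the whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    mixOmics,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
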