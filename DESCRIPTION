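Package: capnopred
Title: Pulmonary Function Prediction from Volumetric Capnography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Predicts spirometric pulmonary function parameters (FEV1 and
    FVC, in liters) from single-breath volumetric capnography. Implements
    capnogram phase segmentation and feature extraction (phase II/III
    slopes, phase volumes, transition angle), a two-level medical-feature
    regression structure (margin classifier at the FEV1/FVC = 0.7 airflow
    limitation cutoff, sigmoid probabilization, feature fusion, gradient
    boosted trees), a one-dimensional convolutional network over the raw
    CO2 time series, and a K-nearest-neighbor error-correction stage that
    combines both structures in a four-dimensional prediction space.
    Includes an adaptive exponential-smoothing controller for sampling
    flow, a composite percentage-error metric family (MPE, MAPE, RMSPE,
    CPE, ACC), a repeated stratified 10-fold cross-validation harness,
    and a synthetic cohort generator so the full pipeline can be
    exercised and tested without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    Rcpp,
    stats,
    utils,
    xgboost
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
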