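Package: afdetect1d
Title: Atrial Fibrillation Detection from Single-Lead ECG with a 1D
    Convolutional Neural Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end detection of atrial fibrillation in variable-length
    single-lead electrocardiogram recordings. Implements histogram-based
    length normalization (overlapping chopping of long records, periodic
    tiling of short ones), a ten-block one-dimensional convolutional neural
    network with batch normalization and pooling variants, an analytic
    per-layer shape and parameter calculator, Adam-based training with
    dropout, stratified K-fold cross-validation, four-class F1 evaluation,
    and exhaustive hyperparameter grid search. Ships a synthetic ECG
    generator so the whole pipeline is testable at desk scale, plus readers
    for PhysioNet/CinC Challenge 2017 style record files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    arrow,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
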