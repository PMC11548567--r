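Package: pulmosound
Title: Lung Sound Classification with a One-Dimensional Convolutional
    Neural Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for four-class respiratory sound classification
    (normal, crackle, wheeze, both) from annotated breathing-cycle
    recordings in the ICBHI 2017 layout. Provides a seedable synthetic
    lung-sound generator, WAV and annotation readers with dataset census
    statistics, a preprocessing pipeline (resampling, cycle extraction,
    length normalisation, spectrogram screening, stratified splitting),
    a from-scratch SMOTE oversampler, a declarative 1D convolutional
    network with an exact shape and parameter-count calculator and a
    compiled training engine, plus grid-search tuning, stratified k-fold
    cross-validation and confusion-matrix evaluation reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
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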