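Package: sleepwave
Title: Sleep Stage Classification from EEG Scalograms with a Compact
    Convolutional Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for automatic sleep staging from
    electroencephalography (EEG): powerline-notch and Butterworth bandpass
    preprocessing, 30-second epoch segmentation, bump-wavelet continuous
    wavelet transform rendered as 64x64 RGB scalogram images, a compact
    19-layer convolutional neural network trained with Adam, and
    confusion-matrix evaluation with stratified splits and k-fold
    cross-validation. Includes a synthetic polysomnography-like EEG
    generator with stage-dependent band power so the whole pipeline is
    testable without clinical recordings, plus EDF and plain-text I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
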