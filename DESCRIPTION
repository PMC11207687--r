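Package: vimsnet
Title: Phase-Locking Connectivity and CNN-LSTM Classification of Motion
    Sickness EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects visually induced motion sickness (VIMS) states from
    multichannel EEG. Implements the full pipeline: EDF/BDF ingestion,
    zero-phase Butterworth preprocessing (band-pass, notch, downsampling,
    average re-reference), decomposition into the six canonical frequency
    bands, phase-locking-value (PLV) functional-connectivity matrices from
    Hilbert instantaneous phase, brain-network topology thresholding, and a
    convolutional-recurrent (CNN-LSTM) classifier of the resting, light and
    heavy sickness states with k-fold cross-validated evaluation. Includes
    a synthetic phase-coupled EEG generator with a closed-form von Mises
    synchrony oracle, so every stage is testable without access to clinical
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    igraph,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
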