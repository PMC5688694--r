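Package: eegdloc
Title: Quantitative EEG Discrimination of Focal and Diffuse Causes of
    Depressed Consciousness
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying the etiology of a depressed level of
    consciousness (DLOC) from multichannel scalp EEG. Implements the full
    analysis pipeline: bipolar montage construction, artifact-aware
    preprocessing (downsampling, per-channel normalization, zero-phase
    Chebyshev lowpass filtering), segmentation into non-overlapping trials
    and epochs, a 25-feature time-series suite (multivariate autoregressive
    eigenvalue features, moments, band powers, Hurst exponent, Hjorth
    complexity, auto-mutual information, bicorrelation, median frequency,
    autocorrelations, composite permutation entropy), PCA with
    cross-validated ROC importance ranking, linear support-vector-machine
    classification with strict subject-level train/test independence, and
    hard/soft accuracy evaluation. A synthetic 18-channel EEG cohort
    generator with focal-like and diffuse-like dynamical classes makes every
    stage testable without clinical recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    pracma,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
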