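Package: arousalseq
Title: Thalamocortical fMRI Dynamics at Behavioral Arousal Transitions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for fast-fMRI studies of spontaneous
    behavioral arousal: detects behavioral arousals from self-paced
    button-press logs with motion-based exclusion, removes time-varying
    cardiac and respiratory artifacts from region-of-interest BOLD
    timeseries by sliding-window phase regression, builds arousal-locked
    ensembles with 20-percent-of-maximum latencies and bootstrap
    confidence intervals, estimates a cross-nucleus temporal sequence by
    cross-correlation lags with flat and hierarchical bootstrap,
    corrects lags for vascular (breathhold) delay, fits a
    double-Gaussian hemodynamic response model for onset times, and
    computes multitaper EEG alpha power around arousal. Includes a
    synthetic session generator with recorded ground truth for every
    estimated quantity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    pracma,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
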