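Package: brainprint
Title: Privacy-Preserving EEG Biometric Authentication via Deep Fingerprints
Version: 0.1.0
Authors@R:
    person("brainprint", "developers", email = "brainprint@example.org",
           role = c("aut", "cre"))
Description: Tools for building and evaluating universal, privacy-preserving
    EEG-based authentication systems. Implements min-max channel
    normalization, Gram-Schmidt orthogonalization, sliding/sampling window
    augmentation, a compact configurable convolutional classifier whose
    feature layers serve as an irreversible EEG fingerprint ("EEG hash"),
    distance-threshold verification calibrated at the equal-error-rate
    operating point of a detection error trade-off curve, greedy orthogonal
    forward channel selection, and a synthetic multi-subject cohort
    generator for end-to-end open-set (unseen-subject) evaluation. Reads
    recordings from EDF (European Data Format) and plain text matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
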