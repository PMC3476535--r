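Package: eegmix
Title: Mixture ICA Source Analysis and Spectral Decoding of EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing high-density electroencephalography (EEG)
    recorded during lower-limb motor tasks. Implements maximum-likelihood
    mixtures of independent component analysis models with adaptive
    generalized-Gaussian source densities and posterior model probabilities,
    equivalent current dipole fitting in an analytic spherical head model,
    across-subject clustering of electrocortical sources, Morlet
    time-frequency analysis with linear time-warping and bootstrap
    significance masking of event-related desynchronization, and single-trial
    naive Bayes decoding of muscle-contraction type with cross-validated
    confusion matrices. Includes a synthetic-EEG generator emulating an
    isometric/isotonic knee/ankle exercise protocol for end-to-end validation,
    plus minimal EDF readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
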