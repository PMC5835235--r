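Package: eegclean
Title: Automated Artifact Removal and Data-Quality Reporting for Developmental EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automated preprocessing for continuous multichannel EEG
    recordings with high artifact load, such as developmental or clinical
    resting-state data. Implements 1 Hz high-pass (or 1-249 Hz band-pass)
    filtering, multitaper sinusoid-regression line-noise removal, two-pass
    joint-probability bad-channel detection, wavelet-enhanced independent
    component analysis (thresholding every component with a robust universal
    threshold), extended Infomax ICA with six-feature automated component
    rejection, optional segment rejection or per-segment channel repair,
    spherical-spline interpolation of bad channels, re-referencing, and a
    standardized per-file data-quality report. Ships a seeded synthetic EEG
    generator with sample-exact ground truth so every stage is testable
    without external data, plus readers and writers for EDF and a plain
    binary-matrix native format.
License: MIT
Encoding: UTF-8
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
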