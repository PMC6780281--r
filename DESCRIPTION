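Package: svwave
Title: Stroke Volume Estimation from Arterial Pressure Waveforms with a
    Calibrated 1-D Convolutional Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates beat-averaged stroke volume from 10.24-second windows
    of the radial arterial blood pressure waveform using a 1-D convolutional
    network whose scalar output is passed through a jointly trained
    per-patient affine calibration (individual scale coefficients). Includes
    a two-element Windkessel simulator of phase-structured surgical
    hemodynamics for fully synthetic end-to-end testing, sliding-window
    dataset construction with patient-level cohort splitting, and the full
    method-comparison toolbox used in hemodynamic monitoring studies:
    Pearson correlation with Fisher confidence intervals, Steiger's test for
    dependent correlations, Bland-Altman agreement, four-quadrant trend
    concordance with a central exclusion zone, and anesthesia
    performance-error metrics (MDPE, MDAPE, RMSE), all stratified by
    surgical phase.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
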