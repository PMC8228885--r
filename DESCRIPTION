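Package: respgate
Title: Respiratory Motion Estimation from Dual Inertial Sensor Nodes with
    Amplitude-Based Gating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates a respiratory motion waveform from two body-worn
    inertial measurement units (a sternum node and an abdomen node) by fusing a
    PCA-derived waveform-shape signal with a quaternion-orientation,
    double-integration position signal, and applies the result to
    amplitude-based gating of emission tomography data. Includes a synthetic
    breathing and sensor simulator for end-to-end validation, cycle-level
    comparison metrics against a reference respiration signal, quantile-based
    equidistant amplitude gating with cycle rejection, and volume-of-interest
    image quality metrics (contrast ratio, signal-to-noise ratio, coefficient
    of variation, contrast-to-noise ratio).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
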