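Package: cufflessbp
Title: Calibration-Free Cuffless Blood Pressure from Local Pulse Wave Velocity
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Signal-processing and hemodynamic-modelling toolkit for
    calibration-free cuffless blood pressure estimation from local pulse
    wave velocity measured on the radial artery.  Simulates dual-channel
    pulse waveforms with known ground truth, designs Kaiser-window FIR
    bandpass filters and Sallen-Key analog front-end stages, detects beats
    with a constant-memory dynamic-gradient peak/trough detector, computes
    beat-wise pulse transit time and pulse wave velocity over a fixed
    sensor separation, inverts the Moens-Korteweg relation with a
    pressure-dependent elastic modulus to mean arterial pressure, and
    evaluates device agreement with ISO 81060-2 statistics and
    Bland-Altman analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
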