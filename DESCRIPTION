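Package: sbftime
Title: Striatal Beat-Frequency Model of Interval Timing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for the striatal beat-frequency (SBF)
    model of interval timing. Provides a bank of cortical oscillators (sine-wave
    phase oscillators or conductance-based Morris-Lecar neurons with f-I
    calibration), a noisy reference memory encoding a criterion time over
    fixed-interval trials, and a coincidence-detector readout. Implements the
    closed-form output functions predicted for the noiseless circuit and for
    Gaussian noise in the memorized criterion time or in the oscillator
    frequencies, together with the peak, width and skewness metrics and the
    regressions used to establish time-scale invariance (the scalar property of
    interval timing). Includes reproducible experiment runners showing that
    scale invariance emerges from criterion-time noise and from frequency
    noise, but not from the noiseless circuit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    minpack.lm,
    pracma,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
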