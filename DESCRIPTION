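Package: scnwave
Title: Phase Waves and Synchronization in Circadian Oscillator Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of circadian phase waves in
    bioluminescence time-lapse recordings of the suprachiasmatic nucleus
    (SCN), and a three-dimensional lattice model of locally coupled phase
    oscillators that reproduces the wave.  Provides envelope-based
    extraction of per-pixel amplitude and phase (with a Hilbert-transform
    cross-check), the Kuramoto synchronization index R, the spatial
    phase-fluctuation statistic Delta, wave-velocity estimation, a
    synthetic-movie generator with known ground truth, and simulation
    experiments that estimate the critical coupling strength and map the
    robustness of synchronization against frequency heterogeneity,
    surface defects and dynamical noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
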