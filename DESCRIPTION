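Package: ringpam
Title: Simulation Workbench for Ring-Segment Detector Optical-Resolution
    Photoacoustic Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-simulation pipeline for optical-resolution photoacoustic
    (optoacoustic) microscopy with an axially extended optical focus and a
    spherically-focused ring-segment ultrasound detector.  Covers Monte-Carlo
    photon transport in voxelized vessel phantoms, 2D k-space pseudospectral
    acoustic propagation in water with quadratic power-law absorption,
    parametric ring-detector geometry with reception-field and
    aperture-sensitivity analysis, and A-scan signal processing (low-pass
    filtering, Hilbert envelope, nonlinear time-to-depth mapping and maximum
    intensity projections).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    signal,
    jsonlite,
    tiff,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: FFTW3 (libfftw3)
Config/testthat/edition: 3
NeedsCompilation: yes
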