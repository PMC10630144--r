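Package: dlao
Title: Deep-Learning Adaptive Optics for Single-Molecule Localization
    Microscopy, in Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A fully simulated closed-loop testbed for sensorless adaptive
    optics in single-molecule localization microscopy (SMLM). A scalar
    pupil-function model renders biplane single-molecule emission patterns
    under wavefront distortions expressed in an orthonormal mirror-mode
    (Zernike-derived) basis; a small convolutional neural network, trained
    on simulated emission patterns, regresses the shared mode amplitudes
    from sparse blinking detections; a per-mode Kalman filter fuses the
    estimates across correction cycles and drives a simulated deformable
    mirror with cross-coupling and stroke nonlinearity. Baselines include
    Gerchberg-Saxton phase retrieval from bead z-stacks and iterative
    metric-based adaptive optics, and evaluation tools provide 3D
    normalized cross-correlation, Poisson Fisher information with
    Cramer-Rao bounds for 3D localization, and convergence statistics for
    repeated compensation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    tiff
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
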