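Package: nitioce
Title: Skin Elasticity from Surface-Wave Anisotropy with a Nearly
    Incompressible Transversely Isotropic Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models skin as a nearly incompressible transversely isotropic
    (NITI) elastic solid and implements the computational chain of acoustic
    micro-tapping optical coherence elastography (OCE): assembly and validation
    of the NITI stiffness tensor and its engineering moduli, Christoffel-equation
    bulk-wave phase velocities, Rayleigh surface-wave speeds on a NITI half-space
    via the Stroh formalism, synthetic surface-wavefield generation with
    group-velocity estimation by arrival-time regression, four-parameter
    inversion of angle-resolved wave-speed scans with leave-one-out
    cross-validation, sliding-kernel local speed mapping, and a
    polarization-sensitive OCT optic-axis estimator based on sliding-window
    plane fits to Stokes trajectories on the Poincare sphere.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
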