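Package: fourpolar
Title: Four-Polarization 3D Orientation and Localization Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolbox for single-molecule orientation and
    localization microscopy (SMOLM) with a four-channel polarization splitter and
    numerical-aperture filtering. Implements a vectorial dipole-near-interface
    forward model of the four polarized point-spread functions, the linear map
    between second-order dipole moments and integrated channel intensities, its
    inversion to mean orientation (eta, xi) and wobble-cone angle (delta),
    nanobead/rotating-polarizer calibration, affine channel registration,
    generalized-likelihood-ratio spot detection, Gaussian and box intensity
    estimators, Fisher-information/Cramer-Rao bounds on the angular parameters,
    Monte-Carlo scene generators with Poisson noise, and post-retrieval
    statistics (population binning of the tilt angle, radiality profiles,
    focus classes, stick-map rendering).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp,
    RcppArmadillo
Imports:
    Rcpp,
    stats,
    generics,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
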