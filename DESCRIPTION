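Package: retether
Title: Tethered Particle Motion Simulation and Track Analysis for Bacterial
    Adhesion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Brownian-dynamics simulation of a micron-scale particle adhering
    to a flat substratum through multiple, reversibly-binding elastic tethers
    that detach under a force threshold and re-attach on surface proximity,
    together with the single-particle-tracking statistics used in bacterial
    vibration spectroscopy (vibration amplitude, position-maps, positional
    autocorrelation, mean-squared displacement and its power-law confinement
    exponent) and retract-curve metrics for bacterial-probe atomic force
    microscopy (adhesion force, adhesion peaks, rupture length, adhesion
    energy). Simulated and experimental position tracks share one tabular
    format and one analysis pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
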