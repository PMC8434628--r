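Package: tfusim
Title: Nonlinear Westervelt Finite-Difference Simulation of Transcranial
    Focused Ultrasound Through Skull-Like Plates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates continuous-wave focused ultrasound transmitted
    through a curved skull-mimicking plate with an explicit
    finite-difference time-domain (FDTD) solver for the nonlinear
    Westervelt equation, using first-order Mur absorbing boundaries and
    an axisymmetric (or full 3-D) grid.  Provides closed-form acoustic
    oracles for verification, focal-field metrics (focal position,
    peak pressure, -6 dB axial length, percent and dB attenuation),
    parameter sweeps over plate thickness, curvature radius, standoff
    distance, density, sound speed and absorption, and linear or
    power-law trend fitting with unit-attenuation summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    minpack.lm,
    yaml,
    jsonlite,
    digest,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
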