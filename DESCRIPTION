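Package: neurofront
Title: Invasion Fronts and Noise-Driven Extinction in Scalar Neural Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying activity invasion and extinction in
    one-dimensional scalar neural fields with an unstable zero-activity state.
    Implements direct simulation of the nonlocal activity equation with
    Gaussian synaptic kernels and piecewise-linear, tanh or sigmoidal firing
    rates; linear-spreading (pulled front) dispersion analysis and minimal
    wave speeds; pulsating-front dispersion in periodically modulated media
    via truncated Fourier (Hill) matrices; Hamilton-Jacobi sharp-interface
    predictions for fronts under slow synaptic heterogeneity; Ito Langevin
    simulation with multiplicative noise and level-set front-wandering
    statistics; and Hamiltonian optimal-path analysis of noise-driven
    extinction times. Results are returned as tibbles with broom-style
    tidiers and ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    parallel,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
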