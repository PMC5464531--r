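Package: tempamp
Title: Temperature-Amplitude Coupling in Circadian Clock Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for studying how temperature
    affects the period and amplitude of biochemical oscillators. Implements
    the classical Goodwin negative-feedback clock and a two-variable
    positive-plus-negative feedback clock, Arrhenius scaling of reaction
    rates with temperature, Q10 temperature coefficients, a random
    parameterization screen linking period stability to geometric-mean
    amplitude increase, Hopf bifurcation location by eigenvalue bisection,
    a fast-slow (singular perturbation) period approximation, and rhythm
    parameter estimation from sampled gene-expression time series by
    harmonic regression and damped-sine fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
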