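Package: landaucell
Title: Self-Regulated Landau Mean-Field Model of Stem Cell Differentiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a Landau mean-field model of collective stem cell
    differentiation in which the intrinsic (gene-expression) noise is itself a
    dynamical variable under negative feedback. Provides the polynomial
    free-energy potential and its drift, closed-form equilibria of the coupled
    order-parameter/noise system, Jacobian-based stability classification via
    the trace-determinant (Poincare) diagram, Hopf-point detection, fixed-noise
    bifurcation and phase-transition analysis (critical noise values, ground
    states, hysteresis sweeps), Euler-Maruyama simulation of single paths and
    trajectory ensembles with finite-size stochastic forcing, and ensemble
    observables: time-resolved probability densities, quasi-potential
    (Waddington landscape) reconstruction, cell-fate fractions, limit-cycle
    summaries, and noise-induced phenotype-switching statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    optparse,
    pracma,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
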