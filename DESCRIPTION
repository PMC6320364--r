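Package: pathtimes
Title: Transition-Path and First-Passage Times of Driven Brownian Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of exit-path and transition-path times of
    overdamped Brownian motion in one-dimensional energy landscapes, at
    equilibrium and driven out of equilibrium by dichotomous (telegraph)
    forces. Provides an Euler-Maruyama Brownian-dynamics simulator with
    telegraph forcing and automated exit protocols, first-passage-time theory
    (mean first-passage-time profiles, Crank-Nicolson Fokker-Planck solution
    with absorbing boundaries, transition-path-time densities and means,
    splitting probabilities), empirical event detection with
    Kolmogorov-Smirnov comparisons, drift and diffusion inference from
    trajectory displacement statistics, and non-equilibrium diagnostics
    (position-force occupancy, coarse-grained probability currents and broken
    detailed balance, path-time asymmetry sweeps, and a synthetic DNA-hairpin
    emulation with doublet-state analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
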