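Package: protrusim
Title: Stochastic Mechano-Chemical Simulation and Bayesian Calibration of 3D Mesenchymal Cell Migration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates single-cell 3D mesenchymal migration as a two-time-scale
    stochastic process: a four-reaction RTK/PI3K chemosensing network advanced by
    tau-leaping (with exact SSA and deterministic ODE cross-checks), spatial
    allocation of activation events over a discretized membrane, protrusion
    birth/growth/retraction under Eshelby inclusion mechanics in a linear-elastic
    collagen matrix, and cell-body translocation driven by the leading protrusion
    against Stokes drag. Includes the automated calibration pipeline: normalized
    histograms and Bhattacharyya-coefficient metrics for longest-protrusion length
    and protrusion count, a biological validity filter on signal thresholds,
    multi-objective Bayesian optimization with Gaussian-process surrogates over a
    mixed nine-parameter space, Pareto-front extraction, and a synthetic in-vitro
    target generator emulating published summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
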