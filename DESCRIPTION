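Package: dyadCME
Title: Discrete-State Stochastic Models of Calcium-Regulated Calcium Influx
    into Small Subspaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Chemical master equation (CME) models of calcium influx into a
    femtoliter-scale subspace (the cardiac dyad), where 1-100 free calcium
    ions make concentration a fundamentally discrete quantity.  Builds the
    truncated generator for unregulated, calcium-activated, calcium-
    inactivated, multi-channel and calmodulin-regulated channel schemes,
    solves for stationary and transient distributions, computes joint and
    conditional moments, and quantifies the small-system deviation of the
    expected concentration from its deterministic (mass-action ODE) limit,
    including the bistability structure of the mean-field equations.  A
    Gillespie direct-method simulator is included as an independent
    verification oracle for every master-equation solve.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    deSolve,
    igraph,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
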