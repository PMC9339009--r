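Package: memconsol
Title: Stochastic Memory Consolidation in Recurrent Attractor Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates lifelong memory storage in sparse Hopfield-type
    attractor networks that combine Hebbian encoding, exponential synaptic
    decay and stochastic rehearsals whose rates are proportional to each
    memory's basin of attraction. Provides mean-field tools (overlap fixed
    points, critical efficacy, basin-size function), a fast stochastic
    simulator of the coupled efficacy dynamics, full binary-network
    simulations with Monte-Carlo basin measurement, structural perturbation
    experiments (additive synaptic noise, synaptic dilution, threshold
    adaptation), heterogeneous Pareto-distributed synaptic decay times, and
    retention-curve fitting (exponential, double-exponential, power-law).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
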