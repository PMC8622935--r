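Package: hopnet
Title: Hopfield Networks, Minimum Energy Flow Learning, and Hyperclique Codes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for learning binary Hopfield attractor networks from data by
    minimizing the convex energy-flow objective, together with exact small-system
    Lenz-Ising diagnostics (Boltzmann distributions, flow matrices, and the
    projection bound that links energy flow to density estimation), classical
    comparison rules (outer-product, perceptron, delta), a combinatorial
    construction of networks over hypercliques with robust exponential memory
    that behave as nonlinear error-correcting codes, and experiment harnesses
    for attractor-based clustering, hidden-clique learning curves, critical
    training ratios, and spike-raster attractor labeling on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
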