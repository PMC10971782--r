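Package: evomotif
Title: Higher-Order Network Motifs and Fixation Dynamics in Structured
    Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how higher-order network motifs, in
    particular three-node wedges and triangles, shape probabilities and
    times to fixation of new mutants in graph-structured populations.
    Provides dK-style graph generators that tune the triangle fraction of
    a network by simulated-annealing edge swaps while holding the degree
    distribution (and, with 2K-preserving rewiring, the full joint degree
    matrix) fixed; exact stochastic simulation of the Moran Birth-death
    and death-Birth processes with Monte Carlo estimates of fixation
    probability and conditional fixation time; the pair-approximation and
    diffusion theory for these quantities, including the inbreeding-like
    parameter F and acceleration and amplification factors; and
    rank-selection evolutionary-optimization experiments on smooth and
    rugged landscapes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
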