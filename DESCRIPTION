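Package: degreedrift
Title: Degree-Coupled Birth-Death Dynamics and Fixation on Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying a birth-death Moran process on graphs in
    which a mutant's death rate is coupled to the degree of the node it
    occupies (d_B(i) = k_i / <k>), so that neutral drift holds only on
    average and the isothermal theorem is violated. Provides network
    generators (star, complete, ring lattice, Watts-Strogatz small-world,
    power-law configuration-model graphs), degree statistics including the
    degree fluctuation, a fast Monte-Carlo simulator of the process, an
    exact master-equation solver for the star graph, an exhaustive
    absorbing-Markov-chain oracle for small graphs, and config-driven
    fixation-probability sweep experiments.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    Matrix,
    Rcpp,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
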