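Package: epifold
Title: Block Copolymer Modelling of Epigenome Folding into Chromatin Domains
Version: 0.1.0
Authors@R: person("Epifold", "Developers", email = "epifold@example.org",
    role = c("aut", "cre"))
Description: Models chromatin as a bead-spring block copolymer whose monomers
    carry chromatin-state labels (active, HP1, Polycomb, black) and attract
    each other through short-range non-specific and state-specific
    interactions. Provides a Gaussian self-consistent solver for the
    stationary matrix of mean squared inter-monomer distances, a
    velocity-Verlet/Andersen molecular-dynamics engine for validation and
    dynamic observables, phase-diagram classification into coil, globule,
    microphase-separated and multistable regimes, and conversion between
    distance matrices and Hi-C-like contact maps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    methods,
    stats,
    utils,
    optparse,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
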