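Package: simplex2
Title: Reconstruction of 2-Simplicial Complexes from Binary Time-Series Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for inferring higher-order network structure from binary
    time-series observations. Implements a statistical inference framework
    that simultaneously reconstructs pairwise links (1-simplexes) and
    three-body interactions (2-simplexes) of a 2-simplicial complex from a
    state matrix recorded under susceptible-infected-susceptible (SIS)
    contagion with simplicial reinforcement, using a Poisson likelihood
    maximised by expectation-maximization, maximum-gap truncation of the
    inferred interaction probabilities, and an efficient two-step strategy
    that first narrows each node's candidate neighbourhood. Also provides
    generators for random, scale-free and small-world simplicial complexes,
    forward simulators for simplicial contagion and simplicial Ising spin
    dynamics, a builder that extracts a 2-simplicial complex from
    face-to-face contact-event streams, a random state-flipping perturbation
    for robustness studies, and F1-based scoring of reconstructed structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
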