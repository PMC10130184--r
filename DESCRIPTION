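Package: rxngap
Title: Hypergraph Neural Link Prediction for Metabolic Network Gap-Filling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts missing reactions in genome-scale metabolic models
    purely from network topology. A metabolic network is represented as an
    undirected hypergraph (metabolites are nodes, reactions are hyperlinks);
    candidate reactions are scored by a neural network that initialises
    metabolite features from the incidence matrix, refines them per reaction
    clique with graph normalisation and Chebyshev spectral graph convolution,
    pools clique features with Frobenius-norm and max-minus-min functions, and
    emits a sigmoid confidence score. Includes the negative-sampling scheme
    used for training, a ranking loss with an Adam optimiser, Monte-Carlo
    internal validation (threshold classification and top-k recovery from a
    reaction pool), a confidence-plus-dissimilarity gap-filling ranker, and a
    seeded synthetic metabolic-network generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
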