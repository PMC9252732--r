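Package: netprio
Title: Network-Based Gene Prioritization with Supervised Machine Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Trains a custom supervised classifier on molecular-network-derived
    features to predict how associated every gene in a weighted gene interaction
    network is to a user-supplied gene set. Supports three network feature
    representations (adjacency, random-walk-with-restart influence kernel, and
    node2vec embeddings), negative-example selection from a gene-set collection
    with hypergeometric overlap filtering, genome-wide scoring with l2-regularized
    logistic regression, model interpretation by weight-vector similarity to a
    corpus of pre-trained models, and export of the top-gene subgraph. Includes a
    stochastic-block-model generator of synthetic networks, gene-set collections,
    and identifier maps so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    optparse
Config/testthat/edition: 3
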