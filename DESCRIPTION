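Package: cmipred
Title: Predicting circRNA-miRNA Interactions from Sequence and Network Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A link-prediction pipeline for circRNA-miRNA interactions (CMIs).
    RNA sequences are embedded with a k-mer skip-gram model trained by negative
    sampling, the bipartite interaction network is embedded with k-order
    transition-matrix factorization (GraRep), sequence embeddings are compressed
    by greedy layer-wise stacked autoencoders, and the modalities are fused by a
    two-stage weighted attention mechanism feeding a multilayer-perceptron link
    classifier. Includes negative sampling, leakage-safe cross-validation, a
    confusion/rank metric suite, a class-imbalance evaluation harness, and a
    seeded synthetic benchmark generator with a planted seed-complementarity
    interaction rule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
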