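Package: sposer
Title: Sparse Positive Similarity Embeddings from Odd-One-Out Judgments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for studying mental similarity spaces with
    the triplet odd-one-out task. Provides triplet experiment designs with
    exhaustive, repeat and pair-coverage sampling blocks; crowdsourcing quality
    control based on reaction times, positional response bias and
    repeated-triplet choice consistency; a sparse positive similarity embedding
    (SPoSE) learner that fits a softmax-of-dot-products choice model by
    projected Adam with L1 sparsity, pruning and dimension sorting;
    hyperparameter grid search with multi-seed averaging and seed-stability
    analysis; representational similarity analysis of dimension ratings against
    model weights with a randomization test; and stimulus-curation steps
    (best-frame selection, category representatives, cosine dissimilarities,
    hierarchical clustering, naming-accuracy exclusion). A synthetic-data
    module simulates choices, reaction times and contaminated workers from a
    ground-truth embedding so the whole pipeline is testable without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
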