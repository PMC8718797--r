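Package: lncDNet
Title: Predicting lncRNA-Disease Associations from Heterogeneous Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts associations between long noncoding RNAs (lncRNAs) and
    diseases from a binary association list and a disease-ontology ancestor
    graph. Disease semantic similarity (ancestor-contribution model on the
    ontology DAG), lncRNA functional similarity, and Gaussian
    interaction-profile kernel similarities are fused into lncRNA and disease
    similarity networks, assembled with the association matrix into one
    heterogeneous graph. Node features are learned by metagraph-guided random
    walks and heterogeneous skip-gram with type-constrained negative
    sampling. Balanced negative training pairs are chosen by K-means
    clustering of all unknown pairs, and candidate pairs are scored by a
    gradient-boosted-tree to logistic-regression cascade (one-hot leaf
    encoding). Includes a planted-block synthetic data generator so the full
    pipeline runs and is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
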