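Package: pirf
Title: Phylogeny-Informed Random Forests for Microbiome Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Random forests whose split-candidate sampling follows
    phylogeny-informed selection probabilities. Microbial features are
    partitioned into phylogenetic clusters from the cophenetic distance
    matrix of a phylogenetic tree (partitioning around medoids with
    silhouette-based selection of the number of clusters), permutation
    importance is computed locally within each cluster, and cluster-specific
    probabilities are integrated with cluster-size weights into a unit-sum
    community-level probability vector that drives weighted feature sampling
    in a final forest. Supports binary classification and regression on
    microbiome feature tables, a zero-inflated synthetic data generator with
    clade-localized signal, five-fold cross-validation with variant
    comparison, and JSON model serialization.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    cluster,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    ranger,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
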