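Package: kglink
Title: Embedding-Based Node and Edge Prediction for Typed Knowledge Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing typed, undirected biomedical knowledge
    graphs with homogeneous node embeddings. Implements node2vec biased
    second-order random walks with skip-gram training and LINE first- and
    second-order proximity embeddings; connectivity-preserving
    ("Connected Monte-Carlo") train/test edge holdouts; degree-aware
    negative edge sampling with a leakage-free (zero false negative)
    pipeline for edge prediction restricted to a single edge type; and
    end-to-end node-type, generic-edge and specific-edge prediction tasks
    evaluated by balanced accuracy and F1 over repeated holdouts. Includes
    a stochastic-block-model generator for synthetic heterogeneous
    knowledge graphs with skewed type frequencies and type-dependent mean
    degrees, used as a fully controlled test bed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    ranger,
    Rcpp,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
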