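Package: probnet
Title: Exact Shortest-Path Counting and Community Detection in
    Probabilistic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for networks whose edges carry independent presence
    probabilities, as produced by interaction databases that report
    confidence scores. Computes the exact probability distribution of the
    number of shortest paths between two nodes by multiplying per-edge
    polynomials over a path-edge bipartite graph with collapse and select
    operators, instead of enumerating the exponentially many deterministic
    instances. Builds on this to compute expected edge and node
    betweenness, expected-modularity community detection (a divisive
    Girvan-Newman adaptation), baseline transforms (binarise, threshold,
    Bernoulli sampling), an LFR-style synthetic benchmark generator with
    planted communities, a brute-force enumeration oracle for
    verification, and a benchmark harness comparing exact counts against
    the baseline methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
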