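Package: mscomm
Title: Multi-Scale Community Detection in Weighted Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Hierarchical community detection for weighted graphs by
    multilayer modularity maximization. Duplicates of a graph are linked
    across neighboring structural-resolution (gamma) layers into a single
    supra-modularity problem that is optimized with a generalized
    Louvain heuristic, so community labels are directly comparable across
    topological scales. Includes a two-modality multiplex extension, a
    multi-slice (temporal) multi-scale extension, node-level stability
    statistics, allegiance matrices with permutation-null consensus
    clustering, inter-layer reliability, cross-graph allegiance
    correlation maps, spatial contiguity statistics, optimal leaf-order
    node sorting, and seeded generators for planted-hierarchy benchmark
    graphs with matched strength-preserving null graphs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Matrix,
    methods,
    Rcpp,
    rlang,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
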