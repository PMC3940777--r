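Package: graphletLP
Title: Graphlet-Orbit Link Prediction and De-Noising for Protein
    Interaction Networks
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Link prediction for undirected protein-protein interaction
    networks based on graphlet automorphism orbits. Enumerates the
    catalog of 2-5-node graphlets together with their node, edge,
    non-edge, and reconciled node-pair orbits, counts orbit touches by
    exhaustive connected-subgraph enumeration, and scores node pairs by
    node-GDV-similarity, (density-weighted) node-pair-GDV-centrality,
    and a tunable combination of the two. Eight classical baseline
    measures (degree product, shared neighbors, Jaccard, Adamic-Adar,
    Katz, local path index, resource allocation) are provided for
    comparison, together with an evaluation harness based on synthetic
    edge-removal noise (AUROC/AUPR), network de-noising, GO-term
    sharing enrichment, and external-network validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Matrix,
    Rcpp,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
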