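Package: modproj
Title: Projection of Fold-Change Vectors onto Co-Expression Module Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores differential-expression profiles against libraries of
    co-expression gene modules. A per-comparison log fold-change vector is
    centered and scaled, restricted to the features it shares with a sparse
    non-negative feature-by-module weight matrix, and its scalar projection
    onto every module direction is compared with a gene-label permutation
    null to yield per-module Z-scores, p-values and significance calls.
    Companion tools cover edgeR-style differential-expression tables
    (CPM filtering, fold-change/FDR threshold calls, multi-comparison Venn
    overlaps), module discretization into gene sets, cross-comparison
    Z-score concordance, hypergeometric gene-set enrichment, and
    enrichment-map style overlap-coefficient networks with a recurrence
    ("hallmark") filter. A seeded synthetic-data generator emulates the
    module matrix, probe-to-gene maps and fold-change vectors with planted
    module signals, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    edgeR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
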