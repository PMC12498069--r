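Package: sses
Title: Hierarchical Spatial-Evolution Classification of Seed-Plant Families
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Classifies seed-plant families into a hierarchical
    spatial-evolution system (floristic elements, distribution supertypes,
    distribution types and subtypes) from per-family geographic species
    counts. Implements the binary distribution-center coding (4 percent
    rule), seeded K-means clustering with elbow diagnostics, cluster-to-type
    labelling with curated overrides, type-relationship analysis
    (agglomerative linkage selection by cophenetic correlation and Gower
    fit, non-metric multidimensional scaling), phylogenetic-signal tests
    (Blomberg's K with permutation p-values, Pagel's lambda by maximum
    likelihood), and descriptive origin and formation statistics. A seeded
    synthetic-data generator produces complete study bundles (count tables,
    dated trees, annotations) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    jsonlite,
    stats,
    utils
Suggests:
    phytools,
    mclust,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
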