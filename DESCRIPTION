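Package: geofuncnet
Title: Functional Gene Co-Occurrence Networks for Microbial Community Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for functional-gene-array (GeoChip-like)
    presence/absence data from microbial communities. Builds weighted
    co-occurrence networks with soft-threshold adjacency, topological
    overlap and module detection; clusters binary gene profiles with
    KMeans++ seeding and equal-distance multi-assignment; mines
    function-level association rules with the Apriori algorithm; and
    computes functional-representation statistics, including
    per-category scaling regressions of gene counts against group size,
    homogeneity tests across sites, and correlations between
    phylogenetic and functional module distributions. Includes a
    synthetic-community generator with planted module structure for
    validation without array data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    mclust,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
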