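Package: exponet
Title: Longitudinal Exposome and Multi-Omics Correlation Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to integrate a longitudinal personal exposome with internal
    multi-omics profiles. Builds thresholded Spearman/FDR correlation networks
    within and between omic blocks, partitions them by iterative
    edge-betweenness community detection with modularity tracking, detects
    dysregulated metabolic modules from untargeted metabolic features via
    adduct mass matching, hidden-metabolite subnetwork expansion, random-walk
    clustering and a Gamma-fitted resampling null on a module activity score,
    performs hypergeometric pathway over-representation tests, and attributes
    clinical-marker variation to exposome categories through a principal
    component regression with partial-least-squares variable importance
    weighting. A seeded synthetic-data module emulates the study design so the
    whole pipeline runs and is verified without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    fitdistrplus,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    jsonlite
Config/testthat/edition: 3
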