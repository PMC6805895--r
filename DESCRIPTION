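Package: innatemapr
Title: Hierarchical Immune Signalling-Map Analysis for Single-Cell Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical machinery for hierarchical signalling-map resources
    describing innate immune polarization in the tumor microenvironment.
    Represents four-level map hierarchies (zones, meta-modules, modules,
    pathways) with entity tagging and GMT gene-set interchange; computes
    reaction confidence scores from publication annotations and shortest-path
    proximity in a protein-protein interaction graph; ranks single cells
    along a latent polarization axis using stability-selected independent
    component analysis and splits them into groups; scores module activity
    per group (mean of the top-half most variant genes) with Welch t-tests
    and significance codes; summarises per-gene survival z-scores per
    meta-module with a chi-squared enrichment test; and compares map content
    against other gene-set resources. Ships a synthetic-data generator with
    planted ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
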