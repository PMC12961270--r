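Package: holocorr
Title: Module-Based Correlation Analysis for Host-Microbiome Multi-Omics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A module-first workflow for exploratory holo-omics analysis.
    Each omics layer (host transcriptome, metagenome, metaproteome,
    metabolome, ...) is reduced to co-varying feature modules via weighted
    correlation networks and topological overlap; each module is represented
    by its most intramodularly connected feature (hub). Hub profiles are then
    correlated across omics layers, across the host-microbiome boundary, and
    against sample metadata, with multiple-testing control, and the results
    are rendered as one integrated annotated heatmap. Ships a latent-factor
    simulator with planted modules, cross-layer couplings and metadata
    associations, plus evaluators that score module recovery and coupling
    detection against the planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    grid,
    yaml,
    jsonlite,
    mclust,
    ComplexHeatmap,
    circlize
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
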