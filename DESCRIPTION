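Package: immunophen
Title: Tumour-Immune Phenotype Classification from Compartmental CD8
    Densities and Bulk RNA-Seq
Version: 0.9.0
Authors@R:
    person("ICON", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for defining and classifying
    tumour-immune phenotypes (infiltrated, excluded, desert) from digital
    pathology and bulk RNA-seq. Includes synthetic cohort and
    immunohistochemistry image generators with planted ground truth,
    compartmental CD8 quantification (nucleus segmentation, tumour/stroma
    compartment assignment, DAB-positive cell counting), polar CD8 metrics
    (quantity R and spatial distribution theta), count-matrix preparation
    (low-expression filtering, TMM size factors, log2 CPM,
    housekeeping-gene scaling), per-gene random-forest permutation
    importance for signature-gene discovery, consensus clustering with
    subsampling, and a confidence-gated nearest-shrunken-centroid
    classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
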