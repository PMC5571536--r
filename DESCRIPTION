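Package: degsom
Title: Cross-Tissue Differential Expression, Treatment-Reversal
    Classification and Self-Organizing Map Co-Expression Modules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for cross-tissue transcriptome comparisons
    of a disease model with and without drug treatment. Starting from a
    gene-by-sample FPKM matrix, the package computes pairwise
    differential-expression contrasts within each tissue (Welch t-test on
    log2(FPKM+1) with Benjamini-Hochberg FDR control), classifies genes
    shared between a disease contrast and a treatment contrast as reversed
    or exacerbated by treatment, discovers co-expression modules with a
    batch Kohonen self-organizing map on a hexagonal lattice (including
    U-matrix distances and module-to-cluster merging), and performs
    Fisher's exact over-representation analysis of gene lists against GMT
    gene-set collections. A synthetic-data generator emulating a
    four-tissue, four-group diabetes/pioglitazone design with planted
    effects provides ground truth for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
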