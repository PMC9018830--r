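Package: hscmark
Title: Diffusion-State Marker Discovery and Repopulating-Cell Frequency
    Estimation for Hematopoietic Stem Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering cell-surface marker genes of human
    hematopoietic stem cells from combined bulk and single-cell RNA-seq.
    Implements quality-control filters and TPM normalisation for
    plate-based single-cell data, highly-variable-gene selection by a
    log-linear mean-CV^2 noise fit, surrogate-variable and empirical-Bayes
    batch correction, diffusion-map embedding with diffusion-pseudotime
    tercile sub-populations, Wilcoxon rank-sum and negative-binomial Wald
    differential expression with Benjamini-Hochberg control, dual-evidence
    marker ranking, pre-ranked gene-set enrichment and
    correlation-adjusted competitive set tests, per-cell gene-module
    expression strength, and single-hit Poisson limiting-dilution
    estimation of repopulating-cell frequencies. Seeded generators of
    synthetic single-cell, bulk and dose-response data allow the whole
    workflow to be exercised end to end.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    sva,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    DESeq2,
    limma,
    fgsea,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
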