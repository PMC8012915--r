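Package: panDMR
Title: Pan-Cancer Differentially Methylated Region Calling and
    Co-Expression Block Disruption
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies differentially methylated regions (DMRs) shared
    across cancer types from Illumina 450K-style beta-value matrices.
    Implements rank-based quantile normalization, per-CpG Welch testing
    with Benjamini-Hochberg FDR control, per-CpG AUROC screening averaged
    across cancer cohorts, DMR calling by probe contiguity and CpG density
    gates, merging of coordinately close regions, and quantification of
    gene co-expression block disruption between normal and tumor tissue.
    Ships a seeded synthetic-cohort generator (manifests, beta cohorts
    with planted hypermethylated runs, expression cohorts with
    group-dependent block correlation) so the full pipeline is testable
    without array downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3),
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    GenomeInfoDb,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    limma,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
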