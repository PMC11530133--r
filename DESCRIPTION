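Package: apucnet
Title: Second-Order Gene-Association Networks, Signature Scoring, and
    Survival Analysis for Androgen-Pathway Gene Modules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying coalescent gene modules in bulk RNA-seq
    cohorts of prostate tissue. Implements a second-order gene-association
    measure (correlation of whole-transcriptome correlation profiles),
    gene-set signature scoring with percentile stratification of patients,
    hormone-receptor correlation analysis, permutation-based gene-set
    enrichment (ES/NES/FDR), Kaplan-Meier/log-rank/Cox survival comparison
    of expression-defined subgroups with claims-gap event imputation, and a
    synthetic multi-cohort simulator with planted stage-dependent
    co-expression structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    uwot,
    MASS
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    mclust,
    jsonlite
Config/testthat/edition: 3
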