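Package: sigdecon
Title: Cell-Type Signature Derivation, Bulk Deconvolution and Survival
    Association Benchmarking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives cell-type transcriptional signatures from heterogeneous
    RNA-seq reference collections using a Bayesian negative-binomial abundance
    model with hierarchical credible-interval marker selection, estimates
    cell-type fractions in bulk samples by nu-support-vector regression,
    relates fractions and gene expression to censored survival (Kaplan-Meier,
    log-rank, Benjamini-Hochberg, Cox), and scores the whole pipeline with a
    Dirichlet-mixture simulation benchmark evaluated by ROC/AUC against
    planted ground truth. Includes a synthetic-data module that emulates the
    statistical structure of curated reference transcriptomes and clinical
    cohorts so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    survival,
    edgeR,
    pROC,
    yaml,
    cluster
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
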