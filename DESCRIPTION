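Package: tmepatterns
Title: Tumor Microenvironment Composition Patterns from Single-Cell RNA-Seq with Bulk Survival Translation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for discovering tumor-microenvironment composition
    patterns from multi-patient single-cell RNA-seq of lung adenocarcinoma
    and translating them to bulk cohorts. Implements quality-control
    filtering, log-normalization and highly variable gene selection,
    PCA/shared-nearest-neighbor graph clustering with marker-driven cell
    type annotation and tumor-cell calling, Wilcoxon marker-gene detection
    with fraction and fold-change filters, expression-bin-matched module
    scores and weighted pathway activity scores, a tumor-cell
    differentiation axis with derived gene signatures, per-patient
    cell-cluster composition analysis with pattern PCA and Spearman
    correlation networks, single-sample gene set enrichment (ssGSEA)
    scoring of bulk cohorts with Kaplan-Meier/log-rank/Cox survival
    stratification, and ligand-receptor interaction permutation tests.
    A synthetic-data module generates single-cell and bulk cohorts with
    planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    igraph,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
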