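Package: hfsig
Title: Blood Immune-Cell Gene Signature Discovery for Post-Infarction Heart Failure
Version: 0.1.0
Authors@R:
    person("hfsig", "developers", email = "hfsig@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for discovering compact blood
    transcriptomic signatures that predict heart failure after myocardial
    infarction. Implements per-cell-type differential expression and cluster
    marker detection (Wilcoxon rank-sum with expression-fraction and
    log-fold-change gates), hypergeometric over-representation and preranked
    gene-set enrichment, single-sample gene-set variation scoring (kernel-CDF
    rank random walk), nearest-centroid classification with multiple random
    validation (pooled prediction scores, ROC/AUC, Welch-t ROC p-values,
    Wilson intervals), a cell-type prediction-power screening rule, and a
    cyclic leave-one-out AUC-maximizing signature refinement. A synthetic-data
    generator with planted markers, discriminative panels and enriched gene
    sets provides ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    Matrix,
    matrixStats,
    jsonlite,
    yaml,
    withr,
    digest,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
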