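Package: strictscreen
Title: Cell-Type Enrichment and Expression-Strictness Screening of Disease Gene Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Screens disease gene panels against annotated single-cell expression
    data. Computes gene by cell-type expression specificity and a bootstrap
    enrichment test over random same-size gene lists with FDR control, a per-gene
    expression "strictness" statistic (the inverse standard deviation of per-cell
    fold changes, a dosage-requirement measure) with a Central Limit Theorem based
    gene-set significance test and Bonferroni correction, Stouffer meta-analysis of
    per-dataset results, and a negative-binomial single-cell simulator with known
    marker and dispersion ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
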