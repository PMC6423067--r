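Package: vesicomics
Title: Biomarker Selection for Extracellular Vesicle Multi-Omics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical pipeline for nominating immunomodulatory proteins
    and miRNAs in mesenchymal stromal cell derived extracellular vesicles
    from paired (donor-matched) control versus inflammation-primed designs.
    Provides univariate protein selection (per-donor fold-change presence
    rule, Welch tests, Benjamini-Hochberg adjustment), greedy forward
    variable ranking in principal component score space (Ranking-PCA)
    followed by PLS-DA classification with leave-one-individual-out
    cross-validation and non-error-rate reporting, a simplified negative
    binomial Wald test for miRNA count data, miRNA/protein block
    integration, miRNA-target pathway coverage statistics with chord-edge
    export, hypergeometric over-representation analysis, and synthetic
    data generators with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
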