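Package: gersub
Title: Batch-Robust Molecular Subtype Classification from Gene-Pair Rank
    Reversals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Trains and applies a molecular subtype classifier for bulk
    transcriptomics that is robust to batch effects by construction. Absolute
    expression is replaced by intrasample gene ranks; oriented gene pairs
    whose rank order reverses in one subtype are screened by a reversal-ratio
    statistic with Fisher exact tests, refined by cross-validated elastic-net
    logistic regression, and samples are assigned to the subtype with the
    highest mean pair-indicator score. Includes one-vs-rest evaluation
    metrics, a score-plus-one-hot t-SNE visualization, a synthetic multi-batch
    cohort generator with planted rank-reversal structure, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    Rtsne,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    yaml,
    optparse
Config/testthat/edition: 3
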