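Package: immex
Title: Scoring and Prioritization of Tumor-Intrinsic Immune-Exclusion Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for nominating tumor-intrinsic signaling pathways associated
    with an immune-excluded (non-T cell-inflamed) tumor microenvironment from
    bulk and single-cell transcriptomes. Implements T cell-inflamed signature
    scoring and quantile classification, direction-aware pathway activation
    scores, concordance activation z-scores, per-cell pathway scoring with
    linear mixed-model infiltration contrasts (likelihood ratio tests,
    Benjamini-Hochberg FDR), geometric-mean rank integration across evidence
    streams with printed pass filters, a 12-gene p38 activation score, and
    RECIST-style trial response summaries with Kaplan-Meier estimates. Includes
    a synthetic cohort generator with planted, recoverable ground truth so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    fgsea,
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
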