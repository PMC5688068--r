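Package: voclearn
Title: Urinary Volatile Organic Compound Biomarker Discovery by PLS-DA with
    Stability Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for discovering discriminating volatile organic compounds
    (VOCs) in SPME GC-MS urine profiling studies of two-group cohorts.
    Implements the full analysis chain: synthetic two-group cohort generation
    with planted markers, internal-standard normalisation, triplicate-median
    collapsing, log transformation and autoscaling, PCA outlier screening by
    Hotelling's T2 and DModX, post-transformed PLS-DA with VIP scores,
    7-fold cross-validated Q2 and AUC, permutation testing, Monte-Carlo
    stability selection with VIP-threshold tuning, a univariate
    t-test/FDR/ROC battery with post-hoc power, and the merge rule that
    unites multivariate and univariate selections into a putative marker
    set. Also provides Kovats retention-index and HOMA-IR utilities and
    parsers for packaged VOC identification tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    pROC,
    jsonlite
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
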