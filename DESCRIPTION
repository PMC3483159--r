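Package: fscstats
Title: Finite-Size Corrected Gumbel Statistics for Gapped Local Alignment Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gumbel (Karlin-Altschul) statistics for gapped local alignment
    scores, with both the classical mean-length finite-size correction and a
    distributional finite-size correction that models the sequence lengths an
    alignment must consume to reach a score as bivariate normal and computes
    the expected positive-part alignment area. Includes an affine-gap
    Smith-Waterman aligner with traceback, Monte-Carlo calibration of the
    Gumbel scale and pre-factor and of the linear length-moment models,
    empirical p-value standards by direct simulation, and pooled ROC-n
    retrieval evaluation with query-level bootstrap errors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
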