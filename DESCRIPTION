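Package: dietwire
Title: Diet-Contrast Multi-Tissue Co-Expression Networks with PCIT and
    Regulatory Impact Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for contrasting two dietary (or other two-group) conditions
    across multiple tissues at the transcriptome and network level. Implements
    TMM/CPM count preprocessing, per-tissue two-group differential expression
    with an analytic false discovery rate, RIF1/RIF2 regulatory impact factor
    scoring of transcription factors and cofactors, PCIT (partial correlation
    and information theory) co-expression network inference, phenotype-anchored
    condition-specific networks, and differential-connectivity analytics for
    phenotypes and genes. Includes a negative-binomial synthetic-data generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    edgeR,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
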