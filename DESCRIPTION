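Package: pqtlmr
Title: Proteome-Wide Two-Sample Mendelian Randomization with pQTL
    Instruments
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for proteome-wide two-sample Mendelian randomization
    using protein quantitative trait loci (pQTLs) as instruments.
    Reads and harmonizes GWAS summary statistics, selects and classifies
    cis/trans instruments with LD clumping and weak-instrument screening,
    estimates causal effects with the inverse-variance-weighted delta
    method plus a pleiotropy-robust sensitivity battery (robust IVW,
    MR-Egger, weighted median, weighted mode, contamination mixture,
    MR-PRESSO, constrained maximum likelihood), tests causal direction
    with the Steiger test, meta-analyzes cohorts, applies two-tier
    multiple-testing control, and runs hypergeometric gene-set
    enrichment. A synthetic summary-statistics generator with known
    ground truth makes every stage testable without access to restricted
    GWAS data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
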