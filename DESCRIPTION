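Package: targetmr
Title: Drug-Target Mendelian Randomization with Metabolite Mediation and
    Phenome-Wide Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for drug-target Mendelian randomization (MR) on GWAS
    summary statistics: construction of genetic proxies for pharmacological
    target inhibition (cis-variant selection, approximate-Bayes-factor
    colocalization, LD clumping, effect inversion), a two-sample MR
    estimator suite (inverse-variance weighted, MR-Egger, weighted median,
    MR-PRESSO outlier detection), multivariable-MR mediation with the
    proportion-mediated decomposition, inverse-variance meta-analysis of
    replicate datasets, and Bonferroni-controlled phenome-wide batch-MR
    screens. Includes a synthetic summary-statistics generator with known
    causal truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
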