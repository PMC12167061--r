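Package: prsceiling
Title: Polygenic Score Accuracy Ceilings from Captured Heritability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study how polygenic risk score (PRS) discrimination
    converges with GWAS sample size and what bounds it. Includes a synthetic
    genotype-panel generator with tunable linkage disequilibrium, a
    rare-skewed allele-frequency spectrum, emulated imputation quality and
    liability-threshold phenotypes; alpha-model and attenuated alpha-model
    effect-size samplers; captured-heritability metrics for genotyped
    (LD-tagging) and imputed variant panels; the liability-threshold
    maximum-achievable-AUC approximation with simulation validation and a
    best-fit alpha calibration; effective-sample-size bookkeeping, PRS
    scoring, rank-based AUC with inverse-variance meta-analysis, and
    simulated GWAS convergence curves; and annotation-enrichment regressions
    on imputation quality with multiple-testing control.
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
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
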