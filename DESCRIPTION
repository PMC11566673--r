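Package: imputeval
Title: Empirical Evaluation and Calibration of Genotype Imputation Quality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating genotype imputation accuracy against a
    sequenced truth set and for harmonising software imputation quality
    scores across tools. Computes per-variant empirical accuracy (Pearson r
    for best-guess and dosage genotypes, squared empirical accuracy,
    concordance, and allele-level false positive/negative/total error
    rates), re-implements the per-variant quality scores reported by
    common imputation programs (Beagle dosage R2, MACH/Minimac Rsq,
    IMPUTE INFO), applies reference-panel filters (biallelic, minor allele
    count, sliding-window excess heterozygosity), and derives
    software-equivalent quality-score filtering thresholds by calibrating
    score bins against empirical accuracy, with true/false positive and
    false negative accounting. Includes a deterministic synthetic
    truth/imputed genotype simulator so the whole pipeline is testable
    without external data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
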