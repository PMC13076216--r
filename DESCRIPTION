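Package: maxvep
Title: Maximum-Confidence Ensemble Aggregation and Co-Distillation for
    Variant Effect Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale toolkit for protein-language-model style variant
    effect prediction built around log-likelihood-ratio (LLR) substitution
    scoring. Implements wild-type-marginal LLR matrices with sliding-window
    segmentation for long proteins, maximum-confidence (elementwise minimum)
    and averaging ensemble aggregation with the class-conditional Gaussian
    order-statistic theory that explains when each aggregator wins, iterative
    co-distillation of pluggable student scorers against fixed aggregate
    targets, teacher-to-student knowledge distillation, a clinical and
    deep-mutational-scanning evaluation suite (balanced bootstrap AUC,
    per-gene AUC, score calibration, accuracy-coverage curves, binary
    classification metrics, Spearman panels, win rates, minor-allele
    frequency stratification), and rare-variant summary-statistic regression
    benchmarks. A synthetic-data module generates protein families with
    conserved domains, complementary blind-spot scorers, labeled variant
    sets, assay tables and gene-phenotype summary statistics so every
    component is testable without external downloads.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    Biostrings,
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
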