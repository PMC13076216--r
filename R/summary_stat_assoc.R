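#' Regress variant scores against single-variant effect sizes
#'
#' For one gene-phenotype pair, a linear regression of the per-variant
#' predictions against the summary-statistic effect sizes; the standardized
#' slope (the Pearson correlation) proxies the gene-level effect size and the
#' two-sided p-value comes from the product-moment correlation test. No
#' multiple-testing adjustment is applied.
#'
#' @param scores Per-variant predictions.
#' @param betas Per-variant effect sizes.
#' @return One-row tibble: `r`, `p`, `n`.
#' @export
variant_score_regression <- function(scores, betas) {
  keep <- is.finite(scores) & is.finite(betas)
  scores <- scores[keep]; betas <- betas[keep]
  if (length(scores) < 3L) abort("need at least 3 variants")
  if (sd(scores) == 0 || sd(betas) == 0) {
    abort("degenerate regression: constant scores or effect sizes")
  }
  ct <- cor.test(scores, betas, alternative = "two.sided")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = length(scores))
}

#' Run the regression over every gene-phenotype pair
#'
#' @param table Summary-statistic tibble (long, one row per variant) with
#'   `gene`, `phenotype`, `beta` and the score column.
#' @param score Name of the prediction column (default `"score"`).
#' @return Tibble: `gene`, `phenotype`, `r`, `p`, `n` (plus `plof_beta` if
#'   present in `table`).
#' @export
pair_regressions <- function(table, score = "score") {
  table |>
    dplyr::group_by(.data$gene, .data$phenotype) |>
    dplyr::group_modify(function(df, key) {
      out <- variant_score_regression(df[[score]], df$beta)
      if ("plof_beta" %in% names(df)) out$plof_beta <- df$plof_beta[1]
      out
    }) |>
    dplyr::ungroup()
}

#' Filter gene-phenotype pairs to the benchmark subset
#'
#' Keeps pairs with (1) at least `min_missense` missense variants and (2) a
#' gene-level missense p-value below `gene_p_threshold`; within kept pairs,
#' only variants individually associated with the phenotype
#' (`p < single_variant_p`) are retained. Filters commute: applying them in
#' any order yields the same set.
#'
#' @param table Long summary-statistic tibble with `gene`, `phenotype`, `p`,
#'   `gene_missense_p` columns.
#' @param min_missense Minimum variants per pair (default 25).
#' @param gene_p_threshold Gene-level missense p threshold (default 1e-10).
#' @param single_variant_p Per-variant p threshold (default 0.05).
#' @return The filtered tibble.
#' @export
filter_benchmark_pairs <- function(table, min_missense = 25L,
                                   gene_p_threshold = 1e-10,
                                   single_variant_p = 0.05) {
  table |>
    dplyr::group_by(.data$gene, .data$phenotype) |>
    dplyr::filter(dplyr::n() >= min_missense,
                  .data$gene_missense_p[1] < gene_p_threshold) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$p < single_variant_p)
}

#' Mean association strength over pairs
#'
#' The average `-log10(p)` across gene-phenotype pair regressions, with
#' p-values floored at `floor` (default 1e-300) so underflowing pairs stay
#' finite.
#'
#' @param results Pair-regression tibble with a `p` column.
#' @param floor Smallest p-value used (default 1e-300).
#' @return Scalar mean `-log10(p)`.
#' @export
association_strength <- function(results, floor = 1e-300) {
  mean(-log10(pmax(results$p, floor)))
}

#' Direction-of-effect concordance with pLoF burden
#'
#' Among pairs whose regression p-value is below `significance`, the
#' fraction whose correlation sign matches the sign of the gene-level pLoF
#' burden effect. Pairs with a zero pLoF effect are excluded with a warning.
#'
#' @param results Pair-regression tibble with `r`, `p` and `plof_beta`
#'   columns (pass `plof_betas` separately to override).
#' @param plof_betas Optional numeric vector aligned with `results`.
#' @param significance Regression p-value cutoff (default 0.1).
#' @return Scalar concordance fraction (NA if no pair qualifies).
#' @export
direction_concordance <- function(results, plof_betas = NULL,
                                  significance = 0.1) {
  plof <- plof_betas %||% results$plof_beta
  if (is.null(plof)) abort("pLoF effect sizes are required")
  keep <- results$p < significance
  if (any(plof[keep] == 0)) {
    warn("pairs with zero pLoF effect excluded from concordance")
    keep <- keep & plof != 0
  }
  if (!any(keep)) return(NA_real_)
  mean(sign(results$r[keep]) == sign(plof[keep]))
}

#' Log-MAF baseline scores for the association benchmark
#'
#' The allele-frequency comparator: the same regression run with
#' `log10(MAF)` as the score, using a pseudo-frequency for zero MAF.
#'
#' @param af Allele frequencies (NA treated as 0 via [maf()]).
#' @param pseudo Pseudo-frequency added before the log (default 1e-6).
#' @return Numeric scores.
#' @export
log_maf_score <- function(af, pseudo = 1e-6) {
  log10(maf(af) + pseudo)
}
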