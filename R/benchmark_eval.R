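#' Area under the ROC curve for pathogenic/benign labels
#'
#' Orientation is benign-high throughout the package: AUC is the probability
#' that a randomly chosen benign variant scores above a randomly chosen
#' pathogenic one, with half credit for ties — the Mann-Whitney U statistic
#' divided by `n_pathogenic * n_benign`, computed from average ranks.
#'
#' @param scores Numeric scores (higher = more benign).
#' @param labels Labels: `"pathogenic"`/`"benign"` strings, a factor, or a
#'   logical vector (TRUE = pathogenic).
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' auc(c(-3, -2, 1, 2), c("pathogenic", "pathogenic", "benign", "benign"))
auc <- function(scores, labels) {
  path <- as_pathogenic(labels)
  if (length(scores) != length(path)) abort("scores and labels differ in length")
  if (anyNA(scores)) abort("scores must be finite (drop missing rows first)")
  n_p <- as.numeric(sum(path)); n_b <- as.numeric(sum(!path))
  if (n_p == 0L || n_b == 0L) {
    abort("AUC is undefined when only one class is present")
  }
  r <- rank(scores)  # average ranks: ties get half credit
  (sum(r[!path]) - n_b * (n_b + 1) / 2) / (n_p * n_b)
}

as_pathogenic <- function(labels) {
  if (is.logical(labels)) return(labels)
  l <- tolower(as.character(labels))
  if (!all(l %in% c("pathogenic", "benign"))) {
    abort("labels must be 'pathogenic'/'benign' (or logical)")
  }
  l == "pathogenic"
}

#' Bootstrap AUC over label-balanced resamples
#'
#' Each resample draws `resample_size / 2` variants per class with
#' replacement and the AUC is computed on the union; reported are the mean
#' and standard deviation over resamples.
#'
#' @param data Tibble with `score` and `label` columns.
#' @param n_resamples Number of resamples (default 50).
#' @param resample_size Total variants per resample (default 6000).
#' @param seed Integer seed.
#' @return One-row tibble: `auc_mean`, `auc_sd`, `n_resamples`,
#'   `resample_size`.
#' @export
bootstrap_balanced_auc <- function(data, n_resamples = 50L,
                                   resample_size = 6000L, seed = 1L) {
  path <- as_pathogenic(data$label)
  idx_p <- which(path); idx_b <- which(!path)
  if (!length(idx_p) || !length(idx_b)) abort("need both classes")
  half <- resample_size %/% 2L
  aucs <- withr_seed(seed, {
    vapply(seq_len(n_resamples), function(i) {
      take <- c(sample(idx_p, half, replace = TRUE),
                sample(idx_b, half, replace = TRUE))
      auc(data$score[take], path[take])
    }, numeric(1))
  })
  tibble::tibble(auc_mean = mean(aucs), auc_sd = sd(aucs),
                 n_resamples = n_resamples, resample_size = resample_size)
}

#' Per-gene AUC
#'
#' AUC computed separately for every gene with at least `min_variants`
#' labeled variants and both classes present; genes failing either condition
#' are excluded.
#'
#' @param data Tibble with `gene`, `score`, `label`.
#' @param min_variants Minimum labeled variants per gene (default 10).
#' @return Tibble: `gene`, `n_variants`, `auc`. The benchmark summary is
#'   `mean(result$auc)`.
#' @export
per_gene_auc <- function(data, min_variants = 10L) {
  kept <- data |>
    dplyr::group_by(.data$gene) |>
    dplyr::filter(dplyr::n() >= min_variants,
                  dplyr::n_distinct(as_pathogenic(.data$label)) == 2L)
  if (!nrow(kept)) {
    return(tibble::tibble(gene = character(), n_variants = integer(),
                          auc = numeric()))
  }
  dplyr::summarise(kept, n_variants = dplyr::n(),
                   auc = auc(.data$score, .data$label), .groups = "drop")
}

#' Balance classes within every gene
#'
#' Subsamples the majority class per gene (without replacement) so that
#' pathogenic and benign counts are equal at `min(n_p, n_b)`; genes with a
#' missing class drop out entirely.
#'
#' @param data Tibble with `gene` and `label`.
#' @param seed Integer seed for the subsampling.
#' @return The balanced subset of `data`.
#' @export
balance_per_gene <- function(data, seed = 1L) {
  withr_seed(seed, {
    data |>
      dplyr::group_by(.data$gene) |>
      dplyr::group_modify(function(df, key) {
        path <- as_pathogenic(df$label)
        k <- min(sum(path), sum(!path))
        if (k == 0L) return(df[0, ])
        take <- c(sample(which(path), k), sample(which(!path), k))
        df[sort(take), ]
      }) |>
      dplyr::ungroup()
  })
}

#' Calibrate raw scores to probabilities
#'
#' Fits a logistic regression of the pathogenic label on the raw score using
#' a small class-balanced calibration sample (default 1000 variants, 500 per
#' class, drawn without replacement when possible) and maps every score
#' monotonically to the probability of *pathogenic*; 0.5 is the induced
#' classification threshold, so on separable data the pathogenic class mean
#' is above 0.5 and the benign mean below.
#'
#' @param data Tibble with `score` and `label`.
#' @param n_calibration Calibration sample size (split equally by class).
#' @param seed Integer seed for the calibration sample.
#' @return `data` with a `calibrated` column (P(pathogenic) in `[0, 1]`).
#' @export
calibrate_scores <- function(data, n_calibration = 1000L, seed = 1L) {
  path <- as_pathogenic(data$label)
  idx_p <- which(path); idx_b <- which(!path)
  if (!length(idx_p) || !length(idx_b)) {
    abort("calibration needs both classes")
  }
  half <- n_calibration %/% 2L
  take <- withr_seed(seed, {
    c(sample(idx_p, half, replace = half > length(idx_p)),
      sample(idx_b, half, replace = half > length(idx_b)))
  })
  # separable calibration sets trip glm.fit's convergence warnings; the
  # fitted monotone map is still what the procedure calls for
  fit <- withCallingHandlers(
    glm(y ~ score,
        data = data.frame(y = path[take], score = data$score[take]),
        family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge",
                conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  dplyr::mutate(data, calibrated = as.numeric(
    predict(fit, newdata = data.frame(score = data$score),
            type = "response")))
}

#' Accuracy-coverage curve under symmetric threshold exclusion
#'
#' Scores are calibrated to P(pathogenic); for each exclusion half-width `t`
#' the variants with calibrated scores inside `(0.5 - t, 0.5 + t)` — the
#' ones the method is least certain about — are dropped, and the balanced
#' accuracy (mean of per-class accuracies at the 0.5 threshold) is computed
#' on the remainder. The whole procedure repeats over independently resampled
#' calibration sets.
#'
#' @param data Tibble with `score` and `label`.
#' @param thresholds Exclusion half-widths (default `seq(0, 0.45, 0.05)`).
#' @param repeats Calibration resamples (default 10).
#' @param n_calibration Calibration sample size per repeat.
#' @param seed Integer seed.
#' @return Tibble: `threshold`, `coverage`, `coverage_sd`, `accuracy`,
#'   `accuracy_sd` (means and sds over repeats; plot bands at +-2 sd).
#' @export
accuracy_coverage_curve <- function(data, thresholds = seq(0, 0.45, by = 0.05),
                                    repeats = 10L, n_calibration = 1000L,
                                    seed = 1L) {
  path <- as_pathogenic(data$label)
  per_rep <- purrr::map(seq_len(repeats), function(r) {
    cal <- calibrate_scores(data, n_calibration, seed = seed + r - 1L)
    purrr::map_dfr(thresholds, function(t) {
      keep <- cal$calibrated <= 0.5 - t | cal$calibrated >= 0.5 + t
      if (!any(keep)) {
        return(tibble::tibble(threshold = t, coverage = 0,
                              accuracy = NA_real_))
      }
      pred_path <- cal$calibrated[keep] >= 0.5
      truth <- path[keep]
      accs <- c(
        if (any(truth)) mean(pred_path[truth]),
        if (any(!truth)) mean(!pred_path[!truth]))
      tibble::tibble(threshold = t, coverage = mean(keep),
                     accuracy = mean(accs))
    })
  })
  dplyr::bind_rows(per_rep) |>
    dplyr::group_by(.data$threshold) |>
    dplyr::summarise(coverage_sd = sd(.data$coverage),
                     coverage = mean(.data$coverage),
                     accuracy_sd = sd(.data$accuracy),
                     accuracy = mean(.data$accuracy),
                     .groups = "drop") |>
    dplyr::select("threshold", "coverage", "coverage_sd",
                  "accuracy", "accuracy_sd")
}

#' Binary classification metrics at a probability threshold
#'
#' Computes AUC, area under the precision-recall curve, accuracy, diagnostic
#' odds ratio (with a +0.5 continuity correction applied to all cells when
#' any cell is zero), Matthews correlation coefficient and F1 from the
#' confusion table of calibrated scores at `threshold` (pathogenic is the
#' positive class).
#'
#' @param data Tibble with `calibrated` (P(pathogenic)) and `label`.
#' @param threshold Classification threshold (default 0.5).
#' @return One-row tibble of metrics.
#' @export
binary_metrics <- function(data, threshold = 0.5) {
  path <- as_pathogenic(data$label)
  pred <- data$calibrated >= threshold
  counts <- confusion_counts(pred, path)
  out <- confusion_metrics(counts$tp, counts$fp, counts$fn, counts$tn)
  out$auc <- auc(-data$calibrated, path)  # calibrated is pathogenic-high
  out$auprc <- auprc(data$calibrated, path)
  dplyr::select(out, "auc", "auprc", "accuracy", "dor", "mcc", "f1",
                dplyr::everything())
}

confusion_counts <- function(pred_positive, truth_positive) {
  list(tp = sum(pred_positive & truth_positive),
       fp = sum(pred_positive & !truth_positive),
       fn = sum(!pred_positive & truth_positive),
       tn = sum(!pred_positive & !truth_positive))
}

#' @rdname binary_metrics
#' @param tp,fp,fn,tn Confusion-table counts.
#' @export
confusion_metrics <- function(tp, fp, fn, tn) {
  n <- tp + fp + fn + tn
  accuracy <- (tp + tn) / n
  f1 <- if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den
  cells <- c(tp, fp, fn, tn)
  if (any(cells == 0)) cells <- cells + 0.5
  dor <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  tibble::tibble(accuracy = accuracy, f1 = f1, mcc = mcc, dor = dor,
                 tp = tp, fp = fp, fn = fn, tn = tn)
}

# step-wise average precision (positive class scored high)
auprc <- function(scores, positive) {
  ord <- order(scores, decreasing = TRUE)
  pos <- positive[ord]
  # process tied scores as blocks
  blocks <- cumsum(!duplicated(scores[ord]))
  tp <- cumsum(pos); k <- seq_along(pos)
  last_of_block <- !duplicated(blocks, fromLast = TRUE)
  tp_b <- tp[last_of_block]; k_b <- k[last_of_block]
  prec <- tp_b / k_b
  rec <- tp_b / sum(positive)
  sum(diff(c(0, rec)) * prec)
}

#' Absolute-deviation-from-wild-type transform for DMS measurements
#'
#' Some assays score deleterious variants on *both* sides of the wild-type
#' value; for those, measurements are replaced by `abs(x - WT)` (WT is 0 or
#' 1 by assay convention). On a data frame the transform is applied once per
#' assay and recorded in a `transformed` column; re-applying errors.
#'
#' @param x Numeric measurements, or an assay tibble with `measurement` and
#'   `wt_value` columns.
#' @param wt_value Wild-type measurement value (vector version only).
#' @return Transformed measurements (vector), or the tibble with
#'   `measurement` replaced and `transformed = TRUE`.
#' @export
apply_wt_transform <- function(x, wt_value = NULL) {
  if (is.data.frame(x)) {
    if ("transformed" %in% names(x) && isTRUE(x$transformed[1])) {
      abort("assay measurements were already WT-transformed")
    }
    return(dplyr::mutate(x,
                         measurement = abs(.data$measurement - .data$wt_value),
                         transformed = TRUE))
  }
  stopifnot(is.numeric(x), !is.null(wt_value))
  abs(x - wt_value)
}

#' Per-assay Spearman correlations and their aggregate
#'
#' Computes the Spearman correlation (average-rank ties) between a
#' prediction column and the experimental measurement within each assay.
#' Assays with constant measurements or predictions are skipped with a
#' warning. The aggregate is the unweighted mean over assays by default;
#' passing `group` (e.g. `"protein_id"`) averages within groups first, a
#' simple per-protein weighting hook.
#'
#' @param assays Assay tibble with `assay_id`, `measurement`, and the
#'   prediction column.
#' @param prediction Name of the prediction column (default `"prediction"`).
#' @param group Optional grouping column for the aggregate.
#' @return List with `per_assay` (tibble `assay_id`, `n`, `spearman`) and
#'   `aggregate` (scalar mean).
#' @export
dms_spearman <- function(assays, prediction = "prediction", group = NULL) {
  per_assay <- assays |>
    dplyr::group_by(.data$assay_id) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 2L || sd(df$measurement) == 0 ||
          sd(df[[prediction]]) == 0) {
        warn(sprintf("assay %s skipped (constant or too small)", key$assay_id))
        return(tibble::tibble(n = nrow(df), spearman = NA_real_))
      }
      tibble::tibble(n = nrow(df),
                     spearman = cor(df[[prediction]], df$measurement,
                                    method = "spearman"))
    }) |>
    dplyr::ungroup()
  kept <- dplyr::filter(per_assay, !is.na(.data$spearman))
  aggregate <- if (!is.null(group)) {
    key <- assays |>
      dplyr::distinct(.data$assay_id, .data[[group]])
    kept |>
      dplyr::left_join(key, by = "assay_id") |>
      dplyr::group_by(.data[[group]]) |>
      dplyr::summarise(s = mean(.data$spearman), .groups = "drop") |>
      dplyr::pull("s") |>
      mean()
  } else {
    mean(kept$spearman)
  }
  list(per_assay = per_assay, aggregate = aggregate)
}

#' Rank scores of models from their aggregate correlations
#'
#' Ascending ranks (1 = worst) with average ranks on ties.
#'
#' @param aggregates Named numeric vector of per-model aggregate
#'   correlations.
#' @return Tibble `model`, `aggregate`, `rank_score`.
#' @export
rank_score <- function(aggregates) {
  tibble::tibble(model = names(aggregates),
                 aggregate = unname(aggregates),
                 rank_score = unname(rank(aggregates)))
}

#' Pairwise win-rate matrix across assays
#'
#' `win_rate(m1, m2)` is the fraction of assays on which model `m1`'s
#' per-assay Spearman correlation *strictly* exceeds `m2`'s; ties credit
#' neither model, so `w(a, b) + w(b, a) = 1 - tie_fraction(a, b)` and the
#' diagonal is 0.
#'
#' @param rho Tibble with `assay_id`, `model`, `spearman` (every model on
#'   every assay).
#' @return M x M numeric matrix with model names on both dimensions.
#' @export
win_rate_matrix <- function(rho) {
  wide <- tidyr::pivot_wider(rho[c("assay_id", "model", "spearman")],
                             names_from = "model", values_from = "spearman")
  models <- setdiff(names(wide), "assay_id")
  S <- as.matrix(wide[models])
  if (anyNA(S)) abort("every model needs a correlation on every assay")
  M <- length(models)
  W <- matrix(0, M, M, dimnames = list(models, models))
  for (a in seq_len(M)) {
    for (b in seq_len(M)) {
      if (a != b) W[a, b] <- mean(S[, a] > S[, b])
    }
  }
  W
}

#' Minor allele frequency helpers
#'
#' `maf()` is `min(AF, 1 - AF)`, with missing allele frequencies set to 0
#' (variants absent from the population database are treated as maximally
#' rare). `maf_stratified_auc()` filters the labeled set to variants with
#' MAF strictly below each threshold and reports the balanced bootstrap AUC
#' per threshold.
#'
#' @param af Allele frequencies in `[0, 1]`; NA allowed.
#' @return For `maf()`, numeric MAF values.
#' @export
maf <- function(af) {
  out <- pmin(af, 1 - af)
  out[is.na(af)] <- 0
  out
}

#' @rdname maf
#' @param data Tibble with `score`, `label`, `af`.
#' @param thresholds MAF thresholds.
#' @param n_resamples,resample_size,seed Passed to
#'   [bootstrap_balanced_auc()].
#' @return For `maf_stratified_auc()`, a tibble with one row per threshold:
#'   `maf_threshold`, `n_retained`, `auc_mean`, `auc_sd`.
#' @export
maf_stratified_auc <- function(data, thresholds = c(1e-5, 1e-4, 1e-3, 1e-2, 1e-1),
                               n_resamples = 50L, resample_size = 2000L,
                               seed = 1L) {
  m <- maf(data$af)
  purrr::map_dfr(thresholds, function(t) {
    sub <- data[m < t, , drop = FALSE]
    res <- bootstrap_balanced_auc(sub, n_resamples, resample_size, seed)
    tibble::tibble(maf_threshold = t, n_retained = nrow(sub),
                   auc_mean = res$auc_mean, auc_sd = res$auc_sd)
  })
}

#' Plot an accuracy-coverage curve
#'
#' @param data Output of [accuracy_coverage_curve()].
#' @return A ggplot object.
#' @export
plot_accuracy_coverage <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(.data$coverage, .data$accuracy)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$accuracy - 2 * .data$accuracy_sd,
      ymax = .data$accuracy + 2 * .data$accuracy_sd), alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "coverage (fraction annotated)",
                  y = "balanced accuracy") +
    ggplot2::theme_minimal()
}
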