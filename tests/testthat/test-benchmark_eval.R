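test_that("AUC matches the exhaustive pairwise oracle, including ties", {
  set.seed(1)
  for (k in 1:10) {
    n <- sample(10:60, 1)
    scores <- round(rnorm(n), 1)  # rounding forces ties
    labels <- ifelse(runif(n) < 0.5, "pathogenic", "benign")
    if (length(unique(labels)) < 2) labels[1:2] <- c("pathogenic", "benign")
    expect_equal(auc(scores, labels), auc_oracle(scores, labels))
  }
  expect_equal(auc(c(-2, -1, 1, 2),
                   c("pathogenic", "pathogenic", "benign", "benign")), 1)
  expect_error(auc(1:3, rep("benign", 3)), "one class")
})

test_that("monotone transforms leave AUC and Spearman unchanged", {
  set.seed(2)
  scores <- rnorm(50)
  labels <- ifelse(scores + rnorm(50) > 0, "benign", "pathogenic")
  a0 <- auc(scores, labels)
  expect_equal(auc(exp(scores), labels), a0)
  expect_equal(auc(3 * scores - 7, labels), a0)
  x <- rnorm(30); y <- x + rnorm(30)
  expect_equal(cor(exp(x), y, method = "spearman"),
               cor(x, y, method = "spearman"))
})

test_that("balanced bootstrap AUC is seeded and degenerate for a perfect scorer", {
  perfect <- tibble::tibble(
    score = c(rnorm(300, 5), rnorm(300, -5)),
    label = rep(c("benign", "pathogenic"), each = 300))
  b <- bootstrap_balanced_auc(perfect, n_resamples = 20, resample_size = 200,
                              seed = 4)
  expect_equal(b$auc_mean, 1)
  expect_equal(b$auc_sd, 0)
  noisy <- tibble::tibble(
    score = c(rnorm(500, 1), rnorm(500, -1)),
    label = rep(c("benign", "pathogenic"), each = 500))
  b1 <- bootstrap_balanced_auc(noisy, 25, 400, seed = 7)
  b2 <- bootstrap_balanced_auc(noisy, 25, 400, seed = 7)
  expect_identical(b1, b2)
  b_small <- bootstrap_balanced_auc(noisy, 25, 50, seed = 7)
  expect_lt(b1$auc_sd, b_small$auc_sd)
})

test_that("per-gene AUC applies the variant-count and two-class filters", {
  set.seed(5)
  genes <- rep(paste0("g", 1:20), each = 15)
  df <- tibble::tibble(
    gene = genes,
    label = ifelse(runif(300) < 0.5, "pathogenic", "benign"))
  df$score <- ifelse(df$label == "benign", rnorm(300, 1), rnorm(300, -1))
  res <- per_gene_auc(df, min_variants = 10)
  # oracle loop
  for (g in unique(df$gene)) {
    sub <- df[df$gene == g, ]
    if (length(unique(sub$label)) == 2 && nrow(sub) >= 10) {
      expect_equal(res$auc[res$gene == g], auc_oracle(sub$score, sub$label))
    } else {
      expect_false(g %in% res$gene)
    }
  }
  # single qualifying gene: the mean is that gene's AUC
  one <- df[df$gene == "g1", ]
  r1 <- per_gene_auc(one, min_variants = 10)
  expect_equal(mean(r1$auc), auc_oracle(one$score, one$label))
  # raising the threshold never includes more genes
  expect_lte(nrow(per_gene_auc(df, min_variants = 16)), nrow(res))
})

test_that("per-gene balancing equalizes class counts and drops one-class genes", {
  df <- tibble::tibble(
    gene = c(rep("a", 8), rep("b", 6), rep("c", 4)),
    label = c(rep("pathogenic", 5), rep("benign", 3),
              rep("pathogenic", 3), rep("benign", 3),
              rep("pathogenic", 4)),
    score = rnorm(18))
  bal <- balance_per_gene(df, seed = 1)
  counts <- table(bal$gene, bal$label)
  expect_equal(unname(counts["a", ]), c(3, 3))
  expect_equal(unname(counts["b", ]), c(3, 3))
  expect_false("c" %in% bal$gene)
  expect_equal(nrow(bal), 2 * 3 + 2 * 3)
  # already balanced: unchanged up to identity
  bal2 <- balance_per_gene(bal, seed = 2)
  expect_equal(nrow(bal2), nrow(bal))
})

test_that("calibration is monotone (AUC-preserving) and correctly oriented", {
  set.seed(8)
  df <- tibble::tibble(
    score = c(rnorm(400, 2), rnorm(400, -2)),
    label = rep(c("benign", "pathogenic"), each = 400))
  cal <- calibrate_scores(df, n_calibration = 200, seed = 3)
  expect_true(all(cal$calibrated >= 0 & cal$calibrated <= 1))
  # calibrated = P(pathogenic): flips orientation, preserves ranking
  expect_equal(auc(-cal$calibrated, cal$label), auc(df$score, df$label))
  expect_gt(mean(cal$calibrated[cal$label == "pathogenic"]), 0.5)
  expect_lt(mean(cal$calibrated[cal$label == "benign"]), 0.5)
  expect_identical(calibrate_scores(df, 200, seed = 3)$calibrated,
                   cal$calibrated)
  expect_error(calibrate_scores(dplyr::filter(df, label == "benign"), 100),
               "both classes")
})

test_that("accuracy-coverage curves behave for perfect and imperfect scorers", {
  set.seed(9)
  perfect <- tibble::tibble(
    score = c(rnorm(300, 6), rnorm(300, -6)),
    label = rep(c("benign", "pathogenic"), each = 300))
  curve <- accuracy_coverage_curve(perfect, thresholds = seq(0, 0.4, 0.1),
                                   repeats = 4, n_calibration = 200, seed = 2)
  expect_true(all(abs(curve$accuracy - 1) < 1e-12))
  expect_equal(curve$coverage[curve$threshold == 0], 1)
  noisy <- tibble::tibble(
    score = c(rnorm(400, 1), rnorm(400, -1)),
    label = rep(c("benign", "pathogenic"), each = 400))
  curve2 <- accuracy_coverage_curve(noisy, thresholds = seq(0, 0.45, 0.05),
                                    repeats = 5, n_calibration = 300, seed = 5)
  expect_true(all(diff(curve2$coverage) <= 1e-12))
  expect_equal(curve2$coverage[1], 1)
})

test_that("binary metrics match hand arithmetic on a fixed confusion table", {
  m <- confusion_metrics(tp = 40, fp = 10, fn = 10, tn = 40)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$f1, 0.8)
  expect_equal(m$mcc, 0.6)
  expect_equal(m$dor, 16)
  all_right <- confusion_metrics(50, 0, 0, 50)
  expect_equal(all_right$accuracy, 1)
  expect_equal(all_right$mcc, 1)
  # swapping the label convention flips the MCC sign
  swapped <- confusion_metrics(tp = 10, fp = 40, fn = 40, tn = 10)
  expect_equal(swapped$mcc, -m$mcc)
  # continuity correction keeps DOR finite on zero cells
  expect_true(is.finite(confusion_metrics(10, 0, 5, 20)$dor))
})

test_that("binary_metrics computes the table from calibrated probabilities", {
  df <- tibble::tibble(
    calibrated = c(0.9, 0.8, 0.7, 0.2, 0.1, 0.4),
    label = c("pathogenic", "pathogenic", "benign",
              "benign", "benign", "pathogenic"))
  m <- binary_metrics(df)
  expect_equal(c(m$tp, m$fp, m$fn, m$tn), c(2, 1, 1, 2))
  expect_equal(m$accuracy, 4 / 6)
  expect_equal(m$auc, auc_oracle(-df$calibrated, df$label))
})

test_that("average precision matches a hand-computed small case", {
  # scores descending: P, B, P, B with pathogenic positive
  # precision at the two positives: 1/1 and 2/3; AP = 0.5 * 1 + 0.5 * 2/3
  scores <- c(0.9, 0.8, 0.6, 0.3)
  pos <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(maxvep:::auprc(scores, pos), 0.5 * 1 + 0.5 * 2 / 3)
})

test_that("the WT transform is the absolute deviation, applied exactly once", {
  expect_equal(apply_wt_transform(1.4, 1), 0.4)
  expect_equal(apply_wt_transform(-0.3, 0), 0.3)
  df <- tibble::tibble(measurement = c(1.4, 0.6), wt_value = 1)
  tr <- apply_wt_transform(df)
  expect_equal(tr$measurement, c(0.4, 0.4))
  expect_error(apply_wt_transform(tr), "already")
})

test_that("per-assay Spearman matches an independent rank computation", {
  set.seed(10)
  assays <- purrr::map_dfr(1:10, function(i) {
    n <- 30
    meas <- rnorm(n)
    tibble::tibble(assay_id = paste0("a", i), measurement = meas,
                   prediction = 0.6 * meas + rnorm(n, 0, 0.8))
  })
  res <- dms_spearman(assays)
  for (i in 1:10) {
    sub <- assays[assays$assay_id == paste0("a", i), ]
    oracle <- cor(rank(sub$prediction), rank(sub$measurement))
    expect_equal(res$per_assay$spearman[res$per_assay$assay_id == paste0("a", i)],
                 oracle, tolerance = 1e-12)
  }
  expect_equal(res$aggregate, mean(res$per_assay$spearman))
  # perfect and anti-monotone predictions
  p1 <- tibble::tibble(assay_id = "x", measurement = 1:10, prediction = (1:10)^2)
  expect_equal(dms_spearman(p1)$aggregate, 1)
  p2 <- tibble::tibble(assay_id = "x", measurement = 1:10, prediction = -(1:10))
  expect_equal(dms_spearman(p2)$aggregate, -1)
  # constant assays are skipped with a warning
  p3 <- tibble::tibble(assay_id = "x", measurement = rep(1, 5), prediction = 1:5)
  expect_warning(r3 <- dms_spearman(p3), "skipped")
  expect_true(is.na(r3$per_assay$spearman))
})

test_that("win rates use strict inequality and match the double-loop oracle", {
  # model m1 better everywhere
  rho <- tidyr::expand_grid(assay_id = paste0("a", 1:5),
                            model = c("m1", "m2")) |>
    dplyr::mutate(spearman = ifelse(model == "m1", 0.8, 0.5))
  W <- win_rate_matrix(rho)
  expect_equal(W["m1", "m2"], 1)
  expect_equal(W["m2", "m1"], 0)
  # identical vectors: all ties, both zero
  rho2 <- dplyr::mutate(rho, spearman = 0.5)
  W2 <- win_rate_matrix(rho2)
  expect_equal(W2["m1", "m2"], 0)
  expect_equal(W2["m2", "m1"], 0)
  # random 3 x 20 table vs oracle
  set.seed(11)
  rho3 <- tidyr::expand_grid(assay_id = paste0("a", 1:20),
                             model = c("x", "y", "z")) |>
    dplyr::mutate(spearman = round(runif(60), 1))
  W3 <- win_rate_matrix(rho3)
  S <- tidyr::pivot_wider(rho3, names_from = model, values_from = spearman)
  for (a in c("x", "y", "z")) for (b in c("x", "y", "z")) {
    if (a == b) {
      expect_equal(W3[a, b], 0)
    } else {
      expect_equal(W3[a, b], mean(S[[a]] > S[[b]]))
      ties <- mean(S[[a]] == S[[b]])
      expect_equal(W3[a, b] + W3[b, a], 1 - ties)
    }
  }
})

test_that("rank scores rise with the aggregate and average over ties", {
  rs <- rank_score(c(a = 0.3, b = 0.5, c = 0.5, d = 0.1))
  expect_equal(rs$rank_score, c(2, 3.5, 3.5, 1))
})

test_that("MAF formula and missing-AF rule are applied before stratification", {
  expect_equal(maf(c(0.3, 0.9, NA, 0, 1)), c(0.3, 0.1, 0, 0, 0))
  set.seed(12)
  df <- tibble::tibble(
    score = c(rnorm(400, 1.5), rnorm(400, -1.5)),
    label = rep(c("benign", "pathogenic"), each = 400),
    af = c(rbeta(400, 2, 20), rbeta(400, 1, 200)))
  df$af[sample(800, 80)] <- NA
  strat <- maf_stratified_auc(df, thresholds = c(1e-3, 1e-2, 1e-1, 0.5),
                              n_resamples = 10, resample_size = 200, seed = 3)
  expect_true(all(diff(strat$n_retained) >= 0))
  expect_true(all(strat$auc_mean > 0.9))
})
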