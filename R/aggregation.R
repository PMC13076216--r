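#' Align LLR matrices from several scorers into a stack
#'
#' @param matrices List of [llr_matrix()] objects for the *same* protein
#'   (identical shape and masking).
#' @param models Character vector of model names (defaults to list names or
#'   `model1..M`).
#' @return A `score_stack` object.
#' @export
score_stack <- function(matrices, models = NULL) {
  if (!length(matrices)) abort("a score stack needs at least one matrix")
  models <- models %||% names(matrices) %||%
    paste0("model", seq_along(matrices))
  stopifnot(length(models) == length(matrices))
  ref <- matrices[[1]]
  for (m in matrices[-1]) {
    if (!identical(dim(m), dim(ref)) ||
        !identical(llr_sequence(m), llr_sequence(ref))) {
      abort("all matrices in a stack must share protein and shape")
    }
    if (!identical(llr_mask(m), llr_mask(ref))) {
      abort("all matrices in a stack must share the missing-score mask")
    }
  }
  structure(list(matrices = matrices, models = as.character(models),
                 protein_id = llr_protein_id(ref)),
            class = "score_stack")
}

#' @export
print.score_stack <- function(x, ...) {
  cat(sprintf("<score_stack> %s: %d models x (%d x 20)\n", x$protein_id,
              length(x$models), nrow(x$matrices[[1]])))
  invisible(x)
}

stack_array <- function(stack) {
  # M x L x 20 array
  vapply(stack$matrices, function(m) unclass(m),
         matrix(0, nrow(stack$matrices[[1]]), 20L)) |>
    aperm(c(3L, 1L, 2L))
}

#' Aggregate a score stack across models
#'
#' `aggregate_min()` is the maximum-confidence rule: every variant takes the
#' minimum LLR across models, i.e. the prediction of the model most confident
#' that the wild-type residue matters at that position. `aggregate_mean()`
#' takes the arithmetic mean instead (the rule used to average two final
#' models into a combined predictor). Wild-type entries stay 0 and masked
#' entries stay masked.
#'
#' @param stack A [score_stack()].
#' @return An `llr_aggregate` object: the aggregated [llr_matrix()], the
#'   aggregator tag, and (min mode) the per-entry argmin model index with
#'   ties broken toward the lowest model index.
#' @export
#' @examples
#' p <- protein_record("P1", "MKTAY")
#' a <- score_llr(uniform_scorer(), p)
#' agg <- aggregate_min(score_stack(list(m1 = a, m2 = a)))
#' all(agg$llr == 0)
aggregate_min <- function(stack) {
  stopifnot(inherits(stack, "score_stack"))
  arr <- stack_array(stack)
  ref <- stack$matrices[[1]]
  vals <- apply(arr, c(2L, 3L), function(v) {
    if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)
  })
  argmin <- apply(arr, c(2L, 3L), function(v) {
    if (all(is.na(v))) NA_integer_ else which.min(v)
  })
  wt <- wt_cells(ref)
  vals[wt] <- 0
  out <- new_llr_matrix(vals, stack$protein_id, llr_sequence(ref),
                        llr_mask(ref) | is.na(vals))
  structure(list(llr = out, aggregator = "min", argmin = argmin,
                 models = stack$models),
            class = "llr_aggregate")
}

#' @rdname aggregate_min
#' @export
aggregate_mean <- function(stack) {
  stopifnot(inherits(stack, "score_stack"))
  arr <- stack_array(stack)
  ref <- stack$matrices[[1]]
  vals <- apply(arr, c(2L, 3L), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  wt <- wt_cells(ref)
  vals[wt] <- 0
  out <- new_llr_matrix(vals, stack$protein_id, llr_sequence(ref),
                        llr_mask(ref) | is.na(vals))
  structure(list(llr = out, aggregator = "mean", argmin = NULL,
                 models = stack$models),
            class = "llr_aggregate")
}

#' @export
print.llr_aggregate <- function(x, ...) {
  cat(sprintf("<llr_aggregate> %s over %d models (%s)\n", x$aggregator,
              length(x$models), x$llr |> llr_protein_id()))
  invisible(x)
}

#' Fraction of variants each model contributes to a min-aggregate
#'
#' Over all unmasked, non-wild-type entries, the fraction of entries whose
#' argmin points at each model (ties were already resolved toward the lowest
#' model index during aggregation). Fractions sum to 1.
#'
#' @param result An `llr_aggregate` in `min` mode.
#' @return Tibble with `model` and `fraction`.
#' @export
model_contributions <- function(result) {
  stopifnot(inherits(result, "llr_aggregate"))
  if (!identical(result$aggregator, "min")) {
    abort("model contributions are defined for min-mode aggregates only")
  }
  keep <- !llr_mask(result$llr) & !wt_cells(result$llr)
  idx <- result$argmin[keep]
  counts <- tabulate(idx, nbins = length(result$models))
  tibble::tibble(model = result$models,
                 fraction = counts / sum(counts))
}

#' Filter out noninformative protein segments
#'
#' Each segment is summarized by the minimum aggregated score over all its
#' variant positions *excluding the first position* (the initiator
#' methionine). Segments whose minimum is above the 95th percentile of the
#' per-segment minimum distribution — segments where even the most damaging
#' predicted variant looks neutral — are dropped.
#'
#' @param segments Data frame with a segment `id` column and `min_score`
#'   column (per-segment minimum, first position excluded), or a named
#'   numeric vector of per-segment minima. Use [segment_min_score()] to
#'   compute the statistic from a matrix.
#' @param percentile Percentile threshold (default 0.95), computed with the
#'   linear-interpolation convention (`quantile(type = 7)`).
#' @return Tibble of the kept segments with a `kept` flag for all inputs.
#' @export
filter_segments <- function(segments, percentile = 0.95) {
  if (is.numeric(segments)) {
    segments <- tibble::tibble(
      id = names(segments) %||% as.character(seq_along(segments)),
      min_score = unname(segments))
  }
  stopifnot(all(c("id", "min_score") %in% names(segments)))
  if (!nrow(segments)) abort("no segments to filter")
  cut <- quantile(segments$min_score, percentile, type = 7, names = FALSE)
  dplyr::mutate(tibble::as_tibble(segments),
                kept = .data$min_score <= cut)
}

#' @rdname filter_segments
#' @param matrix An [llr_matrix()] for one segment.
#' @export
segment_min_score <- function(matrix) {
  stopifnot(inherits(matrix, "llr_matrix"))
  keep <- !llr_mask(matrix) & !wt_cells(matrix)
  keep[1L, ] <- FALSE  # exclude the first position from the statistic
  if (!any(keep)) return(NA_real_)
  min(unclass(matrix)[keep])
}

#' Shift target scores to match a base model's empirical mean
#'
#' Before distillation the aggregated target grid is shifted by a constant so
#' its mean over unmasked non-wild-type entries equals the base model's
#' empirical mean over the same entries; the shift is computed once and held
#' fixed. The shift applies to non-wild-type entries only; wild-type entries
#' are excluded from the mean computation and stay exactly 0.
#'
#' @param targets Target [llr_matrix()] (e.g. a min-aggregate).
#' @param base_mean Scalar mean of the base model over unmasked non-WT
#'   entries (see [llr_mean()]).
#' @return List with the shifted `targets` ([llr_matrix()]) and the constant
#'   `shift` applied.
#' @export
mean_shift_targets <- function(targets, base_mean) {
  stopifnot(inherits(targets, "llr_matrix"), is.numeric(base_mean))
  m <- llr_mean(targets)
  if (is.na(m)) abort("targets have no unmasked non-wild-type entries")
  shift <- base_mean - m
  keep <- !llr_mask(targets) & !wt_cells(targets)
  vals <- unclass(targets)
  vals[keep] <- vals[keep] + shift
  out <- new_llr_matrix(vals, llr_protein_id(targets), llr_sequence(targets),
                        llr_mask(targets))
  list(targets = out, shift = shift)
}

#' Mean LLR over unmasked non-wild-type entries
#'
#' @param x An [llr_matrix()] or list of them (pooled mean).
#' @return Scalar mean (NA if no eligible entries).
#' @export
llr_mean <- function(x) {
  if (inherits(x, "llr_matrix")) x <- list(x)
  vals <- unlist(lapply(x, function(m) {
    keep <- !llr_mask(m) & !wt_cells(m)
    unclass(m)[keep]
  }))
  if (!length(vals)) return(NA_real_)
  mean(vals)
}
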