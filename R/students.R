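#' Window-linear student scorers
#'
#' A toy trainable scorer honoring the student contract: it can (a) score any
#' protein into an LLR matrix and (b) take gradient fit-steps against target
#' LLR matrices under a masked MSE loss. Mirroring how language-model
#' scorers work, the student predicts a per-position *logit* for each amino
#' acid — a linear function of the one-hot encoding of the wild-type letters
#' in a window of `radius` residues around the position (plus an intercept
#' and, optionally, per-position indicators) — and emits
#' `LLR(t, a) = logit(t, a) - logit(t, wt_t)`, so wild-type entries are 0 by
#' construction and the whole map stays linear in the weights. A heavyweight
#' model (e.g. a transformer protein language model) can stand in anywhere a
#' student is accepted by implementing [score_llr()] and
#' [student_fit_step()].
#'
#' @param radius Window radius in residues (features per output:
#'   `20 * (2 * radius + 1) + 1`, plus `length` positional features when
#'   positional).
#' @param length Optional protein length: when given, the student also gets
#'   one indicator feature per position (a per-position parametric model),
#'   raising capacity for fixed-length protein families; positions beyond
#'   `length` simply lack the feature. `NULL` = purely local model (the
#'   capacity-limited variant).
#' @param name Student name.
#' @param init_sd Standard deviation of the random weight initialization
#'   (0 = all-zero weights, fully deterministic).
#' @param seed Seed for the random initialization.
#' @return A `window_student` object.
#' @export
window_student <- function(radius = 2L, length = NULL, name = "student",
                           init_sd = 0, seed = 1L) {
  radius <- as.integer(radius)
  stopifnot(radius >= 0L)
  n_pos <- if (is.null(length)) 0L else as.integer(length)
  p <- 20L * (2L * radius + 1L) + 1L + n_pos
  W <- if (init_sd > 0) {
    withr_seed(seed, matrix(rnorm(p * 20L, 0, init_sd), nrow = p))
  } else {
    matrix(0, nrow = p, ncol = 20L)
  }
  structure(list(W = W, V = matrix(0, nrow = p, ncol = 20L),
                 radius = radius, n_pos = n_pos, version = 1L),
            name = name, class = c("window_student", "vep_student"))
}

#' @export
print.window_student <- function(x, ...) {
  cat(sprintf("<window_student> %s: radius %d, %d parameters\n",
              scorer_name(x), x$radius, length(x$W)))
  invisible(x)
}

# L x p design matrix: intercept + one-hot window letters + position indicators
window_features <- function(sequence, radius, n_pos = 0L) {
  chars <- seq_chars(sequence)
  L <- length(chars)
  idx <- aa_index(chars)
  p_win <- 20L * (2L * radius + 1L) + 1L
  X <- matrix(0, nrow = L, ncol = p_win + n_pos)
  X[, 1L] <- 1
  offs <- seq.int(-radius, radius)
  for (k in seq_along(offs)) {
    src <- seq_len(L) + offs[k]
    ok <- src >= 1L & src <= L & !is.na(idx[pmin(pmax(src, 1L), L)])
    cols <- 1L + (k - 1L) * 20L + idx[src[ok]]
    X[cbind(which(ok), cols)] <- 1
  }
  if (n_pos > 0L) {
    t_ok <- seq_len(min(L, n_pos))
    X[cbind(t_ok, p_win + t_ok)] <- 1
  }
  X
}

#' @export
score_llr.window_student <- function(scorer, protein, window = 1022L,
                                     overlap = 511L) {
  protein <- as_protein(protein)
  chars <- seq_chars(protein$sequence)
  X <- window_features(protein$sequence, scorer$radius, scorer$n_pos)
  P <- X %*% scorer$W
  idx <- aa_index(chars)
  mask <- matrix(FALSE, nrow = length(chars), ncol = 20L)
  ok <- !is.na(idx)
  vals <- P
  if (any(ok)) {
    wt_logit <- P[cbind(which(ok), idx[ok])]
    vals[ok, ] <- P[ok, , drop = FALSE] - wt_logit
    vals[cbind(which(ok), idx[ok])] <- 0
  }
  if (any(!ok)) {
    mask[!ok, ] <- TRUE
    vals[!ok, ] <- NA_real_
  }
  new_llr_matrix(vals, protein$id, protein$sequence, mask)
}

#' One full-batch gradient step on the masked MSE
#'
#' Generic so that other student implementations can plug in. For
#' [window_student()], `batch` is the prepared design/target pair from the
#' trainer and the step is plain gradient descent on
#' `mean((X W - Y)[unmasked non-WT])^2`.
#'
#' @param student Student object.
#' @param batch List with `X` (stacked design), `Y` (stacked targets) and
#'   `M` (logical matrix, TRUE = entry enters the loss).
#' @param lr Learning-rate scalar.
#' @param momentum Heavy-ball momentum coefficient in `[0, 1)`.
#' @return List with the updated `student` and the scalar `loss` *before*
#'   the step.
#' @export
student_fit_step <- function(student, batch, lr, momentum = 0) {
  UseMethod("student_fit_step")
}

# predicted LLRs for a stacked batch: logits minus the per-row WT logit
batch_llr <- function(student, batch) {
  P <- batch$X %*% student$W
  wt <- batch$wt_idx
  ok <- !is.na(wt)
  wt_logit <- numeric(nrow(P))
  wt_logit[ok] <- P[cbind(which(ok), wt[ok])]
  P - wt_logit
}

#' @export
student_fit_step.window_student <- function(student, batch, lr, momentum = 0) {
  R <- batch_llr(student, batch) - batch$Y
  R[!batch$M] <- 0
  n <- sum(batch$M)
  loss <- sum(R^2) / n
  if (!is.finite(loss)) abort("training diverged: non-finite loss")
  # gradient w.r.t. logits: residual, with -rowSum placed on the WT column
  G <- R
  ok <- !is.na(batch$wt_idx)
  G[cbind(which(ok), batch$wt_idx[ok])] <- -rowSums(R[ok, , drop = FALSE])
  grad <- 2 * crossprod(batch$X, G) / n
  student$V <- momentum * student$V - lr * grad
  student$W <- student$W + student$V
  list(student = student, loss = loss)
}

# stack design/target matrices for a set of proteins and per-protein targets
student_batch <- function(student, proteins, target_list) {
  Xs <- list(); Ys <- list(); Ms <- list(); Ws <- list()
  for (i in seq_len(nrow(proteins))) {
    id <- proteins$id[i]
    tgt <- target_list[[id]]
    if (is.null(tgt)) abort(sprintf("no targets for protein %s", id))
    X <- window_features(proteins$sequence[i], student$radius, student$n_pos)
    Y <- unclass(tgt)
    M <- !llr_mask(tgt) & !wt_cells(tgt)
    Y[!M] <- 0
    Xs[[i]] <- X; Ys[[i]] <- Y; Ms[[i]] <- M
    Ws[[i]] <- aa_index(seq_chars(proteins$sequence[i]))
  }
  list(X = do.call(rbind, Xs), Y = do.call(rbind, Ys),
       M = do.call(rbind, Ms), wt_idx = unlist(Ws))
}

masked_mse <- function(student, batch) {
  R <- batch_llr(student, batch) - batch$Y
  R[!batch$M] <- 0
  sum(R^2) / sum(batch$M)
}
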