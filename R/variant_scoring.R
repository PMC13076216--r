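#' LLR matrices
#'
#' The central per-protein object: an L x 20 grid of substitution
#' log-likelihood ratios
#' `LLR(t, a) = log p(x_t = a | x) - log p(x_t = wt_t | x)`
#' computed from a single wild-type forward pass. Entries at the wild-type
#' letter are exactly 0; higher scores are more benign, strongly negative
#' scores damaging. Rows whose wild-type letter is nonstandard are masked.
#'
#' @param logprobs L x 20 natural-log probability matrix from
#'   [score_position_logprobs()].
#' @param protein Protein record or sequence string (must match `logprobs`
#'   length).
#' @return An object of class `llr_matrix`: a numeric L x 20 matrix with
#'   attributes `protein_id`, `sequence` and a logical `mask` (TRUE where no
#'   score is available).
#' @export
#' @examples
#' p <- protein_record("P1", "MKTAY")
#' m <- llr_matrix(score_position_logprobs(uniform_scorer(), p), p)
#' all(m == 0)
llr_matrix <- function(logprobs, protein) {
  protein <- as_protein(protein)
  chars <- seq_chars(protein$sequence)
  L <- length(chars)
  lp <- as.matrix(logprobs)
  if (nrow(lp) != L || ncol(lp) != 20L) {
    abort(sprintf("logprobs are %d x %d but protein has length %d",
                  nrow(lp), ncol(lp), L))
  }
  idx <- aa_index(chars)
  scores <- matrix(0, nrow = L, ncol = 20L, dimnames = list(NULL, AA_ALPHABET))
  mask <- matrix(FALSE, nrow = L, ncol = 20L)
  ok <- !is.na(idx)
  if (any(!ok)) {
    warn(sprintf("protein %s: %d position(s) with nonstandard letters masked",
                 protein$id, sum(!ok)))
    mask[!ok, ] <- TRUE
    scores[!ok, ] <- NA_real_
  }
  if (any(ok)) {
    wt_lp <- lp[cbind(which(ok), idx[ok])]
    scores[ok, ] <- lp[ok, , drop = FALSE] - wt_lp
    scores[cbind(which(ok), idx[ok])] <- 0  # exact zero at the WT letter
  }
  new_llr_matrix(scores, protein$id, protein$sequence, mask)
}

new_llr_matrix <- function(scores, protein_id, sequence, mask) {
  dimnames(scores) <- NULL
  dimnames(mask) <- NULL
  colnames(scores) <- AA_ALPHABET
  structure(scores,
            protein_id = protein_id, sequence = sequence, mask = mask,
            class = c("llr_matrix", class(matrix())))
}

#' @export
print.llr_matrix <- function(x, ...) {
  cat(sprintf("<llr_matrix> %s: %d positions x 20 amino acids (%d masked entries)\n",
              attr(x, "protein_id"), nrow(x), sum(attr(x, "mask"))))
  invisible(x)
}

llr_mask <- function(x) attr(x, "mask")
llr_protein_id <- function(x) attr(x, "protein_id")
llr_sequence <- function(x) attr(x, "sequence")

# logical matrix marking the WT letter cell of each unmasked position
wt_cells <- function(x) {
  chars <- seq_chars(llr_sequence(x))
  idx <- aa_index(chars)
  wt <- matrix(FALSE, nrow = nrow(x), ncol = 20L)
  ok <- !is.na(idx)
  wt[cbind(which(ok), idx[ok])] <- TRUE
  wt
}

#' Score a protein with a scorer, segmenting long sequences
#'
#' Runs the scorer and assembles the full LLR matrix. Proteins longer than
#' `window` are segmented into overlapping sliding windows (defaults: 1022
#' residues with 511 overlap), each window is scored independently, and the
#' per-position scores are stitched back (each position keeps the score from
#' the window in which it is most central).
#'
#' @param scorer Scorer or student object.
#' @param protein Protein record or sequence string.
#' @param window,overlap Sliding-window parameters; see [plan_segments()].
#' @return An [llr_matrix()].
#' @export
score_llr <- function(scorer, protein, window = 1022L, overlap = 511L) {
  UseMethod("score_llr")
}

#' @export
score_llr.default <- function(scorer, protein, window = 1022L, overlap = 511L) {
  protein <- as_protein(protein)
  L <- nchar(protein$sequence)
  plan <- plan_segments(L, window = window, overlap = overlap)
  if (nrow(plan) == 1L) {
    return(llr_matrix(score_position_logprobs(scorer, protein), protein))
  }
  mats <- purrr::pmap(plan, function(start, end) {
    sub <- list(id = protein$id,
                sequence = substr(protein$sequence, start, end))
    llr_matrix(score_position_logprobs(scorer, sub), sub)
  })
  stitch_segments(mats, plan, protein)
}

#' Plan sliding windows over a long protein
#'
#' @param L Protein length.
#' @param window Window size in residues (default 1022).
#' @param overlap Overlap between consecutive windows (default 511); must be
#'   smaller than `window`.
#' @return Tibble with 1-based inclusive `start`, `end` columns. A protein
#'   with `L <= window` gets the single window `[1, L]`; otherwise windows
#'   advance by `window - overlap` and the last window is anchored to end at
#'   `L` (so it may overlap its predecessor by more than `overlap`).
#' @export
#' @examples
#' plan_segments(2000)
plan_segments <- function(L, window = 1022L, overlap = 511L) {
  L <- as.integer(L); window <- as.integer(window); overlap <- as.integer(overlap)
  stopifnot(L >= 1L, window >= 1L, overlap >= 0L)
  if (overlap >= window) abort("overlap must be smaller than window")
  if (L <= window) {
    return(tibble::tibble(start = 1L, end = L))
  }
  stride <- window - overlap
  starts <- seq.int(1L, L - window, by = stride)
  last <- L - window + 1L
  if (tail(starts, 1L) != last) starts <- c(starts, last)
  tibble::tibble(start = starts, end = starts + window - 1L)
}

#' Stitch per-window LLR matrices into a full-length matrix
#'
#' Every position of the full protein takes the score row from the window in
#' which it is most central (smallest distance to the window midpoint); ties
#' go to the earlier window.
#'
#' @param segment_matrices List of [llr_matrix()] objects, one per window of
#'   `plan`, each scored on the corresponding subsequence.
#' @param plan Segment plan from [plan_segments()].
#' @param protein Full-length protein record.
#' @return Full-length [llr_matrix()].
#' @export
stitch_segments <- function(segment_matrices, plan, protein) {
  protein <- as_protein(protein)
  L <- nchar(protein$sequence)
  if (length(segment_matrices) != nrow(plan)) {
    abort("need exactly one scored matrix per planned window")
  }
  widths <- plan$end - plan$start + 1L
  for (i in seq_along(segment_matrices)) {
    if (nrow(segment_matrices[[i]]) != widths[i]) {
      abort(sprintf("window %d matrix has %d rows, plan expects %d",
                    i, nrow(segment_matrices[[i]]), widths[i]))
    }
  }
  centers <- (plan$start + plan$end) / 2
  scores <- matrix(NA_real_, nrow = L, ncol = 20L)
  mask <- matrix(TRUE, nrow = L, ncol = 20L)
  pos <- seq_len(L)
  dist <- abs(outer(pos, centers, `-`))
  pick <- apply(dist, 1L, which.min)  # which.min takes the earliest tie
  for (w in seq_len(nrow(plan))) {
    rows <- which(pick == w)
    if (!length(rows)) next
    local <- rows - plan$start[w] + 1L
    scores[rows, ] <- segment_matrices[[w]][local, , drop = FALSE]
    mask[rows, ] <- llr_mask(segment_matrices[[w]])[local, , drop = FALSE]
  }
  new_llr_matrix(scores, protein$id, protein$sequence, mask)
}

#' Look up the LLR of one substitution
#'
#' @param matrix An [llr_matrix()].
#' @param position 1-based residue position.
#' @param ref_aa Reference (wild-type) amino acid; must match the protein
#'   sequence at `position` — a mismatch signals coordinate or isoform
#'   problems and errors.
#' @param alt_aa Alternate amino acid.
#' @return Numeric score (0 when `ref_aa == alt_aa`; NA for masked entries).
#' @export
variant_score <- function(matrix, position, ref_aa, alt_aa) {
  stopifnot(inherits(matrix, "llr_matrix"))
  L <- nrow(matrix)
  if (!is.numeric(position) || position < 1 || position > L) {
    abort(sprintf("position %s outside [1, %d]", toString(position), L))
  }
  wt <- substr(llr_sequence(matrix), position, position)
  if (!identical(toupper(ref_aa), wt)) {
    abort(sprintf(
      "reference mismatch at position %d: matrix has %s, query has %s",
      position, wt, ref_aa))
  }
  if (identical(toupper(ref_aa), toupper(alt_aa))) return(0)
  col <- aa_index(toupper(alt_aa))
  if (is.na(col)) abort(sprintf("alt amino acid %s not in alphabet", alt_aa))
  if (llr_mask(matrix)[position, col]) return(NA_real_)
  unname(matrix[position, col])
}

#' Tidy an LLR matrix into a long tibble
#'
#' @param x An [llr_matrix()].
#' @param wt Keep wild-type (ref == alt) rows? Default FALSE.
#' @param ... Unused.
#' @return Tibble with `protein_id`, `position`, `ref_aa`, `alt_aa`, `score`
#'   (NA where masked).
#' @export
tidy.llr_matrix <- function(x, wt = FALSE, ...) {
  chars <- seq_chars(llr_sequence(x))
  out <- tibble::tibble(
    protein_id = llr_protein_id(x),
    position = rep(seq_len(nrow(x)), each = 20L),
    ref_aa = rep(chars, each = 20L),
    alt_aa = rep(AA_ALPHABET, nrow(x)),
    score = as.vector(t(unclass(x)))
  )
  if (!wt) out <- dplyr::filter(out, .data$ref_aa != .data$alt_aa)
  out
}

#' Heat map of an LLR matrix
#'
#' @param object An [llr_matrix()].
#' @param ... Unused.
#' @return A ggplot object (position on x, amino acid on y, score as fill).
#' @export
autoplot.llr_matrix <- function(object, ...) {
  df <- tidy(object, wt = TRUE)
  ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$alt_aa,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey80") +
    ggplot2::labs(x = "position", y = "amino acid", fill = "LLR",
                  title = llr_protein_id(object)) +
    ggplot2::theme_minimal()
}

#' Read and write LLR score tables
#'
#' Long-format TSV with columns `protein_id`, `position`, `ref_aa`,
#' `alt_aa`, `score` (and optionally `model`); masked entries are written
#' with an empty score. [write_llr_wide_csv()] emits the companion
#' wide format (one row per position, 20 amino-acid columns).
#'
#' @param x An [llr_matrix()].
#' @param path File path.
#' @param model Optional model name column to add.
#' @param append Append to an existing file (no header)?
#' @return `path` invisibly for writers; for [read_llr_tsv()] a tibble of all
#'   rows; [collect_llr_matrix()] rebuilds an [llr_matrix()] from such a
#'   tibble for one protein (and one model, if a model column is present).
#' @export
write_llr_tsv <- function(x, path, model = NULL, append = FALSE) {
  df <- tidy(x, wt = FALSE)
  if (!is.null(model)) df <- dplyr::mutate(df, model = model, .before = 1L)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = !append, append = append, na = "")
  invisible(path)
}

#' @rdname write_llr_tsv
#' @export
read_llr_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = c("", "NA", "."),
                          comment.char = "#")
  tibble::as_tibble(df)
}

#' @rdname write_llr_tsv
#' @param scores Long tibble with `position`, `ref_aa`, `alt_aa`, `score`
#'   for a single protein.
#' @param protein_id Id to record on the rebuilt matrix.
#' @export
collect_llr_matrix <- function(scores, protein_id = NULL) {
  stopifnot(all(c("position", "ref_aa", "alt_aa", "score") %in% names(scores)))
  protein_id <- protein_id %||% scores$protein_id[1] %||% "protein"
  L <- max(scores$position)
  ref <- character(L)
  ref[scores$position] <- scores$ref_aa
  sequence <- paste(ref, collapse = "")
  mat <- matrix(0, nrow = L, ncol = 20L)
  mask <- matrix(FALSE, nrow = L, ncol = 20L)
  col <- aa_index(scores$alt_aa)
  mat[cbind(scores$position, col)] <- scores$score
  na_rows <- is.na(scores$score)
  mask[cbind(scores$position[na_rows], col[na_rows])] <- TRUE
  # positions whose WT letter is nonstandard are fully masked
  bad <- which(is.na(aa_index(ref)) | ref == "")
  if (length(bad)) {
    mask[bad, ] <- TRUE
    mat[bad, ] <- NA_real_
    ref[ref == ""] <- "X"
    sequence <- paste(ref, collapse = "")
  }
  mat[is.na(mat) & !mask] <- 0
  new_llr_matrix(mat, protein_id, sequence, mask)
}

#' @rdname write_llr_tsv
#' @export
write_llr_wide_csv <- function(x, path) {
  df <- data.frame(position = seq_len(nrow(x)),
                   ref_aa = seq_chars(llr_sequence(x)),
                   unclass(x), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_llr_tsv
#' @export
read_llr_wide_csv <- function(path, protein_id = "protein") {
  df <- utils::read.csv(path, check.names = FALSE, na.strings = c("", "NA"))
  mat <- as.matrix(df[, AA_ALPHABET])
  mask <- is.na(mat)
  sequence <- paste(df$ref_aa, collapse = "")
  new_llr_matrix(mat, protein_id, sequence, mask)
}
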