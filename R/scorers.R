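#' Scorer objects
#'
#' A *scorer* is anything that, given a protein sequence, returns one
#' probability distribution over the 20 canonical amino acids per position
#' (the wild-type-marginal scheme: a single forward pass on the unmutated
#' sequence yields all substitution probabilities at once). The package ships
#' simple reference scorers; arbitrary models plug in through [fn_scorer()]
#' or by implementing the `scorer_logprobs()` method, and trainable students
#' (see [window_student()]) implement [score_llr()] directly.
#'
#' @name scorers
NULL

new_scorer <- function(x, class, name) {
  structure(x, name = name, class = c(class, "vep_scorer"))
}

#' @export
print.vep_scorer <- function(x, ...) {
  cat("<", class(x)[1], "> ", attr(x, "name") %||% "", "\n", sep = "")
  invisible(x)
}

#' @describeIn scorers Scorer assigning probability 1/20 to every amino acid
#'   at every position (all LLRs are zero).
#' @export
uniform_scorer <- function() {
  new_scorer(list(), "uniform_scorer", "uniform")
}

#' @describeIn scorers Degenerate scorer placing all mass on the wild-type
#'   letter; off-wild-type log-probabilities are clamped to the configured
#'   floor `log(1e-12)`.
#' @export
onehot_scorer <- function() {
  new_scorer(list(), "onehot_scorer", "onehot")
}

#' @describeIn scorers Position-specific profile scorer. `profile` is an
#'   L x 20 matrix of per-position amino-acid probabilities (rows sum to 1)
#'   in [AA_ALPHABET] order; proteins scored with it must have length L.
#' @param profile L x 20 probability matrix.
#' @param name Human-readable scorer name.
#' @export
profile_scorer <- function(profile, name = "profile") {
  profile <- as.matrix(profile)
  stopifnot(ncol(profile) == 20L, all(profile >= 0))
  profile <- profile / rowSums(profile)
  new_scorer(list(profile = profile), "profile_scorer", name)
}

#' @describeIn scorers Wrap a function `fn(sequence)` returning an L x 20
#'   natural-log probability matrix as a scorer.
#' @param fn Function of a sequence string.
#' @export
fn_scorer <- function(fn, name = "custom") {
  stopifnot(is.function(fn))
  new_scorer(list(fn = fn), "fn_scorer", name)
}

#' Name of a scorer or student
#' @param scorer A scorer object.
#' @return Character scalar.
#' @export
scorer_name <- function(scorer) attr(scorer, "name") %||% class(scorer)[1]

scorer_logprobs <- function(scorer, sequence) UseMethod("scorer_logprobs")

#' @export
scorer_logprobs.uniform_scorer <- function(scorer, sequence) {
  L <- nchar(sequence)
  matrix(log(1 / 20), nrow = L, ncol = 20L)
}

#' @export
scorer_logprobs.onehot_scorer <- function(scorer, sequence) {
  chars <- seq_chars(sequence)
  lp <- matrix(LOGP_FLOOR, nrow = length(chars), ncol = 20L)
  idx <- aa_index(chars)
  ok <- !is.na(idx)
  lp[cbind(which(ok), idx[ok])] <- 0
  lp
}

#' @export
scorer_logprobs.profile_scorer <- function(scorer, sequence) {
  L <- nchar(sequence)
  profile <- scorer$profile
  if (nrow(profile) != L) {
    abort(sprintf(
      "profile scorer expects length %d, got sequence of length %d",
      nrow(profile), L
    ))
  }
  log(pmax(profile, 1e-12))
}

#' @export
scorer_logprobs.fn_scorer <- function(scorer, sequence) {
  scorer$fn(sequence)
}

#' Per-position amino-acid log-probabilities for a protein
#'
#' Runs a scorer on the wild-type sequence and validates the result: one row
#' per residue, 20 columns in [AA_ALPHABET] order, each row normalized
#' (logsumexp equal to 0 within 1e-6) after flooring at `log(1e-12)`.
#'
#' @param scorer A scorer object (see [scorers]).
#' @param protein A protein record (one-row data frame from
#'   [protein_record()]) or a sequence string.
#' @return L x 20 matrix of natural-log probabilities, with the protein id
#'   and sequence attached as attributes.
#' @export
#' @examples
#' p <- protein_record("P1", "MKTAY")
#' lp <- score_position_logprobs(uniform_scorer(), p)
#' all.equal(unique(as.vector(lp)), log(1 / 20))
score_position_logprobs <- function(scorer, protein) {
  protein <- as_protein(protein)
  lp <- scorer_logprobs(scorer, protein$sequence)
  lp <- as.matrix(lp)
  L <- nchar(protein$sequence)
  if (nrow(lp) != L || ncol(lp) != 20L) {
    abort(sprintf(
      "scorer returned a %d x %d matrix for a protein of length %d",
      nrow(lp), ncol(lp), L
    ))
  }
  if (any(is.na(lp)) || any(lp == Inf)) {
    abort("scorer returned non-finite log-probabilities")
  }
  lp <- pmax(lp, LOGP_FLOOR)
  lse <- apply(lp, 1L, logsumexp)
  if (any(abs(lse) > 1e-6)) {
    bad <- which(abs(lse) > 1e-6)[1]
    abort(sprintf(
      "log-probabilities at position %d are not normalized (logsumexp = %.3g)",
      bad, lse[bad]
    ))
  }
  dimnames(lp) <- list(NULL, AA_ALPHABET)
  attr(lp, "protein_id") <- protein$id
  attr(lp, "sequence") <- protein$sequence
  lp
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

as_protein <- function(protein) {
  if (is.character(protein) && length(protein) == 1L) {
    return(list(id = "protein", sequence = toupper(protein)))
  }
  protein <- as.list(protein)
  if (is.null(protein$id) || is.null(protein$sequence)) {
    abort("protein must have `id` and `sequence`")
  }
  list(id = as.character(protein$id)[1],
       sequence = toupper(as.character(protein$sequence)[1]))
}
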