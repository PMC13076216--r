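#' The canonical amino-acid alphabet
#'
#' All LLR grids and position log-probability matrices in this package use the
#' 20 canonical amino acids in the fixed column order
#' `ACDEFGHIKLMNPQRSTVWY`. Nonstandard letters (X, U, B, Z, ...) are permitted
#' in sequences but the corresponding matrix rows are masked rather than
#' scored.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# floor applied to log-probabilities so degenerate (one-hot) scorers stay finite
LOGP_FLOOR <- log(1e-12)

aa_index <- function(letters) match(letters, AA_ALPHABET)

seq_chars <- function(sequence) strsplit(sequence, "")[[1]]

#' Create a protein record
#'
#' Normalizes a sequence to uppercase and records which positions carry a
#' nonstandard letter (anything outside [AA_ALPHABET]); those positions are
#' carried along but masked during scoring.
#'
#' @param id Protein identifier.
#' @param sequence Amino-acid sequence (length >= 1).
#' @return A one-row tibble with columns `id`, `sequence`, `length`,
#'   `n_nonstandard`.
#' @export
#' @examples
#' protein_record("P1", "MKTAY")
protein_record <- function(id, sequence) {
  stopifnot(is.character(id), length(id) == 1L)
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) abort("protein sequence must have length >= 1")
  chars <- seq_chars(sequence)
  tibble::tibble(
    id = id,
    sequence = sequence,
    length = length(chars),
    n_nonstandard = sum(!chars %in% AA_ALPHABET)
  )
}

#' Read protein records from a FASTA file
#'
#' Standard multi-FASTA; the description line is split on the first
#' whitespace to form the id.
#'
#' @param path Path to a FASTA file.
#' @return Tibble of protein records (one row per sequence).
#' @export
read_fasta_proteins <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("reading FASTA requires the Biostrings package")
  }
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) abort(paste0("no sequences found in ", path))
  ids <- vapply(strsplit(names(aa), "\\s+"), `[[`, character(1), 1L)
  purrr::map2_dfr(ids, as.character(aa), protein_record)
}

#' Write protein records to a FASTA file
#'
#' @param proteins Tibble with `id` and `sequence` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_proteins <- function(proteins, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("writing FASTA requires the Biostrings package")
  }
  aa <- Biostrings::AAStringSet(setNames(proteins$sequence, proteins$id))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
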