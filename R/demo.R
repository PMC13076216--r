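#' End-to-end toy pipeline
#'
#' Exercises the whole toolkit on synthetic data at desk scale: generates a
#' two-domain protein family with complementary blind-spot scorers, compares
#' each base scorer's AUC with the min-aggregate AUC on generated labeled
#' variants, runs one maximum-confidence round followed by one averaging
#' round of co-distillation of window-linear students, evaluates a DMS-like
#' assay panel, computes the aggregation-theory regime map, and runs the
#' summary-statistic association benchmark. All stages are seeded from the
#' single `seed`.
#'
#' @param seed Integer master seed.
#' @param outdir Optional directory; when given, each stage's table is
#'   written as a provenance-headered TSV.
#' @param n_proteins,protein_length Family size (defaults 12 proteins of
#'   length 120).
#' @return Named list of stage results (`aggregation`, `codistillation`,
#'   `dms`, `theory`, `association`), each a tibble.
#' @export
run_demo <- function(seed = 1L, outdir = NULL, n_proteins = 12L,
                     protein_length = 120L) {
  fam <- generate_family(n_proteins, protein_length, seed = seed)
  truth <- fam$truth
  proteins <- fam$proteins
  scorers <- make_blindspot_scorers(
    fam, detectability = list(scorerA = "domainA", scorerB = "domainB"))
  variants <- generate_labeled_variants(proteins, truth, n_per_protein = 40L,
                                        label_noise = 0.05, seed = seed + 1L)

  # --- aggregation: base scorers vs maximum confidence -----------------
  mats <- lapply(scorers, function(sc) {
    lapply(seq_len(nrow(proteins)),
           function(i) score_llr(sc, proteins[i, ])) |>
      setNames(proteins$id)
  })
  base_aucs <- vapply(names(scorers), function(s) {
    student_eval_auc(scorers[[s]], proteins, variants)
  }, numeric(1))
  min_mats <- lapply(proteins$id, function(id) {
    aggregate_min(score_stack(lapply(mats, `[[`, id), names(scorers)))$llr
  })
  names(min_mats) <- proteins$id
  scored <- variants
  scored$score <- purrr::pmap_dbl(
    variants[c("protein_id", "position", "ref_aa", "alt_aa")],
    function(protein_id, position, ref_aa, alt_aa) {
      variant_score(min_mats[[protein_id]], position, ref_aa, alt_aa)
    })
  agg_tbl <- tibble::tibble(
    model = c(names(base_aucs), "MIN"),
    auc = c(unname(base_aucs), auc(scored$score, scored$label)))

  # --- co-distillation: min round then averaging round -----------------
  students <- purrr::imap(scorers, function(sc, nm) {
    knowledge_distill(sc, window_student(radius = 2L, length = protein_length,
                                         name = paste0("st_", nm)),
                      proteins, train_config(epochs = 40L, seed = seed),
                      holdout_fraction = 0.25)$student
  })
  hist <- run_schedule(students, proteins, c("min", "mean"),
                       train_config(epochs = 40L, seed = seed),
                       eval_set = variants)
  codi_tbl <- hist$report

  # --- DMS evaluation ---------------------------------------------------
  assays <- dplyr::bind_rows(
    generate_dms_assays(proteins[1, ], truth, seed = seed + 2L),
    generate_dms_assays(proteins[2, ], truth, inverted = TRUE, wt_convention = 1,
                        assay_id = paste0(proteins$id[2], "_inv"),
                        seed = seed + 3L))
  assays <- dplyr::bind_rows(
    dplyr::filter(assays, !.data$inverted),
    apply_wt_transform(dplyr::filter(assays, .data$inverted)))
  assays <- score_variant_table(hist$students[[1]], proteins, assays) |>
    dplyr::rename(prediction = "score")
  dms <- dms_spearman(assays)
  dms_tbl <- dms$per_assay

  # --- theory regime map ------------------------------------------------
  theory_tbl <- regime_map(separations = c(0.5, 1, 2, 4),
                           sigma_ratios = c(1, 2, 4, 8), n_models = 10L)

  # --- association benchmark -------------------------------------------
  stats <- generate_summary_stats(n_genes = 8L, n_phenotypes = 2L,
                                  gamma = 0.5, seed = seed + 4L)
  pairs <- filter_benchmark_pairs(stats, min_missense = 25L,
                                  gene_p_threshold = 1, single_variant_p = 1)
  res <- pair_regressions(pairs)
  assoc_tbl <- tibble::tibble(
    mean_log10p = association_strength(res),
    concordance = direction_concordance(res),
    n_pairs = nrow(res))

  out <- list(aggregation = agg_tbl, codistillation = codi_tbl,
              dms = dms_tbl, theory = theory_tbl, association = assoc_tbl)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out)) {
      write_report_tsv(out[[nm]], file.path(outdir, paste0(nm, ".tsv")),
                       seed = seed)
    }
  }
  out
}

#' Write a tibble as a provenance-headered TSV
#'
#' Tab-separated UTF-8 with `#`-prefixed provenance lines (toolkit version
#' and seed) and `.` for missing values; readable back with
#' [read_llr_tsv()].
#'
#' @param data A data frame.
#' @param path Output path.
#' @param seed Seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(data, path, seed = NA_integer_) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  version <- as.character(utils::packageVersion("maxvep"))
  writeLines(sprintf("# maxvep %s", version), con)
  writeLines(sprintf("# seed: %s", seed), con)
  utils::write.table(data, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}
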