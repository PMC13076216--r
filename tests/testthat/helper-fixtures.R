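# Shared fixtures, built once per test run.

# random normalized log-prob matrix (Dirichlet rows)
random_logprobs <- function(L, seed = 1L, alpha = 1) {
  set.seed(seed)
  t(vapply(seq_len(L), function(i) {
    g <- rgamma(20, shape = alpha)
    log(g / sum(g))
  }, numeric(20)))
}

# scorer emitting a fixed log-prob matrix regardless of sequence content
fixed_scorer <- function(lp, name = "fixed") {
  fn_scorer(function(sequence) lp[seq_len(nchar(sequence)), , drop = FALSE],
            name = name)
}

random_protein <- function(L, seed = 1L, id = "RP1") {
  set.seed(seed)
  protein_record(id, paste(sample(AA_ALPHABET, L, replace = TRUE),
                           collapse = ""))
}

# small two-domain family + complementary blind-spot scorers + variants
blindspot_fixture <- function(seed = 1L, n_proteins = 12L, len = 120L,
                              label_noise = 0.05) {
  fam <- generate_family(n_proteins, len, seed = seed)
  scorers <- make_blindspot_scorers(
    fam, detectability = list(A = "domainA", B = "domainB"))
  variants <- generate_labeled_variants(fam$proteins, fam$truth,
                                        n_per_protein = 40L,
                                        label_noise = label_noise,
                                        seed = seed + 100L)
  list(fam = fam, proteins = fam$proteins, truth = fam$truth,
       scorers = scorers, variants = variants)
}

# min-aggregate scores added to a variant table
min_aggregate_scores <- function(fx) {
  mats <- lapply(fx$scorers, function(sc) {
    out <- lapply(seq_len(nrow(fx$proteins)),
                  function(i) score_llr(sc, fx$proteins[i, ]))
    names(out) <- fx$proteins$id
    out
  })
  mins <- lapply(fx$proteins$id, function(id) {
    aggregate_min(score_stack(lapply(mats, `[[`, id), names(fx$scorers)))$llr
  })
  names(mins) <- fx$proteins$id
  v <- fx$variants
  v$score <- purrr::pmap_dbl(
    v[c("protein_id", "position", "ref_aa", "alt_aa")],
    function(protein_id, position, ref_aa, alt_aa) {
      variant_score(mins[[protein_id]], position, ref_aa, alt_aa)
    })
  v
}

# O(n^2) pairwise AUC oracle: P(benign > pathogenic) + half credit for ties
auc_oracle <- function(scores, labels) {
  path <- tolower(as.character(labels)) == "pathogenic"
  b <- scores[!path]; p <- scores[path]
  total <- 0
  for (x in b) for (y in p) {
    total <- total + (x > y) + 0.5 * (x == y)
  }
  total / (length(b) * length(p))
}
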