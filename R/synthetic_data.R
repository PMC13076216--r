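#' Synthetic protein families with conserved domains
#'
#' Generates a toy protein family whose columns are drawn from
#' Dirichlet-parameterized per-position amino-acid distributions: background
#' columns are high-entropy, domain columns mix a consensus letter with a
#' random distribution so that conservation is tunable. The returned truth
#' object records the generating column distributions and a per-position
#' *sensitivity* in `[0, 1]` (one minus the normalized column entropy):
#' conserved positions are mutationally sensitive, background positions are
#' tolerant. This emulates the real-data phenomenon motivating
#' maximum-confidence aggregation — well-conserved domains (think KRAB or
#' BRICHOS) that only some scorers detect.
#'
#' @param n_proteins Number of family members.
#' @param length Protein length L.
#' @param domain_specs Tibble with `name`, `start`, `end`, `conservation`
#'   (in (0, 1]); spans must lie within the protein and not overlap.
#' @param background_entropy Dirichlet concentration for background columns
#'   (larger = closer to uniform, i.e. higher entropy). Default 5.
#' @param seed Integer seed; the generator is fully reproducible.
#' @return List with `proteins` (tibble of records) and `truth` (a
#'   `synthetic_truth` object: `column_probs`, `sensitivity`, `domains`,
#'   `seed`).
#' @export
#' @examples
#' fam <- generate_family(
#'   n_proteins = 6, length = 60,
#'   domain_specs = tibble::tibble(name = "d1", start = 11, end = 25,
#'                                 conservation = 0.9),
#'   seed = 1)
#' fam$proteins
generate_family <- function(n_proteins, length,
                            domain_specs = default_domains(length),
                            background_entropy = 5, seed = 1L) {
  stopifnot(n_proteins >= 1, length >= 1)
  domain_specs <- tibble::as_tibble(domain_specs)
  validate_domains(domain_specs, length)
  withr_seed(seed, {
    probs <- matrix(0, nrow = length, ncol = 20L)
    in_domain <- rep(FALSE, length)
    for (t in seq_len(length)) {
      probs[t, ] <- rdirichlet1(rep(background_entropy, 20L))
    }
    for (d in seq_len(nrow(domain_specs))) {
      span <- seq.int(domain_specs$start[d], domain_specs$end[d])
      in_domain[span] <- TRUE
      cons <- domain_specs$conservation[d]
      for (t in span) {
        consensus <- sample.int(20L, 1L)
        base <- rdirichlet1(rep(1, 20L))
        p <- (1 - cons) * base
        p[consensus] <- p[consensus] + cons
        probs[t, ] <- p
      }
    }
    seqs <- vapply(seq_len(n_proteins), function(i) {
      paste(AA_ALPHABET[apply(probs, 1L, function(p) {
        sample.int(20L, 1L, prob = p)
      })], collapse = "")
    }, character(1))
  })
  proteins <- purrr::map2_dfr(sprintf("SYN%03d", seq_len(n_proteins)), seqs,
                              protein_record)
  sens <- 1 - apply(probs, 1L, shannon_entropy) / log(20)
  truth <- structure(list(column_probs = probs,
                          sensitivity = pmin(pmax(sens, 0), 1),
                          in_domain = in_domain,
                          domains = domain_specs,
                          seed = seed,
                          background_entropy = background_entropy),
                     class = "synthetic_truth")
  list(proteins = proteins, truth = truth)
}

#' @rdname generate_family
#' @export
default_domains <- function(length) {
  stopifnot(length >= 40)
  third <- floor(length / 3)
  tibble::tibble(
    name = c("domainA", "domainB"),
    start = c(max(2L, floor(third / 2)), 2L * third),
    end = c(max(2L, floor(third / 2)) + floor(third / 2),
            2L * third + floor(third / 2)),
    conservation = c(0.9, 0.9))
}

validate_domains <- function(domain_specs, length) {
  req <- c("name", "start", "end", "conservation")
  if (!all(req %in% names(domain_specs))) {
    abort("domain_specs needs name, start, end, conservation columns")
  }
  if (any(domain_specs$start < 1 | domain_specs$end > length |
          domain_specs$start > domain_specs$end)) {
    abort("domain spans must lie within [1, length]")
  }
  if (any(domain_specs$conservation <= 0 | domain_specs$conservation > 1)) {
    abort("conservation must be in (0, 1]")
  }
  covered <- unlist(purrr::map2(domain_specs$start, domain_specs$end, seq))
  if (anyDuplicated(covered)) abort("domains must not overlap")
  invisible(domain_specs)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Build complementary blind-spot profile scorers
#'
#' Each scorer is a position-specific profile scorer estimated from the
#' family's column counts with a pseudocount. Domains *masked* for a scorer
#' are background-randomized in its training view: those columns are replaced
#' by the uniform distribution, so the scorer emits near-zero LLRs there (it
#' cannot see the conservation) while domains it detects yield strongly
#' negative LLRs for non-consensus substitutions. Two scorers with
#' complementary masks reproduce the ensemble blind-spot phenomenon: the
#' min-aggregate detects every domain while each base scorer misses one.
#'
#' @param family Output of [generate_family()] (or its `proteins` tibble
#'   plus `truth`).
#' @param truth The `synthetic_truth` (defaults to `family$truth`).
#' @param detectability Named list: for each scorer, the character vector of
#'   domain names it can see. Domains missing from every scorer trigger a
#'   warning.
#' @param pseudocount Pseudocount added to column counts (default 0.5).
#' @return Named list of [profile_scorer()] objects.
#' @export
make_blindspot_scorers <- function(family, truth = family$truth,
                                   detectability, pseudocount = 0.5) {
  proteins <- if (is.data.frame(family)) family else family$proteins
  domains <- truth$domains
  seen <- unique(unlist(detectability))
  unseen <- setdiff(domains$name, seen)
  if (length(unseen)) {
    warn(paste0("no scorer can detect domain(s): ",
                paste(unseen, collapse = ", ")))
  }
  L <- nchar(proteins$sequence[1])
  counts <- matrix(0, nrow = L, ncol = 20L)
  for (s in proteins$sequence) {
    idx <- aa_index(seq_chars(s))
    ok <- !is.na(idx)
    counts[cbind(which(ok), idx[ok])] <-
      counts[cbind(which(ok), idx[ok])] + 1
  }
  out <- lapply(names(detectability), function(sc) {
    visible <- detectability[[sc]]
    cts <- counts
    hidden <- domains[!domains$name %in% visible, , drop = FALSE]
    for (d in seq_len(nrow(hidden))) {
      span <- seq.int(hidden$start[d], hidden$end[d])
      cts[span, ] <- 0  # background-randomized: pseudocount-only = uniform
    }
    prob <- (cts + pseudocount)
    profile_scorer(prob / rowSums(prob), name = sc)
  })
  names(out) <- names(detectability)
  out
}

#' Generate a labeled (pathogenic / benign) variant set
#'
#' Variants are drawn uniformly over positions (with standard wild-type
#' letters) and non-wild-type alternate amino acids. The pathogenicity
#' probability increases linearly with the position's ground-truth
#' sensitivity (`rule = "probabilistic"`), or labels are set
#' deterministically by thresholding sensitivity (`rule = "threshold"`).
#' `label_noise` then flips each label independently. Benign variants get
#' higher synthetic allele frequencies than pathogenic ones and a fraction
#' of AF values is left missing, mirroring population databases.
#'
#' @param proteins Tibble of family protein records.
#' @param truth `synthetic_truth` from [generate_family()].
#' @param n_per_protein Variants per protein (>= 2).
#' @param label_noise Independent label-flip probability.
#' @param rule Labeling rule (see above).
#' @param threshold Sensitivity threshold for `rule = "threshold"`.
#' @param af_missing Fraction of variants with missing allele frequency.
#' @param seed Integer seed.
#' @return Tibble: `variant_id`, `gene` (= protein id), `protein_id`,
#'   `position`, `ref_aa`, `alt_aa`, `label`, `af`, `sensitivity`.
#' @export
generate_labeled_variants <- function(proteins, truth, n_per_protein = 40L,
                                      label_noise = 0,
                                      rule = c("probabilistic", "threshold"),
                                      threshold = 0.5, af_missing = 0.1,
                                      seed = 1L) {
  rule <- match.arg(rule)
  stopifnot(n_per_protein >= 2)
  sens <- truth$sensitivity
  rows <- withr_seed(seed, {
    purrr::map_dfr(seq_len(nrow(proteins)), function(i) {
      chars <- seq_chars(proteins$sequence[i])
      ok_pos <- which(!is.na(aa_index(chars)))
      pos <- sample(ok_pos, n_per_protein, replace = TRUE)
      alt <- vapply(pos, function(t) {
        sample(setdiff(AA_ALPHABET, chars[t]), 1L)
      }, character(1))
      s <- sens[pos]
      path <- if (rule == "threshold") s > threshold
              else runif(n_per_protein) < (0.03 + 0.94 * s)
      # guarantee both classes per protein when the rule is probabilistic
      if (rule == "probabilistic" && length(unique(path)) == 1L) {
        flip <- if (path[1]) which.min(s) else which.max(s)
        path[flip] <- !path[flip]
      }
      if (label_noise > 0) {
        path <- xor(path, runif(n_per_protein) < label_noise)
      }
      af <- ifelse(path, rbeta(n_per_protein, 1, 200),
                   rbeta(n_per_protein, 2, 20))
      af[runif(n_per_protein) < af_missing] <- NA_real_
      tibble::tibble(
        gene = proteins$id[i], protein_id = proteins$id[i],
        position = pos, ref_aa = chars[pos], alt_aa = alt,
        label = ifelse(path, "pathogenic", "benign"),
        af = af, sensitivity = s)
    })
  })
  dplyr::mutate(rows,
                variant_id = sprintf("v%05d", dplyr::row_number()),
                .before = 1L)
}

#' Generate a DMS-like assay table for one protein
#'
#' Measurements are a monotone function of ground-truth fitness plus
#' Gaussian noise. With `inverted = TRUE`, variant measurements deviate from
#' the wild-type value in a random direction, so the raw measurement is
#' uninformative and the `abs(x - WT)` transform (see
#' [apply_wt_transform()]) is required to recover the deleteriousness
#' signal — emulating assays where scoring above the WT is also deleterious.
#'
#' @param protein One protein record (one-row tibble).
#' @param truth `synthetic_truth` for the family.
#' @param n_variants Number of assayed variants.
#' @param noise_sd Gaussian measurement noise sd.
#' @param wt_convention Wild-type measurement value, 0 or 1.
#' @param inverted Logical; see above.
#' @param selection_type Assay selection label (fitness, activity, ...).
#' @param assay_id Assay identifier.
#' @param seed Integer seed.
#' @return Tibble: `assay_id`, `selection_type`, `protein_id`, `position`,
#'   `ref_aa`, `alt_aa`, `measurement`, `truth_fitness`, `wt_value`,
#'   `inverted`.
#' @export
generate_dms_assays <- function(protein, truth, n_variants = 100L,
                                noise_sd = 0.05, wt_convention = 1,
                                inverted = FALSE,
                                selection_type = "fitness",
                                assay_id = paste0(protein$id, "_dms"),
                                seed = 1L) {
  stopifnot(wt_convention %in% c(0, 1))
  chars <- seq_chars(protein$sequence[1])
  sens <- truth$sensitivity
  withr_seed(seed, {
    ok_pos <- which(!is.na(aa_index(chars)))
    pos <- sample(ok_pos, n_variants, replace = TRUE)
    alt <- vapply(pos, function(t) {
      sample(setdiff(AA_ALPHABET, chars[t]), 1L)
    }, character(1))
    damage <- sens[pos]             # deleteriousness in [0, 1]
    fitness <- 1 - damage
    direction <- if (inverted) sample(c(-1, 1), n_variants, replace = TRUE)
                 else rep(-1, n_variants)
    measurement <- wt_convention + direction * damage +
      rnorm(n_variants, 0, noise_sd)
  })
  tibble::tibble(
    assay_id = assay_id, selection_type = selection_type,
    protein_id = protein$id[1],
    position = pos, ref_aa = chars[pos], alt_aa = alt,
    measurement = measurement, truth_fitness = fitness,
    wt_value = wt_convention, inverted = inverted)
}

#' Generate gene-phenotype summary statistics
#'
#' A synthetic stand-in for biobank rare-variant summary statistics. For
#' each gene-phenotype pair, per-variant severities are affine in a latent
#' ground-truth sensitivity (clipped to `[0, 1]`); single-variant effect
#' sizes follow `beta_v = gamma * severity_v + e`, `e ~ N(0, se^2)`, with
#' two-sided p-values from the known error model. The per-variant `score`
#' column is a noisy severity prediction (higher = more damaging). The
#' gene-level burden-style effect is the severity-weighted mean of the
#' per-variant betas; the gene-level missense p-value is a Fisher
#' combination of the per-variant p-values — a documented synthetic
#' surrogate for a SKAT-O-style test, not SKAT-O itself. The pLoF burden
#' effect sign is tied to the pair's `gamma`.
#'
#' @param n_genes Number of genes.
#' @param n_phenotypes Number of phenotypes.
#' @param n_variants Variants per gene-phenotype pair.
#' @param gamma Gene-phenotype effect: scalar recycled to all pairs, or a
#'   vector of length `n_genes * n_phenotypes`.
#' @param se Standard error of the per-variant effect estimate.
#' @param score_noise Noise sd on the severity predictions.
#' @param seed Integer seed.
#' @return Tibble with one row per variant: `gene`, `phenotype`, `variant`,
#'   `severity`, `score`, `beta`, `p`, and pair-level columns
#'   `gene_missense_p`, `plof_beta`, `plof_p`, `n_variants`.
#' @export
generate_summary_stats <- function(n_genes = 10L, n_phenotypes = 2L,
                                   n_variants = 50L, gamma = 0.5, se = 0.2,
                                   score_noise = 0.05, seed = 1L) {
  pairs <- tidyr::expand_grid(
    gene = sprintf("G%03d", seq_len(n_genes)),
    phenotype = sprintf("pheno%02d", seq_len(n_phenotypes)))
  gamma <- rep_len(gamma, nrow(pairs))
  withr_seed(seed, {
    out <- purrr::map_dfr(seq_len(nrow(pairs)), function(k) {
      g <- gamma[k]
      u <- runif(n_variants)
      severity <- pmin(pmax(0.1 + 0.8 * u, 0), 1)
      beta <- g * severity + rnorm(n_variants, 0, se)
      z <- beta / se
      p <- 2 * pnorm(-abs(z))
      score <- severity + rnorm(n_variants, 0, score_noise)
      w <- severity / sum(severity)
      plof_beta <- g * mean(severity) + rnorm(1, 0, se / sqrt(n_variants))
      plof_z <- plof_beta / (se / sqrt(n_variants))
      fisher <- -2 * sum(log(pmax(p, 1e-300)))
      tibble::tibble(
        gene = pairs$gene[k], phenotype = pairs$phenotype[k],
        variant = sprintf("%s_%s_v%03d", pairs$gene[k], pairs$phenotype[k],
                          seq_len(n_variants)),
        severity = severity, score = score, beta = beta, p = p,
        gene_burden_beta = sum(w * beta),
        gene_missense_p = pchisq(fisher, df = 2 * n_variants,
                                 lower.tail = FALSE),
        plof_beta = plof_beta,
        plof_p = 2 * pnorm(-abs(plof_z)),
        n_variants = n_variants)
    })
  })
  out
}
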