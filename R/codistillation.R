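#' Training configuration for distillation
#'
#' Defaults mirror a short fixed-epoch schedule: every student trains for the
#' same number of full-batch gradient epochs on the masked MSE toward fixed,
#' precomputed targets.
#'
#' @param epochs Number of epochs (>= 1).
#' @param learning_rate Gradient-descent step size.
#' @param momentum Heavy-ball momentum coefficient (default 0.9); the
#'   optimizer velocity is reset at the start of each training run.
#' @param validation_fraction Fraction of proteins held out for validation
#'   monitoring (0 = none).
#' @param seed Integer seed controlling the validation split and any random
#'   initialization downstream.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 100L, learning_rate = 0.5, momentum = 0.9,
                         validation_fraction = 0, seed = 1L) {
  epochs <- as.integer(epochs)
  if (is.na(epochs) || epochs < 1L) abort("epochs must be >= 1")
  if (validation_fraction < 0 || validation_fraction >= 1) {
    abort("validation_fraction must be in [0, 1)")
  }
  if (momentum < 0 || momentum >= 1) abort("momentum must be in [0, 1)")
  structure(list(epochs = epochs, learning_rate = learning_rate,
                 momentum = momentum,
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Build fixed distillation targets from student predictions
#'
#' Scores every student on every protein, aggregates the stack per protein
#' (`min` = maximum confidence, `mean` = averaging), and shifts the aggregate
#' by one constant per student so its pooled mean over all unmasked non-WT
#' variants matches that student's own pooled base mean. Targets are
#' precomputed and fixed: they do not change while students train.
#'
#' @param students Named list of student/scorer objects.
#' @param proteins Tibble of protein records.
#' @param aggregator `"min"` or `"mean"`.
#' @param base_means Optional named numeric vector of per-student base means;
#'   defaults to each student's current pooled mean (computed once here and
#'   then frozen).
#' @return A `distill_targets` object: per-student lists of target
#'   [llr_matrix()] objects keyed by protein id, the aggregator tag and the
#'   per-student shift constants.
#' @export
build_targets <- function(students, proteins, aggregator = c("min", "mean"),
                          base_means = NULL) {
  aggregator <- match.arg(aggregator)
  students <- named_students(students)
  preds <- predict_all(students, proteins)
  aggs <- lapply(proteins$id, function(id) {
    stack <- score_stack(lapply(preds, `[[`, id), names(students))
    if (aggregator == "min") aggregate_min(stack)$llr
    else aggregate_mean(stack)$llr
  })
  names(aggs) <- proteins$id
  agg_mean <- llr_mean(aggs)
  shifts <- vapply(names(students), function(s) {
    bm <- if (!is.null(base_means)) base_means[[s]] else llr_mean(preds[[s]])
    bm - agg_mean
  }, numeric(1))
  per_student <- lapply(names(students), function(s) {
    lapply(aggs, shift_llr, shift = shifts[[s]])
  })
  names(per_student) <- names(students)
  structure(list(targets = per_student, aggregator = aggregator,
                 shifts = shifts, protein_ids = proteins$id),
            class = "distill_targets")
}

shift_llr <- function(m, shift) {
  keep <- !llr_mask(m) & !wt_cells(m)
  vals <- unclass(m)
  vals[keep] <- vals[keep] + shift
  new_llr_matrix(vals, llr_protein_id(m), llr_sequence(m), llr_mask(m))
}

named_students <- function(students) {
  if (inherits(students, "vep_student") || inherits(students, "vep_scorer")) {
    students <- list(students)
  }
  names(students) <- names(students) %||%
    vapply(students, scorer_name, character(1))
  if (anyDuplicated(names(students))) {
    names(students) <- make.unique(names(students), sep = "_")
  }
  students
}

predict_all <- function(students, proteins) {
  lapply(students, function(st) {
    out <- lapply(seq_len(nrow(proteins)), function(i) {
      score_llr(st, proteins[i, ])
    })
    names(out) <- proteins$id
    out
  })
}

#' Train one student against fixed targets
#'
#' Full-batch gradient descent on the masked MSE (wild-type and masked
#' entries excluded). Deterministic given the config seed.
#'
#' @param student A student object.
#' @param proteins Tibble of protein records.
#' @param targets Named list of target [llr_matrix()] objects keyed by
#'   protein id (e.g. one student's slot of [build_targets()]).
#' @param config A [train_config()].
#' @return List with `student` (trained), `trace` (tibble epoch /
#'   train_mse / val_mse) and `final_mse`.
#' @export
train_student <- function(student, proteins, targets, config = train_config()) {
  stopifnot(inherits(config, "train_config"))
  if (inherits(targets, "distill_targets")) {
    abort("pass one student's target list, e.g. targets$targets[[name]]")
  }
  n <- nrow(proteins)
  val_idx <- integer(0)
  if (config$validation_fraction > 0 && n > 1L) {
    n_val <- max(1L, floor(config$validation_fraction * n))
    val_idx <- withr_seed(config$seed, sample.int(n, n_val))
  }
  train_prot <- if (length(val_idx)) proteins[-val_idx, ] else proteins
  val_prot <- if (length(val_idx)) proteins[val_idx, ] else NULL
  batch <- student_batch(student, train_prot, targets)
  val_batch <- if (!is.null(val_prot)) student_batch(student, val_prot, targets)
  if (!is.null(student$V)) student$V[] <- 0  # fresh optimizer state per run
  trace <- vector("list", config$epochs)
  for (e in seq_len(config$epochs)) {
    step <- student_fit_step(student, batch, config$learning_rate,
                             config$momentum)
    student <- step$student
    trace[[e]] <- tibble::tibble(
      epoch = e, train_mse = step$loss,
      val_mse = if (!is.null(val_batch)) masked_mse(student, val_batch)
                else NA_real_)
  }
  list(student = student, trace = dplyr::bind_rows(trace),
       final_mse = masked_mse(student, batch))
}

#' One round of co-distillation
#'
#' All students score all proteins; the stacks are aggregated into one fixed
#' target grid per protein (mean-shifted per student); each student then
#' trains independently toward the shared targets. When an evaluation set of
#' labeled variants is supplied the report carries each student's AUC before
#' and after the round.
#'
#' @inheritParams build_targets
#' @param config A [train_config()].
#' @param eval_set Optional labeled variant tibble (`protein_id`, `position`,
#'   `ref_aa`, `alt_aa`, `label`).
#' @return List with `students` (updated, named), `targets`, and `report`
#'   (tibble: student, pre/post MSE to target, pre/post AUC).
#' @export
codistill_round <- function(students, proteins, aggregator = c("min", "mean"),
                            config = train_config(), eval_set = NULL) {
  aggregator <- match.arg(aggregator)
  students <- named_students(students)
  targets <- build_targets(students, proteins, aggregator)
  rows <- list(); updated <- list()
  for (s in names(students)) {
    pre_auc <- if (!is.null(eval_set)) {
      student_eval_auc(students[[s]], proteins, eval_set)
    } else NA_real_
    fit <- train_student(students[[s]], proteins, targets$targets[[s]], config)
    post_auc <- if (!is.null(eval_set)) {
      student_eval_auc(fit$student, proteins, eval_set)
    } else NA_real_
    updated[[s]] <- fit$student
    rows[[s]] <- tibble::tibble(
      student = s, aggregator = aggregator,
      mse_initial = fit$trace$train_mse[1], mse_final = fit$final_mse,
      auc_pre = pre_auc, auc_post = post_auc)
  }
  list(students = updated, targets = targets,
       report = dplyr::bind_rows(rows))
}

#' Run a multi-round co-distillation schedule
#'
#' Rounds run in order; each round's training continues from the students'
#' previous-round state. Schedules are written as aggregator tags per round,
#' e.g. `c("min", "mean", "mean")`.
#'
#' @inheritParams codistill_round
#' @param schedule Character vector of aggregator tags (`"min"`/`"mean"`),
#'   one per round.
#' @param configs A single [train_config()] (reused each round) or a list of
#'   one config per round.
#' @return A `codistill_history` list: final `students` and the per-round
#'   `report` tibble (with a `round` column).
#' @export
run_schedule <- function(students, proteins, schedule,
                         configs = train_config(), eval_set = NULL) {
  if (!length(schedule)) abort("schedule needs at least one round")
  if (inherits(configs, "train_config")) {
    configs <- rep(list(configs), length(schedule))
  }
  stopifnot(length(configs) == length(schedule))
  students <- named_students(students)
  reports <- list()
  for (r in seq_along(schedule)) {
    round <- codistill_round(students, proteins, schedule[[r]],
                             configs[[r]], eval_set)
    students <- round$students
    reports[[r]] <- dplyr::mutate(round$report, round = r, .before = 1L)
  }
  structure(list(students = students,
                 report = dplyr::bind_rows(reports),
                 schedule = schedule),
            class = "codistill_history")
}

#' @export
print.codistill_history <- function(x, ...) {
  cat(sprintf("<codistill_history> %d round(s): %s\n",
              length(x$schedule), paste(x$schedule, collapse = "-")))
  print(x$report)
  invisible(x)
}

#' @export
tidy.codistill_history <- function(x, ...) x$report

#' @export
glance.codistill_history <- function(x, ...) {
  x$report |>
    dplyr::group_by(.data$round, .data$aggregator) |>
    dplyr::summarise(mean_auc_pre = mean(.data$auc_pre),
                     mean_auc_post = mean(.data$auc_post),
                     mean_mse_final = mean(.data$mse_final),
                     .groups = "drop")
}

#' Read a training configuration / schedule from YAML or JSON
#'
#' The file mirrors [train_config()] fields (`epochs`, `learning_rate`,
#' `momentum`, `validation_fraction`, `seed`) plus an optional `schedule`
#' list of aggregator tags for [run_schedule()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return List with `config` (a [train_config()]) and `schedule`
#'   (character vector or NULL).
#' @export
read_train_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      abort("reading JSON configs requires jsonlite")
    }
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("reading YAML configs requires the yaml package")
    }
    yaml::read_yaml(path)
  }
  defaults <- train_config()
  cfg <- train_config(
    epochs = raw$epochs %||% defaults$epochs,
    learning_rate = raw$learning_rate %||% defaults$learning_rate,
    momentum = raw$momentum %||% defaults$momentum,
    validation_fraction = raw$validation_fraction %||%
      defaults$validation_fraction,
    seed = raw$seed %||% defaults$seed)
  list(config = cfg, schedule = unlist(raw$schedule) %||% NULL)
}

#' Save and load student checkpoints
#'
#' Checkpoints carry the student's `version` field and are validated on
#' load, so incompatible checkpoints fail fast instead of mis-scoring.
#'
#' @param student A student object.
#' @param path Checkpoint path.
#' @return `path` (save) or the restored student (load).
#' @export
save_student <- function(student, path) {
  if (is.null(student$version)) abort("student lacks a version field")
  saveRDS(list(version = student$version, student = student), path)
  invisible(path)
}

#' @rdname save_student
#' @export
load_student <- function(path) {
  chk <- readRDS(path)
  if (!is.list(chk) || is.null(chk$version)) {
    abort("not a student checkpoint")
  }
  if (chk$version != 1L) {
    abort(sprintf("unsupported checkpoint version %s", chk$version))
  }
  chk$student
}

#' Distill a teacher scorer into a student
#'
#' The teacher scores every protein; the student trains on those LLR grids
#' with the masked MSE. Proteins are split into train and held-out sets; the
#' report carries the Spearman correlation between student and teacher
#' scores on the held-out proteins before and after training.
#'
#' @param teacher Any scorer or student.
#' @param student The student to train.
#' @param proteins Tibble of protein records.
#' @param config A [train_config()].
#' @param holdout_fraction Fraction of proteins held out for the correlation
#'   check (default 0.25, at least one protein).
#' @return List with `student`, `trace`, `spearman_pre`, `spearman_post`,
#'   `holdout_ids`.
#' @export
knowledge_distill <- function(teacher, student, proteins,
                              config = train_config(),
                              holdout_fraction = 0.25) {
  n <- nrow(proteins)
  n_hold <- max(1L, floor(holdout_fraction * n))
  if (n_hold >= n) abort("need at least one training protein")
  hold_idx <- withr_seed(config$seed, sample.int(n, n_hold))
  train_prot <- proteins[-hold_idx, ]
  hold_prot <- proteins[hold_idx, ]
  teach <- predict_all(list(teacher = teacher), proteins)$teacher
  spearman_pre <- heldout_spearman(student, teach, hold_prot)
  fit <- train_student(student, train_prot, teach, config)
  spearman_post <- heldout_spearman(fit$student, teach, hold_prot)
  list(student = fit$student, trace = fit$trace,
       spearman_pre = spearman_pre, spearman_post = spearman_post,
       holdout_ids = hold_prot$id)
}

heldout_spearman <- function(student, teacher_mats, proteins) {
  s_vals <- c(); t_vals <- c()
  for (i in seq_len(nrow(proteins))) {
    id <- proteins$id[i]
    sm <- score_llr(student, proteins[i, ])
    tm <- teacher_mats[[id]]
    keep <- !llr_mask(tm) & !wt_cells(tm)
    s_vals <- c(s_vals, unclass(sm)[keep])
    t_vals <- c(t_vals, unclass(tm)[keep])
  }
  if (sd(s_vals) == 0 || sd(t_vals) == 0) return(0)
  cor(s_vals, t_vals, method = "spearman")
}

#' Score a table of variants with a scorer or student
#'
#' @param scorer Scorer or student.
#' @param proteins Tibble of protein records covering every `protein_id` in
#'   `variants`.
#' @param variants Tibble with `protein_id`, `position`, `ref_aa`, `alt_aa`.
#' @return `variants` with a `score` column appended.
#' @export
score_variant_table <- function(scorer, proteins, variants) {
  mats <- predict_all(list(s = scorer), proteins)$s
  variants$score <- purrr::pmap_dbl(
    variants[c("protein_id", "position", "ref_aa", "alt_aa")],
    function(protein_id, position, ref_aa, alt_aa) {
      m <- mats[[protein_id]]
      if (is.null(m)) abort(sprintf("no protein record for %s", protein_id))
      variant_score(m, position, ref_aa, alt_aa)
    })
  variants
}

student_eval_auc <- function(student, proteins, eval_set) {
  scored <- score_variant_table(student, proteins, eval_set)
  scored <- dplyr::filter(scored, is.finite(.data$score))
  auc(scored$score, scored$label)
}
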