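# small family reused across blocks
fx <- blindspot_fixture(seed = 3, n_proteins = 10L, len = 100L)

test_that("targets from a single student are its own scores (shift 0)", {
  st <- knowledge_distill(fx$scorers$A,
                          window_student(radius = 1, length = 100),
                          fx$proteins, train_config(epochs = 30, seed = 1),
                          holdout_fraction = 0.2)$student
  tg <- build_targets(list(solo = st), fx$proteins, "min")
  expect_equal(tg$shifts[["solo"]], 0, tolerance = 1e-9)
  own <- score_llr(st, fx$proteins[1, ])
  expect_equal(unclass(tg$targets$solo[[fx$proteins$id[1]]]), unclass(own),
               tolerance = 1e-9)
})

test_that("two-student targets equal the elementwise aggregate plus per-student shift", {
  students <- list(a = fx$scorers$A, b = fx$scorers$B)  # scorers obey the contract
  for (aggr in c("min", "mean")) {
    tg <- build_targets(students, fx$proteins, aggr)
    mats_a <- lapply(seq_len(nrow(fx$proteins)),
                     function(i) score_llr(fx$scorers$A, fx$proteins[i, ]))
    mats_b <- lapply(seq_len(nrow(fx$proteins)),
                     function(i) score_llr(fx$scorers$B, fx$proteins[i, ]))
    names(mats_a) <- names(mats_b) <- fx$proteins$id
    id <- fx$proteins$id[2]
    stack <- score_stack(list(a = mats_a[[id]], b = mats_b[[id]]))
    agg <- if (aggr == "min") aggregate_min(stack)$llr
           else aggregate_mean(stack)$llr
    expected <- maxvep:::shift_llr(agg, tg$shifts[["a"]])
    expect_equal(unclass(tg$targets$a[[id]]), unclass(expected),
                 tolerance = 1e-9)
  }
})

test_that("training reduces the masked MSE far below its initial value", {
  small <- blindspot_fixture(seed = 9, n_proteins = 5L, len = 80L)
  teacher <- make_blindspot_scorers(
    small$fam, detectability = list(t = c("domainA", "domainB")))$t
  targets <- maxvep:::predict_all(list(t = teacher), small$proteins)$t
  fit <- train_student(window_student(radius = 2, length = 80),
                       small$proteins, targets,
                       train_config(epochs = 200, seed = 1))
  expect_equal(nrow(fit$trace), 200L)
  expect_lt(fit$final_mse, 0.1 * fit$trace$train_mse[1])
})

test_that("config validation rejects zero epochs and bad fractions", {
  expect_error(train_config(epochs = 0), "epochs")
  expect_error(train_config(validation_fraction = 1), "validation_fraction")
  expect_error(train_config(momentum = 1), "momentum")
})

test_that("a student already at its targets is a fixed point", {
  st <- knowledge_distill(fx$scorers$A, window_student(radius = 1, length = 100),
                          fx$proteins, train_config(epochs = 30, seed = 2),
                          holdout_fraction = 0.2)$student
  own <- maxvep:::predict_all(list(s = st), fx$proteins)$s
  fit <- train_student(st, fx$proteins, own, train_config(epochs = 5, seed = 1))
  expect_lt(fit$final_mse, 1e-20)
  expect_equal(fit$student$W, st$W, tolerance = 1e-12)
})

test_that("training is deterministic given config and seed", {
  st <- window_student(radius = 1, length = 100, init_sd = 0.01, seed = 5)
  targets <- maxvep:::predict_all(list(s = fx$scorers$A), fx$proteins)$s
  cfg <- train_config(epochs = 20, validation_fraction = 0.2, seed = 3)
  f1 <- train_student(st, fx$proteins, targets, cfg)
  f2 <- train_student(st, fx$proteins, targets, cfg)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$student$W, f2$student$W)
})

test_that("targets stay fixed while students train within a round", {
  students <- list(
    a = knowledge_distill(fx$scorers$A, window_student(radius = 1, length = 100),
                          fx$proteins, train_config(epochs = 20, seed = 1))$student,
    b = knowledge_distill(fx$scorers$B, window_student(radius = 1, length = 100),
                          fx$proteins, train_config(epochs = 20, seed = 1))$student)
  tg <- build_targets(students, fx$proteins, "min")
  snapshot <- lapply(tg$targets$a, unclass)
  round <- codistill_round(students, fx$proteins, "min",
                           train_config(epochs = 10, seed = 1))
  expect_identical(lapply(round$targets$targets$a, unclass), snapshot)
})

test_that("self-distillation of one student leaves its scores nearly unchanged", {
  st <- knowledge_distill(fx$scorers$A, window_student(radius = 1, length = 100),
                          fx$proteins, train_config(epochs = 30, seed = 4))$student
  before <- score_llr(st, fx$proteins[1, ])
  round <- codistill_round(list(solo = st), fx$proteins, "min",
                           train_config(epochs = 5, seed = 1))
  after <- score_llr(round$students$solo, fx$proteins[1, ])
  expect_equal(unclass(after), unclass(before), tolerance = 1e-6)
})

test_that("a maximum-confidence round lifts complementary students' AUCs", {
  cfg <- train_config(epochs = 40, seed = 3)
  students <- purrr::imap(fx$scorers, function(sc, nm) {
    knowledge_distill(sc, window_student(radius = 2, length = 100,
                                         name = paste0("st_", nm)),
                      fx$proteins, cfg, holdout_fraction = 0.25)$student
  })
  round <- codistill_round(students, fx$proteins, "min", cfg,
                           eval_set = fx$variants)
  expect_true(all(round$report$auc_post >= round$report$auc_pre))
  expect_gt(mean(round$report$auc_post), mean(round$report$auc_pre) + 0.05)
})

test_that("schedules chain rounds from previous student states", {
  cfg <- train_config(epochs = 25, seed = 6)
  students <- purrr::imap(fx$scorers, function(sc, nm) {
    knowledge_distill(sc, window_student(radius = 2, length = 100,
                                         name = paste0("st_", nm)),
                      fx$proteins, cfg, holdout_fraction = 0.25)$student
  })
  one <- run_schedule(students, fx$proteins, "min", cfg, eval_set = fx$variants)
  expect_equal(nrow(one$report), 2L)
  two <- run_schedule(students, fx$proteins, c("min", "mean"), cfg,
                      eval_set = fx$variants)
  # round 1 of the two-round schedule equals the single-round run
  expect_equal(dplyr::filter(two$report, round == 1)[names(one$report)],
               dplyr::mutate(one$report, round = 1L, .before = 1L)[names(one$report)])
  # the glance summary aggregates per round
  g <- glance(two)
  expect_equal(nrow(g), 2L)
  expect_true(all(g$mean_auc_post >= g$mean_auc_pre - 0.02))
})

test_that("configs read from YAML/JSON and checkpoints round-trip", {
  skip_if_not_installed("yaml")
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("epochs: 12", "learning_rate: 0.3", "seed: 9",
               "schedule:", "  - min", "  - mean"), yml)
  got <- read_train_config(yml)
  expect_equal(got$config$epochs, 12L)
  expect_equal(got$config$learning_rate, 0.3)
  expect_equal(got$config$momentum, train_config()$momentum)
  expect_equal(got$schedule, c("min", "mean"))

  st <- window_student(radius = 1, length = 100, init_sd = 0.01, seed = 2)
  ck <- withr::local_tempfile(fileext = ".ckpt")
  save_student(st, ck)
  back <- load_student(ck)
  expect_identical(back$W, st$W)
  p <- fx$proteins[1, ]
  expect_equal(unclass(score_llr(back, p)), unclass(score_llr(st, p)))
  bad <- withr::local_tempfile()
  saveRDS(list(foo = 1), bad)
  expect_error(load_student(bad), "checkpoint")
})

test_that("knowledge distillation raises held-out teacher correlation", {
  fam <- generate_family(12, 100, seed = 21)
  teacher <- make_blindspot_scorers(
    fam, detectability = list(t = c("domainA", "domainB")))$t
  kd <- knowledge_distill(teacher, window_student(radius = 2, length = 100),
                          fam$proteins, train_config(epochs = 200, seed = 1),
                          holdout_fraction = 0.25)
  expect_gt(kd$spearman_post, kd$spearman_pre)
  expect_gte(kd$spearman_post, 0.9)
  # capacity-limited student improves but stays short of self-correlation 1
  kd2 <- knowledge_distill(teacher, window_student(radius = 1),
                           fam$proteins, train_config(epochs = 100, seed = 1),
                           holdout_fraction = 0.25)
  expect_gt(kd2$spearman_post, kd2$spearman_pre)
  expect_lt(kd2$spearman_post, 0.95)
})
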