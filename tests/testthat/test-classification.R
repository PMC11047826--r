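# small two-feature cohort builder with planted group means/sds
two_feature_cohort <- function(n_per_class, mu1, sd1, mu2, sd2,
                               name1 = "ex.f1", name2 = "ex.f2") {
  n <- sum(n_per_class)
  lab <- rep(c("no_DN", "DN"), n_per_class)
  df <- data.frame(
    subject_id = sprintf("s%04d", seq_len(n)), label = lab,
    stringsAsFactors = FALSE)
  df[[name1]] <- ifelse(lab == "no_DN", rnorm(n, mu1[1], sd1[1]),
                        rnorm(n, mu1[2], sd1[2]))
  df[[name2]] <- ifelse(lab == "no_DN", rnorm(n, mu2[1], sd2[1]),
                        rnorm(n, mu2[2], sd2[2]))
  cohort_dataset(df)
}

test_that("select_features keeps exactly one of two identical columns", {
  set.seed(51)
  co <- two_feature_cohort(c(50, 50), c(0, 1), c(1, 1), c(0, 1), c(1, 1))
  co$ex.f2 <- co$ex.f1    # bit-identical duplicate, r = 1
  kept <- select_features(co, "ex")
  expect_length(kept, 1)
  expect_equal(kept, "ex.f1")   # name order tie-break is deterministic
})

# two-sided power of the pooled t-test at alpha = 0.05
pooled_t_power <- function(m1, s1, m2, s2, n) {
  d <- abs(m1 - m2) / sqrt((s1^2 + s2^2) / 2)
  ncp <- d * sqrt(n / 2)
  df <- 2 * n - 2
  crit <- qt(0.975, df)
  1 - pt(crit, df, ncp) + pt(-crit, df, ncp)
}

test_that("select_features drops noise and keeps a strong effect", {
  # d = 2 effect: power ~ 1, always retained; pure-noise feature retained
  # only on a type-I error, so eliminated at rate 1 - alpha = 0.95
  effect_kept <- 0L; noise_dropped <- 0L
  nrep <- 100
  for (i in seq_len(nrep)) {
    set.seed(500 + i)
    co <- two_feature_cohort(c(200, 200),
                             mu1 = c(0, 2), sd1 = c(1, 1),    # d = 2 effect
                             mu2 = c(0, 0), sd2 = c(1, 1))    # pure noise
    kept <- tryCatch(select_features(co, "ex"), error = function(e) character(0))
    if ("ex.f1" %in% kept) effect_kept <- effect_kept + 1L
    if (!("ex.f2" %in% kept)) noise_dropped <- noise_dropped + 1L
  }
  expect_equal(effect_kept, nrep)
  expect_gte(noise_dropped, nrep * (0.95 - 3 * sqrt(0.95 * 0.05 / nrep)))
})

test_that("selection on pilot heel-toe templates follows the power oracle", {
  # feature_01 analog (0.011/0.005 vs 0.005/0.003): d ~ 1.5, power ~ 1 at
  # n = 200/class, so always retained; feature_02 analog (1.481/0.369 vs
  # 1.402/0.334): d ~ 0.22, eliminated at the rate 1 - power
  f1_kept <- 0L; f2_dropped <- 0L
  nrep <- 100
  for (i in seq_len(nrep)) {
    set.seed(700 + i)
    co <- two_feature_cohort(c(200, 200),
                             mu1 = c(0.011, 0.005), sd1 = c(0.005, 0.003),
                             mu2 = c(1.481, 1.402), sd2 = c(0.369, 0.334))
    kept <- tryCatch(select_features(co, "ex"), error = function(e) character(0))
    if ("ex.f1" %in% kept) f1_kept <- f1_kept + 1L
    if (!("ex.f2" %in% kept)) f2_dropped <- f2_dropped + 1L
  }
  expect_gte(f1_kept, 95)
  p_drop <- 1 - pooled_t_power(1.481, 0.369, 1.402, 0.334, 200)
  se <- sqrt(p_drop * (1 - p_drop) / nrep)
  expect_lt(abs(f2_dropped / nrep - p_drop), 3 * se)
})

test_that("select_features errors when nothing survives", {
  set.seed(53)
  co <- two_feature_cohort(c(30, 30), c(0, 0), c(1, 1), c(0, 0), c(1, 1))
  expect_error(select_features(co, "ex", p_threshold = 1e-6), "relax")
})

test_that("all three model kinds separate well-separated blobs perfectly", {
  set.seed(54)
  co <- two_feature_cohort(c(60, 60), c(0, 10), c(0.5, 0.5),
                           c(0, 10), c(0.5, 0.5))
  for (kind in c("svm", "logistic_regression", "decision_tree")) {
    m <- train_exercise_model(co, "ex", c("ex.f1", "ex.f2"),
                              model_kind = kind, seed = 1)
    p <- predict_exercise_model(m, co)
    expect_equal(mean((p >= 0.5) == (co$label == "DN")), 1.0,
                 info = kind)
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("permuted labels give chance-level cross-validated accuracy", {
  set.seed(55)
  co <- two_feature_cohort(c(200, 200), c(0, 1.5), c(1, 1), c(0, 1), c(1, 1))
  co$label <- sample(co$label)   # break the association
  m <- train_exercise_model(co, "ex", c("ex.f1", "ex.f2"),
                            model_kind = "svm", seed = 2)
  best_cv <- max(m$cv_table$cv_accuracy)
  expect_gte(best_cv, 0.4)
  expect_lte(best_cv, 0.6)
})

test_that("grid search is deterministic for a fixed seed", {
  set.seed(56)
  co <- two_feature_cohort(c(80, 80), c(0, 1), c(1, 1), c(0, 0.5), c(1, 1))
  m1 <- train_exercise_model(co, "ex", c("ex.f1", "ex.f2"), seed = 11)
  m2 <- train_exercise_model(co, "ex", c("ex.f1", "ex.f2"), seed = 11)
  expect_identical(m1$best_params, m2$best_params)
  expect_identical(m1$cv_table$cv_accuracy, m2$cv_table$cv_accuracy)
  expect_error(train_exercise_model(co[co$label == "DN", ], "ex",
                                    c("ex.f1", "ex.f2")), "single class")
})

test_that("split_dataset partitions 423 rows into 296/127 stratified", {
  co <- pilot_cohort(seed = 61)
  aug <- augment_dataset(co, seed = 62)
  sp <- split_dataset(aug, seed = 63)
  expect_lte(abs(nrow(sp$train) - 296), 1)
  expect_lte(abs(nrow(sp$test) - 127), 1)
  # disjoint + exhaustive
  expect_equal(sort(c(sp$train$subject_id, sp$test$subject_id)),
               sort(aug$subject_id))
  expect_length(intersect(sp$train$subject_id, sp$test$subject_id), 0)
  # originals present on the test side roughly proportionally
  expect_gt(sum(sp$test$provenance == "original"), 0)
  expect_error(split_dataset(aug, train_fraction = 1.0), "between 0 and 1")
})

test_that("aggregation is the arithmetic mean of the exercise outputs", {
  set.seed(64)
  # hand-built ensemble of trivial models via the real surface
  mk_cohort <- function(ex) {
    df <- data.frame(subject_id = sprintf("s%02d", 1:40),
                     label = rep(c("no_DN", "DN"), each = 20))
    df[[paste0(ex, ".f")]] <- ifelse(df$label == "DN", rnorm(40, 5), rnorm(40))
    cohort_dataset(df)
  }
  exs <- exercise_registry()$exercise
  big <- mk_cohort(exs[1])
  for (ex in exs[-1])
    big <- cohort_dataset(cbind(big, mk_cohort(ex)[paste0(ex, ".f")]))
  ens <- build_ensemble(big, model_kind = "logistic_regression", seed = 3)
  scr <- aggregate_ensemble(ens, big)
  pm <- as.matrix(scr[, paste0("p_", exs)])
  expect_equal(scr$aggregated, rowMeans(pm), tolerance = 1e-12)
  expect_true(all(scr$aggregated >= 0 & scr$aggregated <= 1))
  # permutation invariance over exercises
  expect_equal(scr$aggregated,
               rowMeans(pm[, sample(ncol(pm))]), tolerance = 1e-12)
  # missing exercise: hard error unless renormalized
  sub <- big[, !startsWith(names(big), exs[1])]
  expect_error(aggregate_ensemble(ens, sub), "missing")
  scr2 <- aggregate_ensemble(ens, sub, renormalize = TRUE)
  expect_equal(scr2$aggregated,
               rowMeans(pm[, paste0("p_", exs[-1])]), tolerance = 1e-12)
})

test_that("screening probabilities agree with a brute-force mean oracle", {
  set.seed(65)
  for (i in 1:5) {
    pm <- matrix(runif(200 * 6), ncol = 6)
    oracle <- apply(pm, 1, function(r) sum(r) / 6)
    expect_equal(rowMeans(pm), oracle, tolerance = 1e-15)
  }
})

test_that("evaluate_predictions reproduces hand-computed confusion metrics", {
  perfect <- evaluate_predictions(c(0.9, 0.9, 0.1, 0.1),
                                  c("DN", "DN", "no_DN", "no_DN"))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$auc, 1)

  # TP=7 FN=2 TN=13 FP=1
  truth <- c(rep("DN", 9), rep("no_DN", 14))
  prob <- c(rep(0.9, 7), rep(0.1, 2), rep(0.1, 13), 0.9)
  r <- evaluate_predictions(prob, truth)
  expect_equal(r$sensitivity, 7 / 9, tolerance = 1e-12)
  expect_equal(r$specificity, 13 / 14, tolerance = 1e-12)
  expect_equal(r$accuracy, 20 / 23, tolerance = 1e-12)
  expect_equal(r$per_class$support, c(14, 9))
  # prevalence-weighted identity
  prev <- 9 / 23
  expect_equal(r$accuracy, r$sensitivity * prev + r$specificity * (1 - prev),
               tolerance = 1e-12)
})

test_that("random scores give chance-level AUC and match pROC", {
  set.seed(66)
  n <- 4000
  prob <- runif(n)
  truth <- sample(c("no_DN", "DN"), n, replace = TRUE)
  r <- evaluate_predictions(prob, truth)
  se <- sqrt(0.25 / min(table(truth)))   # conservative null-AUC SE bound
  expect_lt(abs(r$auc - 0.5), 3 * se)
  # independent trapezoid oracle
  skip_if_not_installed("pROC")
  auc_ref <- as.numeric(pROC::auc(pROC::roc(
    response = truth, predictor = prob, levels = c("no_DN", "DN"),
    direction = "<", quiet = TRUE)))
  expect_equal(r$auc, auc_ref, tolerance = 1e-10)
})

test_that("single-class truth yields a partial report with a warning", {
  expect_warning(r <- evaluate_predictions(c(0.8, 0.7), c("DN", "DN")),
                 "single-class")
  expect_equal(r$sensitivity, 1)
  expect_null(r$auc)
})

test_that("aggregated ensemble discriminates at least as well as single models", {
  # aggregated AUC >= max single-exercise AUC - 0.05, across seeds
  for (s in 1:5) {
    r <- run_cohort_experiment(3000 + s,
                               n_per_group = c(no_DN = 60, DN = 60))
    scr <- r$screening
    single_aucs <- vapply(
      grep("^p_", names(scr), value = TRUE),
      function(col) suppressWarnings(
        evaluate_predictions(scr[[col]], r$truth)$auc),
      numeric(1))
    expect_gte(r$metrics$auc, max(single_aucs) - 0.05)
  }
})
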