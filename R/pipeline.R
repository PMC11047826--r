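#' Run one end-to-end synthetic-cohort screening experiment
#'
#' The full study protocol on a synthetic feature cohort: simulate a
#' labelled cohort from the pilot templates, expand it by class-conditional
#' KDE augmentation, make a stratified train/test split, select features
#' and tune one classifier per exercise on the training side, average the
#' per-exercise probabilities on the test side and score the calls.
#'
#' @param seed Integer seed driving every stochastic step.
#' @param n_per_group Original subjects per group before augmentation
#'   (default 100 per group).
#' @param features Feature templates; default the 12 most discriminative
#'   pilot features ([feature_templates()] with `important_only = TRUE`).
#' @param config A [run_config()] for augmentation counts, split fraction,
#'   model kind and threshold.
#' @return A list with `metrics` (a [evaluate_predictions()] report),
#'   `ensemble`, `screening` (test-side [aggregate_ensemble()] result),
#'   `truth` (test-side labels) and the split sizes.
#' @export
run_cohort_experiment <- function(seed,
                                  n_per_group = c(no_DN = 100, DN = 100),
                                  features = feature_templates(
                                    important_only = TRUE),
                                  config = run_config(seed = seed)) {
  seed <- as.integer(seed)
  spec <- cohort_sim_spec(n_per_group = n_per_group, features = features,
                          edx = NULL, demographics = NULL, seed = seed)
  cohort <- simulate_feature_cohort(spec)
  aug <- augment_dataset(cohort, n_negative = config$n_negative,
                         n_positive = config$n_positive, seed = seed + 1L)
  sp <- split_dataset(aug, train_fraction = config$train_fraction,
                      seed = seed + 2L)
  ens <- build_ensemble(sp$train, model_kind = config$model_kind,
                        seed = seed + 3L, threshold = config$threshold)
  scr <- aggregate_ensemble(ens, sp$test)
  metrics <- evaluate_predictions(scr$aggregated, sp$test$label,
                                  threshold = config$threshold)
  list(metrics = metrics, ensemble = ens, screening = scr,
       truth = sp$test$label,
       n_train = nrow(sp$train), n_test = nrow(sp$test))
}

#' Average ensemble operating characteristics over repeated experiments
#'
#' Repeats [run_cohort_experiment()] across seeds and averages test-side
#' sensitivity, specificity, accuracy and AUC — the Monte-Carlo summary
#' used to characterize the screening pipeline on synthetic cohorts.
#'
#' @param seeds Integer vector of seeds (one experiment each).
#' @param ... Passed to [run_cohort_experiment()].
#' @return A list with `mean` (named vector) and `per_seed` (data.frame of
#'   per-seed metrics).
#' @export
summarize_experiments <- function(seeds, ...) {
  per <- do.call(rbind, lapply(seeds, function(s) {
    r <- run_cohort_experiment(s, ...)
    data.frame(seed = s,
               sensitivity = r$metrics$sensitivity,
               specificity = r$metrics$specificity,
               accuracy = r$metrics$accuracy,
               auc = if (is.null(r$metrics$auc)) NA_real_ else r$metrics$auc,
               n_test = r$n_test)
  }))
  list(mean = c(sensitivity = mean(per$sensitivity),
                specificity = mean(per$specificity),
                accuracy = mean(per$accuracy),
                auc = mean(per$auc)),
       per_seed = per)
}

#' Extract the feature cohort of a set of simulated subjects
#'
#' Signal-level companion to [run_cohort_experiment()]: simulates raw
#' recordings per subject at a given severity, runs the real
#' signal-processing and feature-extraction chain, and assembles a
#' [cohort_dataset()] of spectral band features.
#'
#' @param n_per_group Subjects per group.
#' @param exercises Exercises to record (default all six).
#' @param severity_DN Severity planted for the `DN` group (the `no_DN`
#'   group uses 0).
#' @param seed Integer seed.
#' @param config A [feature_config()].
#' @param duration Seconds per recording.
#' @return A [cohort_dataset()].
#' @export
simulate_signal_cohort <- function(n_per_group = c(no_DN = 5, DN = 5),
                                   exercises = exercise_registry()$exercise,
                                   severity_DN = 0.8, seed = 1L,
                                   config = feature_config(),
                                   duration = 10) {
  rows <- list()
  sidx <- 0L
  for (g in c("no_DN", "DN")) {
    sev <- if (g == "DN") severity_DN else 0
    for (i in seq_len(n_per_group[[g]])) {
      sidx <- sidx + 1L
      sid <- sprintf("s%03d", sidx)
      feats <- list()
      for (k in seq_along(exercises)) {
        ex <- exercises[k]
        spec <- signal_sim_spec(ex, severity = sev, duration = duration,
                                seed = seed + 7919L * sidx + 97L * k)
        fv <- extract_features(simulate_exercise_set(spec, subject_id = sid),
                               config = config)
        v <- fv$features
        names(v) <- paste(ex, names(v), sep = ".")
        feats[[ex]] <- v
      }
      row <- as.data.frame(as.list(unlist(feats, use.names = FALSE)))
      names(row) <- unlist(lapply(feats, names), use.names = FALSE)
      row$subject_id <- sid
      row$label <- g
      rows[[sidx]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  cohort_dataset(out)
}
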