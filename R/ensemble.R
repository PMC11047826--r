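#' Build the per-exercise classifier ensemble
#'
#' For each exercise present in the training cohort this selects features
#' ([select_features()]) and fits one tuned classifier
#' ([train_exercise_model()]). The screening call later averages the
#' per-exercise positive-class probabilities.
#'
#' @param train Training [cohort_dataset()].
#' @param exercises Exercises to include; defaults to all exercises found
#'   in the cohort's feature columns.
#' @param model_kind Classifier family for every exercise (`"svm"`,
#'   `"logistic_regression"` or `"decision_tree"`).
#' @param p_threshold,corr_threshold Passed to [select_features()]. If no
#'   feature survives for an exercise, all of that exercise's candidates
#'   are used instead (with a warning), so the ensemble always has one
#'   model per exercise.
#' @param grid Optional hyperparameter grid; default [default_grid()].
#' @param seed Integer seed; each exercise uses a deterministic offset.
#' @param threshold Decision threshold on the aggregated probability
#'   (default 0.5).
#' @return An object of class `ensemble_model`.
#' @export
build_ensemble <- function(train, exercises = NULL, model_kind = "svm",
                           p_threshold = 0.05, corr_threshold = 0.9,
                           grid = NULL, seed = NULL, threshold = 0.5) {
  train <- cohort_dataset(train)
  if (is.null(exercises)) exercises <- cohort_exercises(train)
  stopifnot(length(exercises) >= 1L)
  models <- list()
  for (i in seq_along(exercises)) {
    ex <- exercises[[i]]
    feats <- tryCatch(
      select_features(train, ex, p_threshold, corr_threshold),
      error = function(e) {
        warning(sprintf(
          "build_ensemble: no feature passed selection for '%s'; using all",
          ex))
        feature_columns(train, ex)
      })
    sub_seed <- if (is.null(seed)) NULL else seed + 131L * i
    models[[ex]] <- train_exercise_model(
      train, ex, feats, model_kind = model_kind, grid = grid,
      seed = sub_seed)
  }
  structure(list(models = models, exercises = exercises,
                 model_kind = model_kind, threshold = threshold,
                 seed = seed),
            class = "ensemble_model")
}

#' Aggregate the six per-exercise outputs into a screening result
#'
#' The screening probability is the arithmetic mean of the per-exercise
#' classifier probabilities, `(1/m) * sum_i ExerciseModel_i(X_i)` with
#' `m` the number of exercise models (six in the full protocol), and the
#' binary call compares it to the decision threshold. By default every
#' exercise model must be applicable to every subject; with
#' `renormalize = TRUE` (home-use robustness) a missing exercise's columns
#' drop that model and the mean renormalizes over the rest.
#'
#' @param ensemble An [build_ensemble()] result.
#' @param cohort Data with the feature columns the models need.
#' @param renormalize Allow missing exercises (default `FALSE`).
#' @return A `screening_result` data.frame: `subject_id`, one probability
#'   column `p_<exercise>` per model, `aggregated`, and `call`
#'   (`"no_DN"`/`"DN"`).
#' @export
aggregate_ensemble <- function(ensemble, cohort, renormalize = FALSE) {
  stopifnot(inherits(ensemble, "ensemble_model"))
  probs <- list()
  for (ex in names(ensemble$models)) {
    m <- ensemble$models[[ex]]
    have <- all(m$features %in% names(cohort))
    if (!have) {
      if (!renormalize)
        stop(sprintf(
          "aggregate_ensemble: exercise '%s' features missing; %s", ex,
          "supply them or set renormalize = TRUE"))
      next
    }
    probs[[ex]] <- predict_exercise_model(m, cohort)
  }
  if (length(probs) == 0L)
    stop("aggregate_ensemble: no exercise model applicable")
  pm <- do.call(cbind, probs)
  agg <- rowMeans(pm)
  out <- data.frame(subject_id = if ("subject_id" %in% names(cohort))
    cohort$subject_id else seq_len(nrow(pm)))
  for (ex in colnames(pm)) out[[paste0("p_", ex)]] <- pm[, ex]
  out$aggregated <- agg
  out$call <- ifelse(agg >= ensemble$threshold, "DN", "no_DN")
  class(out) <- c("screening_result", class(out))
  out
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("<ensemble_model> %d x %s, threshold %.2f\n",
              length(x$models), x$model_kind, x$threshold))
  for (m in x$models)
    cat(sprintf("  %-16s %d feature(s): %s\n", m$exercise,
                length(m$features),
                paste(m$features, collapse = ", ")))
  invisible(x)
}
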