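#' Default hyperparameter grids
#'
#' SVM searches kernel (linear / radial basis / polynomial) crossed with
#' the cost parameter; logistic regression searches the ridge penalty
#' strength; the decision tree searches maximum depth.
#'
#' @param model_kind `"svm"`, `"logistic_regression"` or `"decision_tree"`.
#' @return A data.frame, one row per grid point.
#' @export
default_grid <- function(model_kind = c("svm", "logistic_regression",
                                        "decision_tree")) {
  model_kind <- match.arg(model_kind)
  switch(model_kind,
    svm = expand.grid(kernel = c("linear", "radial", "polynomial"),
                      cost = c(0.1, 1, 10),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE),
    logistic_regression = data.frame(lambda = c(0.0001, 0.001, 0.01, 0.1, 1)),
    decision_tree = data.frame(maxdepth = c(2L, 3L, 4L, 6L, 8L)))
}

# deterministic stratified k-fold assignment
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- sample(idx)           # uses ambient RNG (seeded by caller)
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

fit_one <- function(x, y, model_kind, params) {
  if (model_kind == "svm") {
    e1071::svm(x, y, kernel = as.character(params$kernel), cost = params$cost,
               probability = TRUE, scale = TRUE)
  } else if (model_kind == "logistic_regression") {
    # ridge logistic; glmnet needs >= 2 columns, duplicate if necessary
    xm <- if (ncol(x) == 1L) cbind(x, 0) else x
    glmnet::glmnet(xm, y, family = "binomial", alpha = 0,
                   lambda = params$lambda)
  } else {
    df <- data.frame(x, check.names = FALSE)
    df$.y <- y
    rpart::rpart(.y ~ ., data = df, method = "class",
                 control = rpart::rpart.control(maxdepth = params$maxdepth,
                                                cp = 0, xval = 0))
  }
}

predict_prob_one <- function(fit, x, model_kind, positive = "DN") {
  if (model_kind == "svm") {
    pr <- stats::predict(fit, x, probability = TRUE)
    attr(pr, "probabilities")[, positive]
  } else if (model_kind == "logistic_regression") {
    xm <- if (ncol(x) == 1L) cbind(x, 0) else x
    p <- stats::predict(fit, newx = xm, type = "response")[, 1]
    # glmnet models P(second factor level); our factors are (no_DN, DN)
    p
  } else {
    stats::predict(fit, data.frame(x, check.names = FALSE))[, positive]
  }
}

#' Train one exercise's classifier with cross-validated grid search
#'
#' Fits the requested model kind for a single exercise on the cohort's
#' selected features, choosing hyperparameters by stratified k-fold
#' cross-validated accuracy over the grid (first-best wins on ties, so a
#' fixed seed reproduces the same choice), then refits on all rows.
#'
#' @param cohort Training [cohort_dataset()] containing both classes.
#' @param exercise Exercise name (used to label the model).
#' @param features Character vector of feature columns to use (e.g. from
#'   [select_features()]).
#' @param model_kind `"svm"` (default), `"logistic_regression"` or
#'   `"decision_tree"`.
#' @param grid Hyperparameter grid; default [default_grid()].
#' @param seed Integer seed controlling fold assignment and any stochastic
#'   fitting steps.
#' @param n_folds Cross-validation folds (default 3).
#' @return An object of class `exercise_model` holding the fitted
#'   classifier, the chosen grid row and the cross-validation table.
#' @export
train_exercise_model <- function(cohort, exercise, features,
                                 model_kind = c("svm", "logistic_regression",
                                                "decision_tree"),
                                 grid = NULL, seed = NULL, n_folds = 3L) {
  cohort <- cohort_dataset(cohort)
  model_kind <- match.arg(model_kind)
  if (is.null(grid)) grid <- default_grid(model_kind)
  missing_feats <- setdiff(features, names(cohort))
  if (length(missing_feats) > 0)
    stop("train_exercise_model: features not in cohort: ",
         paste(missing_feats, collapse = ", "))
  y <- factor(cohort$label, levels = c("no_DN", "DN"))
  if (nlevels(droplevels(y)) < 2L)
    stop("train_exercise_model: training data contain a single class")
  x <- as.matrix(cohort[, features, drop = FALSE])
  if (!is.null(seed)) set.seed(seed)
  fold <- stratified_folds(as.character(y), n_folds)
  cv_acc <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    correct <- 0L
    for (k in seq_len(n_folds)) {
      tr <- fold != k
      if (nlevels(droplevels(y[tr])) < 2L) next
      if (!is.null(seed)) set.seed(seed + 104729L * gi + k)
      fit <- fit_one(x[tr, , drop = FALSE], y[tr], model_kind, grid[gi, , drop = FALSE])
      p <- predict_prob_one(fit, x[!tr, , drop = FALSE], model_kind)
      correct <- correct + sum((p >= 0.5) == (y[!tr] == "DN"))
    }
    cv_acc[gi] <- correct / length(y)
  }
  best <- which.max(cv_acc)    # first best: deterministic tie-break
  if (!is.null(seed)) set.seed(seed + 1L)
  fit <- fit_one(x, y, model_kind, grid[best, , drop = FALSE])
  structure(list(exercise = exercise, features = features,
                 model_kind = model_kind, fit = fit,
                 best_params = grid[best, , drop = FALSE],
                 cv_table = cbind(grid, cv_accuracy = cv_acc),
                 seed = seed, positive_class = "DN"),
            class = "exercise_model")
}

#' Positive-class probability from a fitted exercise model
#'
#' @param model An `exercise_model`.
#' @param cohort Data containing the model's feature columns.
#' @return Numeric vector of P(DN) in `[0, 1]`, one per row.
#' @export
predict_exercise_model <- function(model, cohort) {
  stopifnot(inherits(model, "exercise_model"))
  missing_feats <- setdiff(model$features, names(cohort))
  if (length(missing_feats) > 0)
    stop("predict_exercise_model: features not in data: ",
         paste(missing_feats, collapse = ", "))
  x <- as.matrix(cohort[, model$features, drop = FALSE])
  p <- predict_prob_one(model$fit, x, model$model_kind, model$positive_class)
  pmin(pmax(as.numeric(p), 0), 1)
}

#' @export
print.exercise_model <- function(x, ...) {
  cat(sprintf("<exercise_model> %s: %s on %d feature(s); chosen: %s\n",
              x$exercise, x$model_kind, length(x$features),
              paste(sprintf("%s=%s", names(x$best_params),
                            unlist(x$best_params)), collapse = ", ")))
  invisible(x)
}
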