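#' Confusion-matrix metrics, ROC curve and AUC for a screening run
#'
#' Computes, from predicted positive-class probabilities and true labels:
#' per-class precision / recall / F1 / support, sensitivity (recall of the
#' diseased class), specificity (recall of the non-diseased class), overall
#' accuracy, and an ROC curve (FPR, TPR over a sweep of thresholds) with
#' trapezoidal area under the curve.
#'
#' @param prob Numeric vector of P(DN) in `[0, 1]` (e.g. the `aggregated`
#'   column of [aggregate_ensemble()]'s result), or a `screening_result`.
#' @param truth Character/factor vector of true labels, `"no_DN"`/`"DN"`.
#' @param threshold Decision threshold for the binary call (default 0.5).
#' @return An object of class `metrics_report`: list with `confusion`
#'   (2x2 table), `per_class` data.frame, `sensitivity`, `specificity`,
#'   `accuracy`, `roc` (data.frame `threshold`, `fpr`, `tpr`) and `auc`.
#'   With single-class truth the ROC/AUC are omitted (with a warning) and
#'   the rest reported.
#' @export
evaluate_predictions <- function(prob, truth, threshold = 0.5) {
  if (inherits(prob, "screening_result")) prob <- prob$aggregated
  stopifnot(length(prob) == length(truth))
  if (any(prob < 0 | prob > 1)) stop("evaluate_predictions: prob outside [0,1]")
  truth <- as.character(truth)
  if (!all(truth %in% c("no_DN", "DN")))
    stop("evaluate_predictions: truth must be 'no_DN'/'DN'")
  pred <- ifelse(prob >= threshold, "DN", "no_DN")
  lv <- c("no_DN", "DN")
  confusion <- table(truth = factor(truth, lv), pred = factor(pred, lv))
  tp <- confusion["DN", "DN"]; fn <- confusion["DN", "no_DN"]
  tn <- confusion["no_DN", "no_DN"]; fp <- confusion["no_DN", "DN"]
  prec <- function(t, f) if (t + f == 0) NA_real_ else t / (t + f)
  per_class <- data.frame(
    class = lv,
    precision = c(prec(tn, fn), prec(tp, fp)),
    recall = c(prec(tn, fp), prec(tp, fn)),
    support = c(tn + fp, tp + fn))
  per_class$f1 <- with(per_class, ifelse(
    is.na(precision) | is.na(recall) | precision + recall == 0, NA_real_,
    2 * precision * recall / (precision + recall)))
  out <- list(confusion = confusion,
              per_class = per_class[, c("class", "precision", "recall",
                                        "f1", "support")],
              sensitivity = prec(tp, fn),
              specificity = prec(tn, fp),
              accuracy = (tp + tn) / length(truth),
              threshold = threshold)
  if (length(unique(truth)) < 2L) {
    warning("evaluate_predictions: single-class truth; ROC/AUC omitted")
  } else {
    roc <- roc_points(prob, truth)
    out$roc <- roc
    out$auc <- trapezoid_auc(roc$fpr, roc$tpr)
  }
  structure(out, class = "metrics_report")
}

# ROC sweep over the observed score values (plus sentinels)
roc_points <- function(prob, truth) {
  pos <- truth == "DN"
  thr <- c(Inf, sort(unique(prob), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(h) mean(prob[pos] >= h), numeric(1))
  fpr <- vapply(thr, function(h) mean(prob[!pos] >= h), numeric(1))
  data.frame(threshold = thr, fpr = fpr, tpr = tpr)
}

trapezoid_auc <- function(fpr, tpr) {
  o <- order(fpr, tpr)
  sum(diff(fpr[o]) * (utils::head(tpr[o], -1) + utils::tail(tpr[o], -1)) / 2)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  print(x$confusion)
  cat(sprintf("sensitivity %.3f  specificity %.3f  accuracy %.3f",
              x$sensitivity, x$specificity, x$accuracy))
  if (!is.null(x$auc)) cat(sprintf("  AUC %.3f", x$auc))
  cat("\n")
  invisible(x)
}
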