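#' One-by-one feature elimination by p-value and inter-feature correlation
#'
#' Screens a cohort's features for one exercise: features are eliminated
#' one at a time, always dropping the one with the largest two-sample
#' (pooled t-test) p-value, until every retained feature discriminates the
#' classes at `p_threshold`. Then, among retained pairs with absolute
#' Pearson correlation above `corr_threshold`, only the member with the
#' smaller p-value is kept, so no two near-redundant features enter the
#' model. Ties on p-value are broken by dropping the feature with the
#' larger mean absolute correlation to the other features, then by reverse
#' alphabetical order, making the procedure deterministic.
#'
#' @param cohort A [cohort_dataset()] containing both classes.
#' @param exercise Optional exercise name restricting the candidate
#'   columns; `NULL` uses every feature column.
#' @param p_threshold Retention p-value threshold (default 0.05).
#' @param corr_threshold Absolute correlation above which two features are
#'   considered redundant (default 0.9).
#' @return Character vector of retained feature column names. An error if
#'   no feature survives.
#' @export
select_features <- function(cohort, exercise = NULL, p_threshold = 0.05,
                            corr_threshold = 0.9) {
  cohort <- cohort_dataset(cohort)
  fc <- feature_columns(cohort, exercise)
  if (length(fc) < 1L) stop("select_features: no candidate features")
  g1 <- cohort$label == "no_DN"
  g2 <- cohort$label == "DN"
  if (!any(g1) || !any(g2))
    stop("select_features: both classes must be present")
  pval <- vapply(fc, function(nm) {
    two_sample_ttest(x = cohort[[nm]][g1], y = cohort[[nm]][g2])$p.value
  }, numeric(1))
  cormat <- abs(stats::cor(as.matrix(cohort[, fc, drop = FALSE]),
                           use = "pairwise.complete.obs"))
  cormat[is.na(cormat)] <- 0
  mean_abs_r <- function(keep, nm) {
    others <- setdiff(keep, nm)
    if (length(others) == 0L) return(0)
    mean(cormat[nm, others])
  }
  keep <- fc
  # p-value elimination, worst first
  repeat {
    bad <- keep[pval[keep] > p_threshold]
    if (length(bad) == 0L) break
    if (length(keep) == 1L)
      stop("select_features: no feature survives p_threshold = ",
           p_threshold, "; consider relaxing it")
    worst_p <- max(pval[bad])
    cand <- bad[pval[bad] == worst_p]
    if (length(cand) > 1L) {
      r <- vapply(cand, function(nm) mean_abs_r(keep, nm), numeric(1))
      cand <- cand[r == max(r)]
      cand <- sort(cand, decreasing = TRUE)
    }
    keep <- setdiff(keep, cand[1])
    if (length(keep) == 0L)
      stop("select_features: no feature survives p_threshold = ",
           p_threshold, "; consider relaxing it")
  }
  # redundancy pruning among survivors
  repeat {
    if (length(keep) < 2L) break
    sub <- cormat[keep, keep, drop = FALSE]
    diag(sub) <- 0
    if (max(sub) <= corr_threshold) break
    ij <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    pair <- keep[ij]
    # drop the member with the larger p; ties by correlation then name
    drop <- if (pval[pair[1]] > pval[pair[2]]) pair[1]
            else if (pval[pair[2]] > pval[pair[1]]) pair[2]
            else {
              r <- vapply(pair, function(nm) mean_abs_r(keep, nm), numeric(1))
              if (r[1] > r[2]) pair[1]
              else if (r[2] > r[1]) pair[2]
              else sort(pair, decreasing = TRUE)[1]
            }
    keep <- setdiff(keep, drop)
  }
  keep
}
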