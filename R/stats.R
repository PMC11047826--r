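#' Pooled-variance two-sample t-test from raw samples or printed summaries
#'
#' Student's two-sample t-test with pooled variance, callable either on raw
#' samples (`x`, `y`) or directly on published summary statistics
#' (mean / SD / n per group), as needed when only group tables are
#' available.
#'
#' @param x,y Raw samples for the two groups (optional).
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summaries (used when `x`/`y` are
#'   absent). `n1, n2 >= 2`, `sd >= 0`.
#' @return A list with `statistic` (t), `df`, `p.value` (two-sided),
#'   `estimate` (mean difference).
#' @export
two_sample_ttest <- function(x = NULL, y = NULL,
                             mean1 = NULL, sd1 = NULL, n1 = NULL,
                             mean2 = NULL, sd2 = NULL, n2 = NULL) {
  if (!is.null(x) && !is.null(y)) {
    mean1 <- mean(x); sd1 <- stats::sd(x); n1 <- length(x)
    mean2 <- mean(y); sd2 <- stats::sd(y); n2 <- length(y)
  }
  if (is.null(mean1) || is.null(sd1) || is.null(n1) ||
      is.null(mean2) || is.null(sd2) || is.null(n2))
    stop("two_sample_ttest: supply raw samples x,y or full group summaries")
  if (n1 < 2 || n2 < 2) stop("two_sample_ttest: each group needs n >= 2")
  if (sd1 < 0 || sd2 < 0) stop("two_sample_ttest: negative sd")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (sp2 == 0) {
    if (mean1 == mean2)
      return(list(statistic = 0, df = df, p.value = 1,
                  estimate = 0))
    stop("two_sample_ttest: zero pooled variance with unequal means")
  }
  tval <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(statistic = tval, df = df,
       p.value = 2 * stats::pt(-abs(tval), df),
       estimate = mean1 - mean2)
}

#' Pearson chi-square test of an R x C contingency table
#'
#' @param counts Matrix (or table) of nonnegative integer counts with at
#'   least 2 rows and 2 columns. A row or column summing to zero is an
#'   error naming it.
#' @return List with `statistic`, `df`, `p.value` and `expected` counts.
#' @export
chi_square_test <- function(counts) {
  m <- as.matrix(counts)
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("chi_square_test: table must be at least 2 x 2")
  if (any(m < 0) || any(m != round(m)))
    stop("chi_square_test: counts must be nonnegative integers")
  rs <- rowSums(m); cs <- colSums(m)
  if (any(rs == 0))
    stop("chi_square_test: zero-margin row: ",
         paste(which(rs == 0), collapse = ", "))
  if (any(cs == 0))
    stop("chi_square_test: zero-margin column: ",
         paste(which(cs == 0), collapse = ", "))
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p.value = res$p.value, expected = res$expected)
}

#' Mann-Whitney U test (nonparametric two-sample fallback)
#'
#' Wrapper around the Wilcoxon rank-sum test with the normal approximation
#' and tie correction, so heavily tied (e.g. 0/1-valued) data degrade
#' gracefully rather than erroring on exact-p computation.
#'
#' @param x,y Raw samples for the two groups.
#' @return List with `statistic` (U), `p.value` (two-sided).
#' @export
mann_whitney_test <- function(x, y) {
  res <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
  list(statistic = unname(res$statistic), p.value = res$p.value)
}

#' Masked Pearson correlation matrix of EDx parameters vs movement features
#'
#' Correlates each electrodiagnostic (EDx) parameter column with the
#' binary neuropathy label (point-biserial, reported in a `DMN` column)
#' and with each movement feature, using pairwise-complete observations.
#' Cells with `|r|` below `mask_threshold` are masked — printed and
#' exported as empty fields — mirroring the convention of reporting only
#' correlations of at least 0.1 in magnitude.
#'
#' @param cohort A [cohort_dataset()] whose EDx parameters are columns
#'   prefixed `edx.` (as produced by [simulate_feature_cohort()] or
#'   [read_edx_csv()] + merge).
#' @param feature_cols Feature columns to include; default all.
#' @param edx_cols EDx columns (with or without the `edx.` prefix);
#'   default all `edx.*` columns.
#' @param mask_threshold Masking threshold on `|r|` (default 0.100).
#' @return An object of class `correlation_matrix`: list with `r` (rows =
#'   EDx parameters, columns = `DMN` + features), `masked` logical matrix,
#'   `mask_threshold`, `n_pairs`.
#' @export
correlation_matrix <- function(cohort, feature_cols = NULL, edx_cols = NULL,
                               mask_threshold = 0.100) {
  cohort <- cohort_dataset(cohort)
  if (is.null(feature_cols)) feature_cols <- feature_columns(cohort)
  if (is.null(edx_cols)) {
    edx_cols <- grep("^edx\\.", names(cohort), value = TRUE)
  } else {
    edx_cols <- ifelse(startsWith(edx_cols, "edx."), edx_cols,
                       paste0("edx.", edx_cols))
  }
  if (length(edx_cols) == 0L)
    stop("correlation_matrix: no EDx columns found")
  dmn <- as.numeric(cohort$label == "DN")
  cols <- cbind(DMN = dmn, as.matrix(cohort[, feature_cols, drop = FALSE]))
  r <- matrix(NA_real_, nrow = length(edx_cols), ncol = ncol(cols),
              dimnames = list(sub("^edx\\.", "", edx_cols), colnames(cols)))
  npairs <- r
  for (i in seq_along(edx_cols)) {
    e <- cohort[[edx_cols[i]]]
    for (j in seq_len(ncol(cols))) {
      ok <- is.finite(e) & is.finite(cols[, j])
      npairs[i, j] <- sum(ok)
      if (sum(ok) < 3L) next
      if (stats::sd(e[ok]) == 0 || stats::sd(cols[ok, j]) == 0) {
        warning(sprintf(
          "correlation_matrix: constant column in pair (%s, %s); masked",
          edx_cols[i], colnames(cols)[j]))
        next
      }
      r[i, j] <- stats::cor(e[ok], cols[ok, j])
    }
  }
  masked <- is.na(r) | abs(r) < mask_threshold
  structure(list(r = r, masked = masked, mask_threshold = mask_threshold,
                 n_pairs = npairs),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 3, ...) {
  disp <- ifelse(x$masked, "", formatC(x$r, digits = digits, format = "f"))
  dimnames(disp) <- dimnames(x$r)
  print(as.data.frame(disp), right = TRUE)
  invisible(x)
}
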