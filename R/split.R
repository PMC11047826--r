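#' Stratified train/test split of a cohort
#'
#' Partitions the rows into disjoint, exhaustive train and test sets,
#' stratified by class label and (when both provenances are present) by
#' provenance, so original pilot subjects appear in the test side in
#' proportion to their share. Per-stratum counts are allocated by the
#' largest-remainder method, so the train size equals
#' `round(train_fraction * nrow)` exactly.
#'
#' @param cohort A [cohort_dataset()] with at least 2 subjects per class.
#' @param train_fraction Fraction of rows assigned to training, in (0, 1)
#'   (default 0.7).
#' @param seed Optional integer RNG seed for the within-stratum shuffle.
#' @return A list with elements `train` and `test`, both
#'   [cohort_dataset()]s.
#' @export
split_dataset <- function(cohort, train_fraction = 0.7, seed = NULL) {
  cohort <- cohort_dataset(cohort)
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    stop("split_dataset: train_fraction must be strictly between 0 and 1")
  for (cl in c("no_DN", "DN"))
    if (sum(cohort$label == cl) < 2L)
      stop(sprintf("split_dataset: class '%s' has fewer than 2 subjects", cl))
  strat <- cohort$label
  if (length(unique(cohort$provenance)) > 1L)
    strat <- paste(cohort$label, cohort$provenance)
  n <- nrow(cohort)
  n_train <- round(train_fraction * n)
  strata <- split(seq_len(n), strat)
  exact <- vapply(strata, length, integer(1)) * train_fraction
  base <- floor(exact)
  rem <- n_train - sum(base)
  if (rem > 0) {
    frac <- exact - base
    ord <- order(-frac, names(strata))   # largest remainder, name tie-break
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  } else if (rem < 0) {
    frac <- exact - base
    ord <- order(frac, names(strata))
    take <- ord[seq_len(-rem)]
    base[take] <- base[take] - 1
  }
  if (!is.null(seed)) set.seed(seed)
  train_idx <- unlist(lapply(names(strata), function(s) {
    idx <- sample(strata[[s]])
    idx[seq_len(base[[s]])]
  }), use.names = FALSE)
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(n), train_idx)
  if (length(test_idx) == 0L)
    stop("split_dataset: empty test set")
  list(train = cohort_dataset(cohort[train_idx, , drop = FALSE]),
       test = cohort_dataset(cohort[test_idx, , drop = FALSE]))
}
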