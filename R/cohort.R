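# Columns of a cohort data.frame that are not features
COHORT_META_COLS <- c("subject_id", "label", "provenance", "age", "sex")

#' Labelled feature cohort
#'
#' A cohort is a plain data.frame, one row per subject (original or
#' synthetic), with metadata columns `subject_id`, `label`
#' (`"no_DN"`/`"DN"`), `provenance` (`"original"`/`"synthetic"`) and
#' optional `age` (years) and `sex` (`"m"`/`"f"`); every remaining numeric
#' column is a feature, conventionally named `<exercise>.<feature>`.
#'
#' @param df A data.frame with at least `subject_id`, `label` and one
#'   feature column. A missing `provenance` column is filled with
#'   `"original"`.
#' @return The validated data.frame with class `cohort_dataset` prepended.
#' @export
cohort_dataset <- function(df) {
  stopifnot(is.data.frame(df))
  if (!"subject_id" %in% names(df)) stop("cohort_dataset: subject_id missing")
  if (!"label" %in% names(df)) stop("cohort_dataset: label missing")
  if (!all(df$label %in% c("no_DN", "DN")))
    stop("cohort_dataset: label must be 'no_DN' or 'DN'")
  if (!"provenance" %in% names(df)) df$provenance <- "original"
  if (!all(df$provenance %in% c("original", "synthetic")))
    stop("cohort_dataset: provenance must be 'original' or 'synthetic'")
  fc <- setdiff(names(df), COHORT_META_COLS)
  fc <- fc[!startsWith(fc, "edx.")]
  if (length(fc) == 0L) stop("cohort_dataset: no feature columns")
  for (nm in fc)
    if (!is.numeric(df[[nm]]))
      stop(sprintf("cohort_dataset: feature column '%s' is not numeric", nm))
  class(df) <- unique(c("cohort_dataset", class(df)))
  df
}

#' Names of the feature columns of a cohort
#'
#' @param cohort A [cohort_dataset()].
#' @param exercise Optional exercise name; restricts to columns prefixed
#'   `<exercise>.`.
#' @param include_edx Include `edx.*` columns (default `FALSE`).
#' @return Character vector of column names.
#' @export
feature_columns <- function(cohort, exercise = NULL, include_edx = FALSE) {
  fc <- setdiff(names(cohort), COHORT_META_COLS)
  if (!include_edx) fc <- fc[!startsWith(fc, "edx.")]
  if (!is.null(exercise)) {
    fc <- fc[startsWith(fc, paste0(exercise, "."))]
    if (length(fc) == 0L)
      stop(sprintf("feature_columns: no features for exercise '%s'", exercise))
  }
  fc
}

#' Exercises present in a cohort's feature columns
#' @param cohort A [cohort_dataset()].
#' @return Character vector of exercise names, in registry order.
#' @export
cohort_exercises <- function(cohort) {
  fc <- feature_columns(cohort)
  ex <- unique(sub("\\..*$", "", fc))
  intersect(exercise_registry()$exercise, ex)
}
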