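#' Specification for a synthetic feature-level cohort
#'
#' Bundles everything [simulate_feature_cohort()] needs: per-group sample
#' sizes, per-feature Gaussian templates, EDx parameter templates with
#' within-group target correlations, demographic templates and the seed.
#'
#' @param n_per_group Named counts, e.g. `c(no_DN = 15, DN = 8)` (the pilot
#'   cohort's sizes are the default). Each must be at least 2.
#' @param features Feature template data.frame as from
#'   [feature_templates()].
#' @param edx EDx templates as from [edx_templates()]; `NULL` omits EDx
#'   columns.
#' @param demographics As from [demographic_templates()]; `NULL` omits
#'   age/sex.
#' @param subject_latent_sd Optional shared within-subject latent factor
#'   loading in `[0, 1)` inducing correlation between a subject's features
#'   across exercises; 0 (default) keeps features independent.
#' @param seed Integer RNG seed.
#' @return A list of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(n_per_group = c(no_DN = 15, DN = 8),
                            features = feature_templates(),
                            edx = edx_templates(),
                            demographics = demographic_templates(),
                            subject_latent_sd = 0,
                            seed = NULL) {
  stopifnot(all(c("no_DN", "DN") %in% names(n_per_group)),
            all(n_per_group >= 2))
  stopifnot(is.data.frame(features),
            all(c("exercise", "feature", "mean_noDN", "sd_noDN",
                  "mean_DN", "sd_DN") %in% names(features)))
  if (any(features$sd_noDN <= 0) || any(features$sd_DN <= 0))
    stop("cohort_sim_spec: feature template SDs must be positive")
  if (subject_latent_sd < 0 || subject_latent_sd >= 1)
    stop("cohort_sim_spec: subject_latent_sd must be in [0, 1)")
  if (!is.null(edx)) {
    cols <- paste(features$exercise, features$feature, sep = ".")
    for (e in edx) {
      rho <- e$target_corr
      if (any(abs(rho) >= 1))
        stop(sprintf("cohort_sim_spec: |target correlation| >= 1 for '%s'",
                     e$name))
      unknown <- setdiff(names(rho), cols)
      if (length(unknown) > 0)
        stop(sprintf("cohort_sim_spec: EDx '%s' targets unknown feature(s) %s",
                     e$name, paste(unknown, collapse = ", ")))
      if (sum(rho^2) >= 1)
        stop(sprintf(paste0(
          "cohort_sim_spec: EDx '%s' target correlations give a ",
          "non-positive-definite latent covariance (sum of squares %.3f >= 1)"),
          e$name, sum(rho^2)))
    }
  }
  structure(list(n_per_group = n_per_group, features = features, edx = edx,
                 demographics = demographics,
                 subject_latent_sd = subject_latent_sd, seed = seed),
            class = "cohort_sim_spec")
}

# one group's feature draws on the standardized (z) scale
draw_group_z <- function(n, n_feat, latent_sd) {
  z <- matrix(stats::rnorm(n * n_feat), nrow = n)
  if (latent_sd > 0) {
    shared <- stats::rnorm(n)
    z <- sqrt(1 - latent_sd^2) * z + latent_sd * shared
  }
  z
}

#' Simulate a feature-level cohort with correlated EDx parameters
#'
#' Draws per-group Gaussian feature values from the template means/SDs.
#' EDx parameters are generated from the same standardized latent draws:
#' for a parameter with target within-group correlations `rho_j` to
#' features `j`, its standardized value is
#' `sum_j rho_j * z_j + sqrt(1 - sum_j rho_j^2) * eps`, which achieves the
#' targets exactly in expectation when features are independent. Feature
#' templates may carry a finite `lower` bound enforced by rejection
#' resampling (off by default, since truncation shifts the group means).
#'
#' @param spec A [cohort_sim_spec()].
#' @return A [cohort_dataset()] with `sum(n_per_group)` original rows:
#'   demographics, `<exercise>.<feature>` columns and `edx.<param>`
#'   columns.
#' @export
simulate_feature_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  ft <- spec$features
  fcols <- paste(ft$exercise, ft$feature, sep = ".")
  groups <- c("no_DN", "DN")
  rows <- list()
  for (g in groups) {
    n <- spec$n_per_group[[g]]
    mu <- if (g == "no_DN") ft$mean_noDN else ft$mean_DN
    sdv <- if (g == "no_DN") ft$sd_noDN else ft$sd_DN
    z <- draw_group_z(n, nrow(ft), spec$subject_latent_sd)
    # rejection against lower bounds, if any are finite
    lower <- if ("lower" %in% names(ft)) ft$lower else rep(-Inf, nrow(ft))
    for (j in seq_len(nrow(ft))) {
      if (is.finite(lower[j])) {
        bad <- which(mu[j] + sdv[j] * z[, j] < lower[j])
        guard <- 0L
        while (length(bad) > 0 && guard < 1000L) {
          z[bad, j] <- stats::rnorm(length(bad))
          bad <- bad[mu[j] + sdv[j] * z[bad, j] < lower[j]]
          guard <- guard + 1L
        }
      }
    }
    x <- sweep(sweep(z, 2, sdv, "*"), 2, mu, "+")
    colnames(x) <- fcols
    df <- as.data.frame(x)
    df$label <- g
    # EDx parameters from the same latent draws
    if (!is.null(spec$edx)) {
      for (e in spec$edx) {
        rho <- e$target_corr
        jidx <- match(names(rho), fcols)
        resid <- sqrt(1 - sum(rho^2))
        estd <- as.numeric(z[, jidx, drop = FALSE] %*% rho) +
          resid * stats::rnorm(n)
        df[[paste0("edx.", e$name)]] <- e$mean[[g]] + e$sd[[g]] * estd
      }
    }
    if (!is.null(spec$demographics)) {
      dg <- spec$demographics
      df$age <- stats::rnorm(n, dg$age_mean[[g]], dg$age_sd[[g]])
      df$sex <- ifelse(stats::runif(n) < dg$male_fraction[[g]], "m", "f")
    }
    rows[[g]] <- df
  }
  out <- rbind(rows[["no_DN"]], rows[["DN"]])
  out$subject_id <- sprintf("s%03d", seq_len(nrow(out)))
  out$provenance <- "original"
  meta <- intersect(c("subject_id", "label", "provenance", "age", "sex"),
                    names(out))
  out <- out[, c(meta, setdiff(names(out), meta))]
  rownames(out) <- NULL
  cohort_dataset(out)
}
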