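#' Feature templates of the pilot cohort
#'
#' Group summary statistics (mean and SD per feature, for subjects without
#' and with confirmed diabetic neuropathy) of the 24 anonymized movement
#' features reported for the 23-subject pilot cohort this package's
#' generator emulates. Features are numbered because their proprietary
#' definitions are not disclosed; the exercise each belongs to is known.
#' These rows parameterize [simulate_feature_cohort()].
#'
#' @param important_only Keep only the 12 features flagged as most
#'   discriminative (those carried into the correlation analysis against
#'   nerve-conduction parameters).
#' @return A data.frame with columns `exercise`, `feature`, `mean_noDN`,
#'   `sd_noDN`, `mean_DN`, `sd_DN`, `important`, `lower` (physical lower
#'   bound; `-Inf` disables truncation).
#' @export
feature_templates <- function(important_only = FALSE) {
  tab <- rbind(
    c("heel_toe_walk",  "feature_01", 0.011, 0.005, 0.005, 0.003),
    c("heel_toe_walk",  "feature_02", 1.481, 0.369, 1.402, 0.334),
    c("heel_toe_walk",  "feature_03", 1.459, 0.300, 1.418, 0.363),
    c("heel_toe_walk",  "feature_04", 0.107, 0.048, 0.056, 0.031),
    c("tandem_walk",    "feature_05", 1.481, 0.206, 1.327, 0.135),
    c("tandem_walk",    "feature_06", 1.307, 0.094, 1.230, 0.138),
    c("heel_knee",      "feature_07", 0.036, 0.029, 0.012, 0.009),
    c("heel_knee",      "feature_08", 0.068, 0.104, 0.021, 0.014),
    c("heel_knee",      "feature_09", 0.052, 0.072, 0.034, 0.059),
    c("heel_knee",      "feature_10", 0.695, 0.304, 0.442, 0.173),
    c("romberg",        "feature_11", 0.164, 0.131, 0.339, 0.265),
    c("romberg",        "feature_12", 0.109, 0.156, 0.298, 0.282),
    c("romberg",        "feature_13", 0.628, 0.140, 0.542, 0.169),
    c("romberg",        "feature_14", 0.604, 0.173, 0.505, 0.190),
    c("postural_tremor", "feature_15", 0.017, 0.011, 0.011, 0.012),
    c("postural_tremor", "feature_16", 0.020, 0.013, 0.013, 0.008),
    c("postural_tremor", "feature_17", 1.044, 0.487, 0.707, 0.244),
    c("postural_tremor", "feature_18", 1.281, 0.788, 0.839, 0.370),
    c("postural_tremor", "feature_19", 0.638, 0.154, 0.569, 0.159),
    c("postural_tremor", "feature_20", 0.597, 0.172, 0.564, 0.164),
    c("finger_nose",    "feature_21", 1.006, 0.025, 0.960, 0.062),
    c("finger_nose",    "feature_22", 0.003, 0.012, -0.021, 0.033),
    c("finger_nose",    "feature_23", 0.598, 0.195, 0.548, 0.156),
    c("finger_nose",    "feature_24", 0.606, 0.202, 0.616, 0.218))
  df <- data.frame(exercise = tab[, 1], feature = tab[, 2],
                   mean_noDN = as.numeric(tab[, 3]),
                   sd_noDN = as.numeric(tab[, 4]),
                   mean_DN = as.numeric(tab[, 5]),
                   sd_DN = as.numeric(tab[, 6]),
                   stringsAsFactors = FALSE)
  important <- c("feature_01", "feature_04", "feature_05", "feature_06",
                 "feature_07", "feature_10", "feature_11", "feature_12",
                 "feature_16", "feature_17", "feature_21", "feature_22")
  df$important <- df$feature %in% important
  df$lower <- -Inf
  if (important_only) df <- df[df$important, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Synthetic nerve-conduction (EDx) parameter templates
#'
#' Templates for generating electrodiagnostic parameters jointly with the
#' movement features. Target correlations follow the sign and magnitude
#' pattern reported between movement features and nerve-conduction
#' parameters (latency rises, amplitude and conduction velocity fall with
#' neuropathy); they are defined *within group* (label-conditional) and
#' realized by a shared latent Gaussian per subject. Group means and SDs
#' of the EDx parameters themselves were never published: the values here
#' are physiologically plausible synthetic stand-ins, not measurements.
#'
#' @return A list, one element per EDx parameter, each a list with `name`,
#'   `nerve`, `side`, `fiber`, `site`, `measure`, `units`, per-group
#'   `mean` and `sd` (named `no_DN` / `DN`), and `target_corr` — a named
#'   numeric vector of within-group correlations with feature columns.
#' @export
edx_templates <- function() {
  list(
    cv_lm_pr = list(
      name = "cv_lm_pr", nerve = "medianus", side = "left", fiber = "motor",
      site = "pr", measure = "cv", units = "m/s",
      mean = c(no_DN = 52, DN = 43), sd = c(no_DN = 4, DN = 5),
      target_corr = c("heel_toe_walk.feature_01" = 0.650,
                      "heel_toe_walk.feature_04" = 0.596)),
    lat_lm_rp = list(
      name = "lat_lm_rp", nerve = "medianus", side = "left",
      fiber = "sensory", site = "rp", measure = "latency", units = "ms",
      mean = c(no_DN = 3.0, DN = 3.9), sd = c(no_DN = 0.35, DN = 0.6),
      target_corr = c("heel_knee.feature_07" = 0.722,
                      "postural_tremor.feature_16" = -0.583)),
    cv_lp_ps = list(
      name = "cv_lp_ps", nerve = "peroneus", side = "left", fiber = "motor",
      site = "ps", measure = "cv", units = "m/s",
      mean = c(no_DN = 48, DN = 40), sd = c(no_DN = 4, DN = 5),
      target_corr = c("heel_knee.feature_07" = -0.657)),
    amp_rp_se = list(
      name = "amp_rp_se", nerve = "peroneus", side = "right",
      fiber = "motor", site = "se", measure = "amplitude", units = "mV",
      mean = c(no_DN = 6.5, DN = 3.5), sd = c(no_DN = 2.0, DN = 1.5),
      target_corr = c("heel_toe_walk.feature_01" = 0.515,
                      "heel_knee.feature_07" = -0.692)),
    amp_rs_ps = list(
      name = "amp_rs_ps", nerve = "suralis", side = "right",
      fiber = "sensory", site = "ps", measure = "amplitude", units = "uV",
      mean = c(no_DN = 14, DN = 6), sd = c(no_DN = 6, DN = 3),
      target_corr = c("tandem_walk.feature_05" = 0.515,
                      "finger_nose.feature_22" = 0.528)))
}

#' User-experience questionnaire counts of the pilot cohort
#'
#' Published per-question answer counts for the 23 participants who
#' underwent both the electrodiagnostic (EDx/EMNG) and the wearable
#' movement examination, plus the final preference question (21 of 23,
#' 91.3%, chose the wearable exam). These serve as inputs for the
#' contingency-table analyses.
#'
#' @return A list with `questions` — named list of count matrices (rows =
#'   answer grades, columns = EDx exam, wearable exam) — and `preference`
#'   (named counts for the final choice question).
#' @export
questionnaire_counts <- function() {
  q <- function(grades, emng, wearable) {
    m <- cbind(EDx = emng, wearable = wearable)
    rownames(m) <- grades
    m
  }
  list(
    questions = list(
      unpleasant = q(c("no", "mild", "moderate", "severe"),
                     c(1, 7, 11, 4), c(21, 1, 1, 0)),
      pain = q(c("no", "mild", "moderate", "severe"),
               c(0, 8, 11, 4), c(22, 1, 0, 0)),
      fear = q(c("no", "mild", "moderate", "severe"),
               c(10, 5, 5, 3), c(22, 1, 0, 0)),
      duration = q(c("as_it_should_be", "little_longer", "much_longer"),
                   c(5, 12, 6), c(22, 1, 0))),
    preference = c(wearable = 21, either = 2))
}

#' Demographic templates of the pilot cohort
#'
#' Age (years, mean and SD) and male fraction per group in the 23-subject
#' pilot cohort: 15 without neuropathy (50.7 +/- 12.0 years, 5 males) and
#' 8 with neuropathy (63.8 +/- 8.5 years, 3 males).
#'
#' @return A list with `age_mean`, `age_sd`, `male_fraction`, each a named
#'   vector over `no_DN` / `DN`.
#' @export
demographic_templates <- function() {
  list(age_mean = c(no_DN = 50.7, DN = 63.8),
       age_sd = c(no_DN = 12.0, DN = 8.5),
       male_fraction = c(no_DN = 5 / 15, DN = 3 / 8))
}
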