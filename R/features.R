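#' The six standardized movement exercises
#'
#' Registry of the instrumented neurological maneuvers: which limb pair
#' carries the sensors and which eye conditions the exercise is performed
#' under. The tandem walk is performed eyes-open only (fall risk); the
#' heel-toe walk and postural tremor have no eye manipulation.
#'
#' @return A data.frame with columns `exercise`, `limb` (`arms`/`legs`) and
#'   `eye_conditions` (comma-separated).
#' @export
exercise_registry <- function() {
  data.frame(
    exercise = c("heel_toe_walk", "tandem_walk", "heel_knee",
                 "romberg", "postural_tremor", "finger_nose"),
    limb = c("legs", "legs", "legs", "arms", "arms", "arms"),
    eye_conditions = c("not_applicable", "open", "open,closed",
                       "open,closed", "not_applicable", "open,closed"),
    stringsAsFactors = FALSE)
}

exercise_placements <- function(exercise) {
  reg <- exercise_registry()
  limb <- reg$limb[match(exercise, reg$exercise)]
  if (is.na(limb)) stop(sprintf("unknown exercise '%s'", exercise))
  if (limb == "arms") c("left_hand", "right_hand") else c("left_foot", "right_foot")
}

#' One exercise attempt recorded by a set of wearable sensors
#'
#' @param exercise One of the six exercises in [exercise_registry()].
#' @param sensors Named list of [imu_series()], names from
#'   `left_hand`, `right_hand`, `left_foot`, `right_foot`. Arm exercises
#'   require the hand sensors, leg exercises the foot sensors.
#' @param eye_condition `"open"`, `"closed"` or `"not_applicable"`.
#' @param subject_id Optional subject identifier.
#' @return An object of class `exercise_recording`.
#' @export
exercise_recording <- function(exercise, sensors,
                               eye_condition = c("not_applicable", "open",
                                                 "closed"),
                               subject_id = NA_character_) {
  eye_condition <- match.arg(eye_condition)
  reg <- exercise_registry()
  if (!exercise %in% reg$exercise)
    stop(sprintf("unknown exercise '%s'", exercise))
  if (length(sensors) == 0L) stop("exercise_recording: no sensors present")
  ok_places <- c("left_hand", "right_hand", "left_foot", "right_foot")
  if (!all(names(sensors) %in% ok_places))
    stop("exercise_recording: sensor names must be placements: ",
         paste(ok_places, collapse = ", "))
  for (s in sensors) stopifnot(inherits(s, "imu_series"))
  need <- exercise_placements(exercise)
  if (!any(need %in% names(sensors)))
    stop(sprintf("exercise_recording: exercise '%s' requires %s sensors",
                 exercise, paste(need, collapse = "/")))
  dur <- length(sensors[[1]]$t) / sensors[[1]]$sample_rate
  if (dur < 5 || dur > 60)
    stop(sprintf(
      "exercise_recording: duration %.1f s outside the 5-60 s envelope", dur))
  structure(list(exercise = exercise, eye_condition = eye_condition,
                 sensors = sensors, duration = dur,
                 subject_id = subject_id),
            class = "exercise_recording")
}

#' @export
print.exercise_recording <- function(x, ...) {
  cat(sprintf("<exercise_recording> %s (%s), %.1f s, sensors: %s\n",
              x$exercise, x$eye_condition, x$duration,
              paste(names(x$sensors), collapse = ", ")))
  invisible(x)
}

#' Eyes-open vs eyes-closed contrast of a movement feature
#'
#' Postural control with eyes closed deteriorates when deep sensibility is
#' impaired, so the ratio (or difference) of a movement summary between the
#' two eye conditions is a sensitive marker.
#'
#' @param value_open,value_closed Finite scalar feature values from the two
#'   conditions.
#' @param mode `"ratio"` (open / closed, default) or `"difference"`
#'   (open - closed).
#' @param eps Guard for a near-zero denominator in ratio mode: a
#'   denominator with absolute value below `eps` is replaced by `eps`
#'   (keeping its sign where nonzero). Set `eps = 0` to make a zero
#'   denominator an error.
#' @return Scalar contrast value.
#' @export
contrast_feature <- function(value_open, value_closed,
                             mode = c("ratio", "difference"), eps = 1e-12) {
  mode <- match.arg(mode)
  if (!is.finite(value_open) || !is.finite(value_closed))
    stop("contrast_feature: values must be finite")
  if (mode == "difference") return(value_open - value_closed)
  d <- value_closed
  if (abs(d) < eps) {
    if (eps <= 0) stop("contrast_feature: zero denominator in ratio mode")
    d <- if (d < 0) -eps else eps
  }
  if (d == 0) stop("contrast_feature: zero denominator in ratio mode")
  value_open / d
}

#' Feature-extraction configuration
#'
#' @param band_cutoffs_hz Cut-off frequencies for the cumulative band-power
#'   features (default 5, 10, 15 Hz).
#' @param contrast_mode `"ratio"` or `"difference"` for eyes open/closed
#'   contrasts.
#' @param aggregate `"side_mean"` (average the left/right sensors of the
#'   limb pair, default) or `"per_sensor"` (one feature per placement).
#' @param source `"accel"` or `"gyro"` triplet for the norm.
#' @param window_length,overlap_fraction Welch settings.
#' @param cutoff_hz,filter_order Gravity-removal high-pass settings.
#' @param max_gap_samples Longest interior gap filled by interpolation.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(band_cutoffs_hz = c(5, 10, 15),
                           contrast_mode = c("ratio", "difference"),
                           aggregate = c("side_mean", "per_sensor"),
                           source = c("accel", "gyro"),
                           window_length = 256L, overlap_fraction = 0.5,
                           cutoff_hz = 0.1, filter_order = 4L,
                           max_gap_samples = 25L) {
  stopifnot(is.numeric(band_cutoffs_hz), all(band_cutoffs_hz >= 0))
  structure(list(band_cutoffs_hz = sort(band_cutoffs_hz),
                 contrast_mode = match.arg(contrast_mode),
                 aggregate = match.arg(aggregate),
                 source = match.arg(source),
                 window_length = as.integer(window_length),
                 overlap_fraction = overlap_fraction,
                 cutoff_hz = cutoff_hz,
                 filter_order = as.integer(filter_order),
                 max_gap_samples = as.integer(max_gap_samples)),
            class = "feature_config")
}

# norm -> fill gaps -> remove gravity -> Welch PSD for one sensor
sensor_psd <- function(series, config) {
  s <- compute_norm(series, source = config$source)
  s <- fill_gaps(s, max_gap_samples = config$max_gap_samples)
  s <- remove_gravity(s, cutoff_hz = config$cutoff_hz,
                      order = config$filter_order)
  welch_psd(s, window_length = config$window_length,
            overlap_fraction = config$overlap_fraction)
}

band_label <- function(fx) sprintf("psd_%ghz", fx)

# Band features for one recording, named psd_<fx>hz[.<placement>]
recording_band_features <- function(recording, config) {
  need <- exercise_placements(recording$exercise)
  have <- intersect(need, names(recording$sensors))
  if (config$aggregate == "side_mean") {
    missing <- setdiff(need, names(recording$sensors))
    if (length(missing) > 0 && length(have) == 0)
      stop(sprintf("extract_features: missing required sensor(s): %s",
                   paste(missing, collapse = ", ")))
  } else if (length(have) == 0) {
    stop(sprintf("extract_features: missing required sensor(s): %s",
                 paste(need, collapse = ", ")))
  }
  per_sensor <- lapply(recording$sensors[have], function(s) {
    psd <- sensor_psd(s, config)
    vapply(config$band_cutoffs_hz, function(fx) band_power_above(psd, fx),
           numeric(1))
  })
  labels <- vapply(config$band_cutoffs_hz, band_label, character(1))
  if (config$aggregate == "side_mean") {
    m <- do.call(rbind, per_sensor)
    out <- colMeans(m)
    names(out) <- labels
  } else {
    out <- unlist(lapply(names(per_sensor), function(pl) {
      v <- per_sensor[[pl]]
      names(v) <- paste(labels, pl, sep = ".")
      v
    }))
  }
  out
}

#' Extract the spectral feature vector for one exercise
#'
#' Runs the full chain norm -> gap filling -> gravity removal -> Welch PSD
#' -> cumulative band sums for every required sensor, and, when recordings
#' for both eye conditions are supplied, adds open/closed contrast features
#' for each band.
#'
#' @param recordings A single [exercise_recording()] or a list of
#'   recordings of the *same* exercise (e.g. one eyes-open and one
#'   eyes-closed attempt).
#' @param config A [feature_config()].
#' @return An object of class `feature_vector`: list with `subject_id`,
#'   `exercise` and a named numeric `features`. Condition-specific features
#'   are suffixed `.open` / `.closed`; contrasts `.contrast`.
#' @export
extract_features <- function(recordings, config = feature_config()) {
  stopifnot(inherits(config, "feature_config"))
  if (inherits(recordings, "exercise_recording")) recordings <- list(recordings)
  stopifnot(length(recordings) >= 1L)
  for (r in recordings) stopifnot(inherits(r, "exercise_recording"))
  ex <- unique(vapply(recordings, function(r) r$exercise, character(1)))
  if (length(ex) != 1L)
    stop("extract_features: all recordings must be of the same exercise")
  conds <- vapply(recordings, function(r) r$eye_condition, character(1))
  if (anyDuplicated(conds))
    stop("extract_features: duplicate eye condition among recordings")
  by_cond <- lapply(recordings, recording_band_features, config = config)
  names(by_cond) <- conds
  if (length(recordings) == 1L) {
    feats <- by_cond[[1]]
  } else if (all(c("open", "closed") %in% conds)) {
    feats <- c()
    for (cond in conds) {
      v <- by_cond[[cond]]
      names(v) <- paste(names(v), cond, sep = ".")
      feats <- c(feats, v)
    }
    op <- by_cond[["open"]]; cl <- by_cond[["closed"]]
    common <- intersect(names(op), names(cl))
    contr <- vapply(common, function(nm)
      contrast_feature(op[[nm]], cl[[nm]], mode = config$contrast_mode),
      numeric(1))
    names(contr) <- paste(common, "contrast", sep = ".")
    feats <- c(feats, contr)
  } else {
    feats <- unlist(lapply(conds, function(cond) {
      v <- by_cond[[cond]]
      names(v) <- paste(names(v), cond, sep = ".")
      v
    }))
  }
  if (anyDuplicated(names(feats)))
    stop("extract_features: duplicate feature names")
  structure(list(subject_id = recordings[[1]]$subject_id,
                 exercise = ex,
                 features = feats),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> subject %s, %s:\n", x$subject_id, x$exercise))
  print(x$features)
  invisible(x)
}
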