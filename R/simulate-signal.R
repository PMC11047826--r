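#' Specification for a synthetic exercise recording
#'
#' Parameterizes the signal-level generator: which exercise, how severe the
#' (simulated) neuropathy is, and the spectral make-up of the movement. The
#' signal model is gravity (1 g on the vertical axis) + low-frequency
#' postural sway + a tremor oscillation in the tremor band + white sensor
#' noise; for the walking exercises a periodic step-impulse train is added.
#' Severity scales tremor power upward (tremor is more expressed with
#' neuropathy) and step-impulse amplitude downward (reduced foot strength).
#'
#' @param exercise One of the six exercises.
#' @param severity Neuropathy severity in `[0, 1]` (0 healthy, 1
#'   pronounced).
#' @param sample_rate Hz (default 100).
#' @param duration Seconds, within the 5-60 s exercise envelope (default
#'   15).
#' @param tremor_band,sway_band Frequency intervals in Hz (defaults 4-12
#'   and 0.3-2); must lie inside (0, Nyquist).
#' @param tremor_amp Baseline tremor amplitude in g (default 0.02);
#'   severity multiplies it by `0.2 + 1.8 * severity`.
#' @param sway_amp Sway amplitude in g (default 0.05), amplified by
#'   severity and by the eyes-closed condition.
#' @param noise_sd White-noise SD in g (default 0.01).
#' @param gap_rate Per-sample probability of a streaming loss (default 0).
#' @param seed Integer RNG seed.
#' @return A list of class `signal_sim_spec`.
#' @export
signal_sim_spec <- function(exercise, severity = 0, sample_rate = 100,
                            duration = 15, tremor_band = c(4, 12),
                            sway_band = c(0.3, 2), tremor_amp = 0.02,
                            sway_amp = 0.05, noise_sd = 0.01,
                            gap_rate = 0, seed = NULL) {
  reg <- exercise_registry()
  if (!exercise %in% reg$exercise)
    stop(sprintf("signal_sim_spec: unknown exercise '%s'", exercise))
  stopifnot(severity >= 0, severity <= 1,
            sample_rate > 0, duration >= 5, duration <= 60,
            gap_rate >= 0, gap_rate < 1,
            tremor_amp >= 0, sway_amp >= 0, noise_sd >= 0)
  nyq <- sample_rate / 2
  for (b in list(tremor_band, sway_band))
    if (length(b) != 2 || b[1] <= 0 || b[2] >= nyq || b[1] >= b[2])
      stop("signal_sim_spec: bands must be ordered intervals inside (0, Nyquist)")
  structure(list(exercise = exercise, severity = severity,
                 sample_rate = sample_rate, duration = duration,
                 tremor_band = tremor_band, sway_band = sway_band,
                 tremor_amp = tremor_amp, sway_amp = sway_amp,
                 noise_sd = noise_sd, gap_rate = gap_rate, seed = seed),
            class = "signal_sim_spec")
}

# Gaussian-shaped periodic step impulses (walk exercises)
step_train <- function(t, step_hz, amp, width = 0.05) {
  phase <- (t * step_hz) %% 1
  d <- pmin(phase, 1 - phase) / step_hz     # seconds to nearest step event
  amp * exp(-0.5 * (d / width)^2)
}

simulate_sensor <- function(spec, eyes_closed = FALSE) {
  fs <- spec$sample_rate
  t <- seq(0, spec$duration - 1 / fs, by = 1 / fs)
  n <- length(t)
  sev <- spec$severity
  closed_gain <- if (eyes_closed) 1 + 0.8 * sev else 1
  tremor_a <- spec$tremor_amp * (0.2 + 1.8 * sev) * closed_gain
  sway_a <- spec$sway_amp * (1 + 0.6 * sev) * closed_gain
  f_tremor <- stats::runif(1, spec$tremor_band[1], spec$tremor_band[2])
  f_sway <- stats::runif(1, spec$sway_band[1], spec$sway_band[2])
  ph <- stats::runif(4, 0, 2 * pi)
  sway_x <- sway_a * sin(2 * pi * f_sway * t + ph[1])
  sway_y <- 0.7 * sway_a * sin(2 * pi * f_sway * t + ph[2])
  trem_x <- tremor_a * sin(2 * pi * f_tremor * t + ph[3])
  trem_y <- 0.8 * tremor_a * sin(2 * pi * f_tremor * t + ph[4])
  walk <- spec$exercise %in% c("heel_toe_walk", "tandem_walk")
  steps <- if (walk)
    step_train(t, step_hz = 1.8, amp = 0.3 * (1 - 0.6 * sev))
  else 0
  nz <- function() if (spec$noise_sd > 0) stats::rnorm(n, 0, spec$noise_sd)
                   else numeric(n)
  ax <- sway_x + trem_x + nz()
  ay <- sway_y + trem_y + nz()
  az <- 1 + steps + 0.3 * trem_x + nz()
  gyr_scale <- 150  # deg/s per g of oscillation, a plausible limb lever arm
  gx <- gyr_scale * (sway_x + trem_x) + nz() * 50
  gy <- gyr_scale * (sway_y + trem_y) + nz() * 50
  gz <- nz() * 50
  gap <- if (spec$gap_rate > 0) stats::runif(n) < spec$gap_rate
         else rep(FALSE, n)
  # keep endpoints so trimming does not change duration
  gap[c(1L, n)] <- FALSE
  for (ch in c("ax", "ay", "az", "gx", "gy", "gz")) {
    v <- get(ch)
    v[gap] <- NA_real_
    assign(ch, v)
  }
  imu_series(t = t, ax = ax, ay = ay, az = az, gx = gx, gy = gy, gz = gz,
             sample_rate = fs, gap_mask = gap)
}

#' Simulate one synthetic exercise recording
#'
#' Generates an [exercise_recording()] with the sensor placements the
#' exercise requires, following the signal model documented in
#' [signal_sim_spec()]. Pure function of the spec: a fixed seed reproduces
#' the recording exactly.
#'
#' @param spec A [signal_sim_spec()].
#' @param eye_condition Eye condition of this attempt; default the first
#'   condition the exercise is performed under. Eyes-closed amplifies sway
#'   and tremor in proportion to severity (impaired deep sensibility shows
#'   when vision is removed).
#' @param subject_id Optional subject identifier.
#' @return An [exercise_recording()].
#' @export
simulate_recording <- function(spec, eye_condition = NULL,
                               subject_id = NA_character_) {
  stopifnot(inherits(spec, "signal_sim_spec"))
  reg <- exercise_registry()
  conds <- strsplit(reg$eye_conditions[match(spec$exercise, reg$exercise)],
                    ",")[[1]]
  if (is.null(eye_condition)) eye_condition <- conds[1]
  if (!eye_condition %in% conds)
    stop(sprintf("simulate_recording: exercise '%s' is not performed '%s'",
                 spec$exercise, eye_condition))
  if (!is.null(spec$seed))
    set.seed(spec$seed + match(eye_condition,
                               c("not_applicable", "open", "closed")))
  sensors <- lapply(exercise_placements(spec$exercise), function(pl)
    simulate_sensor(spec, eyes_closed = eye_condition == "closed"))
  names(sensors) <- exercise_placements(spec$exercise)
  exercise_recording(spec$exercise, sensors, eye_condition = eye_condition,
                     subject_id = subject_id)
}

#' Simulate all eye-condition attempts of one exercise
#'
#' @param spec A [signal_sim_spec()].
#' @param subject_id Optional subject identifier.
#' @return A list of [exercise_recording()]s, one per condition the
#'   exercise is performed under — ready for [extract_features()].
#' @export
simulate_exercise_set <- function(spec, subject_id = NA_character_) {
  reg <- exercise_registry()
  conds <- strsplit(reg$eye_conditions[match(spec$exercise, reg$exercise)],
                    ",")[[1]]
  lapply(conds, function(cc)
    simulate_recording(spec, eye_condition = cc, subject_id = subject_id))
}
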