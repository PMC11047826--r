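# shared fixture builders (everything generated in code, no stored data)

sine_signal <- function(freq, fs = 100, dur = 30, amp = 1, phase = 0,
                        units = "g") {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  scalar_signal(amp * sin(2 * pi * freq * t + phase), fs, units = units)
}

constant_imu <- function(ax, ay, az, n = 600, fs = 100) {
  t <- seq(0, by = 1 / fs, length.out = n)
  imu_series(t = t, ax = rep(ax, n), ay = rep(ay, n), az = rep(az, n),
             gx = rep(0, n), gy = rep(0, n), gz = rep(0, n),
             sample_rate = fs)
}

# 23-subject pilot-sized cohort (15 no_DN / 8 DN) from the templates
pilot_cohort <- function(seed = 1, edx = NULL) {
  simulate_feature_cohort(cohort_sim_spec(
    n_per_group = c(no_DN = 15, DN = 8), edx = edx,
    demographics = NULL, seed = seed))
}

# analytic squared magnitude of the designed zero-phase Butterworth high-pass
butter_hp_gain2 <- function(f, cutoff = 0.1, order = 4, fs = 100) {
  h <- signal::freqz(signal::butter(order, cutoff / (fs / 2), type = "high"),
                     Fs = fs, n = 4096)
  # nearest evaluated frequency
  idx <- vapply(f, function(fi) which.min(abs(h$f - fi)), integer(1))
  Mod(h$h[idx])^2
}
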