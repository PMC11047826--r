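test_that("welch_psd handles the zero signal and short input", {
  z <- scalar_signal(rep(0, 1000), 100)
  p <- welch_psd(z)
  expect_true(all(p$power == 0))
  expect_equal(p$freqs[1], 0)
  expect_equal(length(p$freqs), 129)
  expect_error(welch_psd(scalar_signal(rnorm(100), 100)), "longer")
})

test_that("welch_psd localizes a bin-centred sine at its frequency", {
  # 6.25 Hz sits exactly on bin 16 of a 256-window at 100 Hz
  f0 <- 16 * 100 / 256
  s <- sine_signal(f0, dur = 60)
  p <- welch_psd(s)
  expect_equal(p$freqs[which.max(p$power)], f0)
  # direct periodogram oracle on one Hann-windowed segment
  seg <- s$values[1:256]
  w <- 0.5 * (1 - cos(2 * pi * (0:255) / 256))
  sp <- abs(fft((seg - mean(seg)) * w))^2
  expect_equal(which.max(sp[1:129]), which.max(p$power))
})

test_that("welch_psd satisfies Parseval: integrated density matches variance", {
  set.seed(31)
  x <- rnorm(60000)
  p <- welch_psd(scalar_signal(x, 100))
  df <- p$freqs[2] - p$freqs[1]
  expect_equal(sum(p$power) * df, var(x), tolerance = 0.05)
})

test_that("welch_psd is scale-equivariant (power scales as a^2)", {
  set.seed(32)
  x <- rnorm(4000)
  p1 <- welch_psd(scalar_signal(x, 100))
  p3 <- welch_psd(scalar_signal(3 * x, 100))
  expect_equal(p3$power, 9 * p1$power, tolerance = 1e-10)
})

test_that("band_power_above implements the cumulative high-band summation", {
  set.seed(33)
  p <- welch_psd(scalar_signal(rnorm(2000), 100))
  expect_equal(band_power_above(p, 0), sum(p$power))
  expect_warning(res <- band_power_above(p, 51), "Nyquist")
  expect_equal(res, 0)

  # uniform power c over B bins with cut-off index k -> c * (B - k + 1)
  c0 <- 0.37
  fake <- structure(list(freqs = (0:128) * 100 / 256,
                         power = rep(c0, 129), window_length = 256L,
                         overlap_fraction = 0.5, sample_rate = 100),
                    class = "psd_estimate")
  fx <- 10
  k <- which(fake$freqs >= fx)[1]
  expect_equal(band_power_above(fake, fx), c0 * (129 - k + 1))
})

test_that("band powers are monotone in the cut-off and ignore low-band power", {
  set.seed(34)
  for (i in 1:20) {
    x <- rnorm(1500) + sin(2 * pi * runif(1, 1, 40) * seq(0, 14.99, 0.01))
    p <- welch_psd(scalar_signal(x, 100))
    b <- vapply(c(5, 10, 15), function(f) band_power_above(p, f), numeric(1))
    expect_true(b[1] >= b[2] && b[2] >= b[3])
  }
  # adding power strictly below fx leaves the band sum unchanged
  base <- sine_signal(12, dur = 40)
  with_low <- scalar_signal(base$values + 2 * sin(2 * pi * 1 *
                                                    seq(0, 39.99, 0.01)), 100)
  p1 <- welch_psd(base); p2 <- welch_psd(with_low)
  k <- p1$freqs >= 8
  expect_equal(sum(p2$power[k]), sum(p1$power[k]), tolerance = 1e-6)
})

test_that("contrast_feature computes ratio and difference with guards", {
  expect_equal(contrast_feature(0.5, 0.5, "ratio"), 1.0)
  expect_equal(contrast_feature(0.5, 0.5, "difference"), 0.0)
  expect_equal(contrast_feature(2, 4, "ratio"), 0.5)
  expect_equal(contrast_feature(2, 4, "difference"), -2)
  expect_error(contrast_feature(1, 0, "ratio", eps = 0), "denominator")
  expect_equal(contrast_feature(1, 0, "ratio", eps = 1e-12), 1e12)
  expect_error(contrast_feature(1, NaN), "finite")
})

test_that("contrast recovers a planted eyes-closed sway factor", {
  # eyes-closed sway power ~2x eyes-open: ratio of band powers ~0.5
  set.seed(36)
  ratios <- replicate(15, {
    t <- seq(0, 19.99, by = 0.01)
    f <- runif(1, 1, 3)
    open <- sin(2 * pi * f * t) + rnorm(2000, sd = 0.05)
    closed <- sqrt(2) * sin(2 * pi * f * t + runif(1, 0, 2 * pi)) +
      rnorm(2000, sd = 0.05)
    po <- welch_psd(scalar_signal(open, 100))
    pc <- welch_psd(scalar_signal(closed, 100))
    contrast_feature(band_power_above(po, 0.5), band_power_above(pc, 0.5))
  })
  expect_equal(mean(ratios), 0.5, tolerance = 0.05)
})

test_that("extract_features yields near-zero band power at rest", {
  spec <- signal_sim_spec("romberg", severity = 0, noise_sd = 0,
                          tremor_amp = 0, sway_amp = 0, seed = 2)
  fv <- extract_features(simulate_exercise_set(spec))
  bands <- fv$features[grep("^psd.*(open|closed)$", names(fv$features))]
  expect_true(all(abs(bands) < 1e-6))
})

test_that("an 8 Hz tremor loads psd_5hz but not psd_10hz", {
  fs <- 100
  t <- seq(0, 14.99, by = 1 / fs)
  osc <- 0.05 * sin(2 * pi * 8 * t)
  mk <- function() imu_series(t = t, ax = osc, ay = 0.8 * osc,
                              az = 1 + 0.2 * osc,
                              gx = rep(0, length(t)), gy = rep(0, length(t)),
                              gz = rep(0, length(t)), sample_rate = fs)
  rec <- exercise_recording("postural_tremor",
                            list(left_hand = mk(), right_hand = mk()),
                            eye_condition = "not_applicable")
  fv <- extract_features(rec)
  expect_gt(fv$features[["psd_5hz"]], fv$features[["psd_10hz"]])
  expect_lt(fv$features[["psd_10hz"]], 0.05 * fv$features[["psd_5hz"]])
})

test_that("extract_features is deterministic and validates sensors", {
  spec <- signal_sim_spec("heel_knee", severity = 0.5, seed = 17)
  f1 <- extract_features(simulate_exercise_set(spec))
  f2 <- extract_features(simulate_exercise_set(spec))
  expect_identical(f1$features, f2$features)

  hand_only <- simulate_recording(signal_sim_spec("romberg", seed = 1))
  expect_error(
    exercise_recording("heel_toe_walk", hand_only$sensors),
    "requires left_foot/right_foot")
})

test_that("per-sensor aggregation exposes one feature per placement", {
  spec <- signal_sim_spec("tandem_walk", severity = 0.2, seed = 23)
  fv <- extract_features(simulate_recording(spec),
                         config = feature_config(aggregate = "per_sensor"))
  expect_true(all(c("psd_5hz.left_foot", "psd_5hz.right_foot") %in%
                    names(fv$features)))
})
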