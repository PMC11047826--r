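test_that("compute_norm is the per-sample Euclidean magnitude", {
  s <- constant_imu(1, 2, 2)
  expect_equal(compute_norm(s)$values, rep(3, 600))
  z <- constant_imu(0, 0, 0)
  expect_equal(compute_norm(z)$values, rep(0, 600))

  # per-sample scalar oracle on random triplets
  set.seed(11)
  n <- 1000
  m <- matrix(rnorm(3 * n), ncol = 3)
  s <- imu_series(t = seq(0, by = 0.01, length.out = n),
                  ax = m[, 1], ay = m[, 2], az = m[, 3], sample_rate = 100)
  oracle <- vapply(seq_len(n),
                   function(i) sqrt(m[i, 1]^2 + m[i, 2]^2 + m[i, 3]^2),
                   numeric(1))
  expect_equal(compute_norm(s)$values, oracle, tolerance = 1e-15)
  expect_true(all(compute_norm(s)$values >= 0))
})

test_that("compute_norm propagates gaps and rejects empty input", {
  s <- constant_imu(1, 2, 2)
  s$gap_mask[10] <- TRUE
  nrm <- compute_norm(s)
  expect_true(is.na(nrm$values[10]))
  expect_true(nrm$gap_mask[10])
  expect_error(imu_series(t = numeric(0), ax = numeric(0), ay = numeric(0),
                          az = numeric(0), sample_rate = 100),
               "no data")
})

test_that("compute_norm is invariant under 3-D rotations of the axes", {
  set.seed(21)
  n <- 200
  m <- matrix(rnorm(3 * n), ncol = 3)
  t <- seq(0, by = 0.01, length.out = n)
  base <- compute_norm(imu_series(t = t, ax = m[, 1], ay = m[, 2],
                                  az = m[, 3], sample_rate = 100))$values
  for (k in 1:10) {
    # random rotation via QR of a Gaussian matrix
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    mr <- m %*% t(q)
    rot <- compute_norm(imu_series(t = t, ax = mr[, 1], ay = mr[, 2],
                                   az = mr[, 3], sample_rate = 100))$values
    expect_equal(rot, base, tolerance = 1e-12)
  }
})

test_that("fill_gaps is the identity on gap-free signals and exact on quadratics", {
  s <- sine_signal(2, dur = 5)
  expect_identical(fill_gaps(s), s)

  t <- seq(0, 5.99, by = 0.01)
  y <- 3 + 2 * t - 4 * t^2
  gap <- rep(FALSE, length(t)); gap[200:202] <- TRUE
  yg <- y; yg[gap] <- NA
  filled <- fill_gaps(scalar_signal(yg, 100, gap_mask = gap))
  expect_equal(filled$values, y, tolerance = 1e-8)
  expect_false(any(filled$gap_mask))
  # non-gap samples bit-identical
  expect_identical(filled$values[!gap], y[!gap])
})

test_that("fill_gaps recovers a sine gap within tolerance of the generator", {
  fs <- 100
  t <- seq(0, 3.99, by = 1 / fs)
  y <- sin(2 * pi * 2 * t)
  gap <- rep(FALSE, length(t)); gap[150:153] <- TRUE
  yg <- y; yg[gap] <- NA
  filled <- fill_gaps(scalar_signal(yg, fs, gap_mask = gap))
  expect_lt(max(abs(filled$values[gap] - y[gap])), 0.02)
})

test_that("fill_gaps errors on over-long gaps and trims edge gaps", {
  y <- rnorm(200)
  gap <- rep(FALSE, 200); gap[50:80] <- TRUE
  expect_error(fill_gaps(scalar_signal(replace(y, gap, NA), 100,
                                       gap_mask = gap), max_gap_samples = 10),
               "gap of 31 samples")
  gap2 <- rep(FALSE, 200); gap2[c(1:3, 198:200)] <- TRUE
  out <- fill_gaps(scalar_signal(replace(y, gap2, NA), 100, gap_mask = gap2))
  expect_equal(length(out$values), 194)
  expect_identical(out$values, y[4:197])
})

test_that("fill_gaps works per channel on imu_series", {
  set.seed(3)
  n <- 300
  t <- seq(0, by = 0.01, length.out = n)
  chans <- replicate(6, cumsum(rnorm(n, sd = 0.1)), simplify = FALSE)
  gap <- rep(FALSE, n); gap[100:102] <- TRUE
  mk <- function(v) replace(v, gap, NA)
  s <- imu_series(t = t, ax = mk(chans[[1]]), ay = mk(chans[[2]]),
                  az = mk(chans[[3]]), gx = mk(chans[[4]]),
                  gy = mk(chans[[5]]), gz = mk(chans[[6]]),
                  sample_rate = 100, gap_mask = gap)
  out <- fill_gaps(s)
  expect_false(any(out$gap_mask))
  expect_identical(out$ax[!gap], chans[[1]][!gap])
  expect_true(all(is.finite(out$az)))
})

test_that("remove_gravity kills DC and preserves the passband", {
  const <- scalar_signal(rep(1, 1500), 100)
  out <- remove_gravity(const)
  expect_lt(max(abs(out$values[300:1200])), 1e-3)

  # central third: the 0.1 Hz zero-phase filter has a multi-second edge
  # transient that the band features above 5 Hz do not see
  s5 <- sine_signal(5, dur = 60)
  y <- remove_gravity(s5)$values
  amp <- max(abs(y[2000:4000]))
  expect_lt(abs(amp - 1), 0.01)   # unit passband gain at 5 Hz
})

test_that("remove_gravity attenuates to the designed stopband gain", {
  s <- sine_signal(0.01, dur = 300)
  y <- remove_gravity(s)$values
  n <- length(y)
  mid_amp <- max(abs(y[round(n * 0.4):round(n * 0.6)]))
  # freqz of the designed filter, squared for the forward-backward pass
  bound <- butter_hp_gain2(0.01)
  expect_lt(mid_amp, 2 * bound + 1e-7)
  expect_lt(mid_amp, 1e-6)
})

test_that("remove_gravity is linear and validates its inputs", {
  set.seed(5)
  s1 <- scalar_signal(rnorm(2000), 100)
  s2 <- scalar_signal(rnorm(2000), 100)
  comb <- scalar_signal(2 * s1$values - 3 * s2$values, 100)
  lhs <- remove_gravity(comb)$values
  rhs <- 2 * remove_gravity(s1)$values - 3 * remove_gravity(s2)$values
  expect_equal(lhs, rhs, tolerance = 1e-6)

  short <- scalar_signal(rnorm(10), 100)
  expect_error(remove_gravity(short), "warm-up")
  gappy <- scalar_signal(c(1, NA, 3, 4), 100)
  expect_error(remove_gravity(gappy), "gaps")
  expect_error(remove_gravity(scalar_signal(rnorm(100), 0.15)), "twice")
})

test_that("gravity removal recenters a resting recording from 1 g to 0", {
  spec <- signal_sim_spec("postural_tremor", severity = 0.3, duration = 30,
                          seed = 8)
  rec <- simulate_recording(spec)
  nrm <- compute_norm(rec$sensors$left_hand)
  expect_equal(mean(nrm$values), 1, tolerance = 0.05)
  filtered <- remove_gravity(fill_gaps(nrm))
  expect_equal(mean(filtered$values), 0, tolerance = 5e-3)
})
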