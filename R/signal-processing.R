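#' Orientation-invariant norm of a three-axis signal
#'
#' Collapses the accelerometer (or gyroscope) triplet of an [imu_series()]
#' into its per-sample Euclidean magnitude, `sqrt(x^2 + y^2 + z^2)`. Because
#' the norm is invariant under rotations of the sensor frame, it removes the
#' dependence on how the wearable was oriented on the limb. Gap samples stay
#' gaps.
#'
#' @param series An [imu_series()].
#' @param source `"accel"` (default) for the acceleration triplet (units g)
#'   or `"gyro"` for angular velocity (deg/s).
#' @return A [scalar_signal()] of the same length.
#' @export
compute_norm <- function(series, source = c("accel", "gyro")) {
  stopifnot(inherits(series, "imu_series"))
  source <- match.arg(source)
  if (length(series$t) == 0L) stop("compute_norm: empty series, no data")
  m <- if (source == "accel")
    cbind(series$ax, series$ay, series$az)
  else
    cbind(series$gx, series$gy, series$gz)
  v <- sqrt(rowSums(m^2))
  v[series$gap_mask] <- NA_real_
  scalar_signal(v, series$sample_rate,
                units = if (source == "accel") "g" else "deg/s",
                gap_mask = series$gap_mask)
}

# Runs of TRUE in a logical vector -> data.frame(start, end, length)
gap_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             length = r$lengths[keep])
}

# Quadratic least-squares fill of one interior gap from the `support`
# nearest valid samples on each side.
fill_one_gap <- function(values, start, end, valid, support = 3L) {
  left <- which(valid & seq_along(values) < start)
  right <- which(valid & seq_along(values) > end)
  left <- utils::tail(left, support)
  right <- utils::head(right, support)
  idx <- c(left, right)
  # center for conditioning
  x0 <- mean(idx)
  fit <- stats::lm.fit(cbind(1, idx - x0, (idx - x0)^2), values[idx])
  xs <- start:end
  co <- fit$coefficients
  co[is.na(co)] <- 0
  cbind(1, xs - x0, (xs - x0)^2) %*% co
}

#' Fill interior signal gaps by local quadratic interpolation
#'
#' Streaming losses leave runs of missing samples; each interior run of
#' length at most `max_gap_samples` is replaced by a degree-2 polynomial
#' fitted by least squares to the three nearest valid samples on each side.
#' Non-gap samples are passed through unchanged and the gap mask is cleared
#' where filled. Leading and trailing gaps cannot be interpolated (no
#' support on one side) and are trimmed off instead of extrapolated.
#'
#' @param x A [scalar_signal()] or [imu_series()] (all six channels are
#'   filled with the same rule).
#' @param max_gap_samples Longest interior gap, in samples, that will be
#'   filled. A longer gap is an error naming its span.
#' @return Object of the same class, gap-free in the interior.
#' @export
fill_gaps <- function(x, max_gap_samples = 25L) {
  UseMethod("fill_gaps")
}

#' @export
fill_gaps.scalar_signal <- function(x, max_gap_samples = 25L) {
  mask <- x$gap_mask
  if (!any(mask)) return(x)
  n <- length(mask)
  keep <- seq_len(n)
  # trim leading/trailing gaps
  first_ok <- which(!mask)[1]
  last_ok <- utils::tail(which(!mask), 1)
  if (is.na(first_ok)) stop("fill_gaps: signal is all gaps")
  keep <- first_ok:last_ok
  vals <- x$values[keep]
  mask <- mask[keep]
  runs <- gap_runs(mask)
  if (nrow(runs) > 0) {
    too_long <- runs$length > max_gap_samples
    if (any(too_long)) {
      r <- runs[which(too_long)[1], ]
      stop(sprintf(
        "fill_gaps: gap of %d samples at [%d, %d] exceeds max_gap_samples = %d",
        r$length, r$start, r$end, max_gap_samples))
    }
    for (i in seq_len(nrow(runs))) {
      vals[runs$start[i]:runs$end[i]] <-
        fill_one_gap(vals, runs$start[i], runs$end[i], !mask)
    }
  }
  scalar_signal(vals, x$sample_rate, units = x$units,
                gap_mask = rep(FALSE, length(vals)))
}

#' @export
fill_gaps.imu_series <- function(x, max_gap_samples = 25L) {
  mask <- x$gap_mask
  if (!any(mask)) return(x)
  first_ok <- which(!mask)[1]
  last_ok <- utils::tail(which(!mask), 1)
  if (is.na(first_ok)) stop("fill_gaps: series is all gaps")
  keep <- first_ok:last_ok
  mask <- mask[keep]
  runs <- gap_runs(mask)
  if (nrow(runs) > 0 && any(runs$length > max_gap_samples)) {
    r <- runs[which(runs$length > max_gap_samples)[1], ]
    stop(sprintf(
      "fill_gaps: gap of %d samples at [%d, %d] exceeds max_gap_samples = %d",
      r$length, r$start, r$end, max_gap_samples))
  }
  chans <- list()
  for (nm in c("ax", "ay", "az", "gx", "gy", "gz")) {
    vals <- x[[nm]][keep]
    if (all(is.na(vals))) { chans[[nm]] <- vals; next }
    for (i in seq_len(nrow(runs))) {
      vals[runs$start[i]:runs$end[i]] <-
        fill_one_gap(vals, runs$start[i], runs$end[i], !mask)
    }
    chans[[nm]] <- vals
  }
  imu_series(t = x$t[keep], ax = chans$ax, ay = chans$ay, az = chans$az,
             gx = chans$gx, gy = chans$gy, gz = chans$gz,
             sample_rate = x$sample_rate,
             gap_mask = rep(FALSE, length(keep)))
}

#' Remove the gravity component by zero-phase Butterworth high-pass filtering
#'
#' A resting accelerometer reads 1 g; movement of interest rides on top of
#' that quasi-static component. This applies an order-`order` Butterworth
#' high-pass filter with the given cut-off, forward and backward
#' (zero-phase, so exercise events are not shifted in time), after removing
#' the signal mean and padding the edges by odd reflection to suppress
#' filter start-up transients.
#'
#' @param x A gap-free [scalar_signal()].
#' @param cutoff_hz High-pass cut-off frequency in Hz (default 0.1).
#' @param order Butterworth order (default 4).
#' @return A [scalar_signal()] with the DC/gravity component removed.
#' @export
remove_gravity <- function(x, cutoff_hz = 0.1, order = 4L) {
  stopifnot(inherits(x, "scalar_signal"))
  if (any(x$gap_mask)) stop("remove_gravity: signal has gaps; fill_gaps first")
  fs <- x$sample_rate
  if (fs <= 2 * cutoff_hz)
    stop("remove_gravity: sample_rate must exceed twice the cut-off")
  n <- length(x$values)
  min_len <- 3L * (order + 1L)
  if (n < min_len)
    stop(sprintf(
      "remove_gravity: signal of %d samples shorter than filter warm-up (%d)",
      n, min_len))
  bt <- signal::butter(order, cutoff_hz / (fs / 2), type = "high")
  v <- x$values - mean(x$values)
  padlen <- min(n - 1L, as.integer(3 * round(fs / cutoff_hz)))
  pre <- 2 * v[1] - v[(padlen + 1L):2L]
  post <- 2 * v[n] - v[(n - 1L):(n - padlen)]
  y <- signal::filtfilt(bt, c(pre, v, post))
  scalar_signal(y[(padlen + 1L):(padlen + n)], fs, units = x$units,
                gap_mask = rep(FALSE, n))
}
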