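#' Six-axis inertial time series from one wearable sensor
#'
#' Container for a uniformly sampled recording from a single inertial
#' measurement unit: tri-axial acceleration in units of g and tri-axial
#' angular velocity in deg/s, together with a per-sample gap mask marking
#' values lost during streaming.
#'
#' @param t Time stamps in seconds. Must be a strictly increasing uniform
#'   grid with step `1/sample_rate`.
#' @param ax,ay,az Acceleration per axis, in g.
#' @param gx,gy,gz Angular velocity per axis, in deg/s.
#' @param sample_rate Sampling rate in Hz (positive scalar).
#' @param gap_mask Logical vector, `TRUE` where the sample is missing.
#'   Defaults to marking any sample with a non-finite value on any axis.
#'
#' @return An object of class `imu_series`: a list with the above fields.
#' @export
imu_series <- function(t, ax, ay, az, gx = NULL, gy = NULL, gz = NULL,
                       sample_rate, gap_mask = NULL) {
  n <- length(t)
  if (n == 0L) stop("imu_series: no data (empty time grid)")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("imu_series: sample_rate must be a positive scalar (Hz)")
  if (is.null(gx)) gx <- rep(NA_real_, n)
  if (is.null(gy)) gy <- rep(NA_real_, n)
  if (is.null(gz)) gz <- rep(NA_real_, n)
  chans <- list(ax = ax, ay = ay, az = az, gx = gx, gy = gy, gz = gz)
  for (nm in names(chans))
    if (length(chans[[nm]]) != n)
      stop(sprintf("imu_series: channel '%s' length %d != %d", nm,
                   length(chans[[nm]]), n))
  if (n > 1L) {
    dt <- diff(t)
    if (any(dt <= 0)) stop("imu_series: t must be strictly increasing")
    if (max(abs(dt - 1 / sample_rate)) > 1e-6 / sample_rate)
      stop("imu_series: t must be a uniform grid with step 1/sample_rate")
  }
  if (is.null(gap_mask)) {
    acc_bad <- !is.finite(ax) | !is.finite(ay) | !is.finite(az)
    gap_mask <- acc_bad
  }
  if (length(gap_mask) != n)
    stop("imu_series: gap_mask length must equal signal length")
  structure(
    c(list(t = as.numeric(t), sample_rate = as.numeric(sample_rate)),
      lapply(chans, as.numeric),
      list(gap_mask = as.logical(gap_mask))),
    class = "imu_series")
}

#' Uniformly sampled scalar signal
#'
#' Carrier for derived one-dimensional signals (e.g. the acceleration norm),
#' keeping the sampling rate, a units tag and the gap mask alongside the
#' values.
#'
#' @param values Numeric sample values.
#' @param sample_rate Sampling rate in Hz.
#' @param units Units tag, e.g. `"g"` or `"deg/s"`.
#' @param gap_mask Logical gap mask; defaults to non-finite values.
#' @return An object of class `scalar_signal`.
#' @export
scalar_signal <- function(values, sample_rate, units = "g", gap_mask = NULL) {
  n <- length(values)
  if (n == 0L) stop("scalar_signal: no data (empty values)")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("scalar_signal: sample_rate must be a positive scalar (Hz)")
  if (is.null(gap_mask)) gap_mask <- !is.finite(values)
  if (length(gap_mask) != n)
    stop("scalar_signal: gap_mask length must equal signal length")
  structure(list(values = as.numeric(values),
                 sample_rate = as.numeric(sample_rate),
                 units = units,
                 gap_mask = as.logical(gap_mask)),
            class = "scalar_signal")
}

#' @export
length.scalar_signal <- function(x) length(x$values)

#' @export
print.imu_series <- function(x, ...) {
  cat(sprintf("<imu_series> %d samples @ %g Hz (%.2f s), %d gap(s)\n",
              length(x$t), x$sample_rate, length(x$t) / x$sample_rate,
              sum(x$gap_mask)))
  invisible(x)
}

#' @export
print.scalar_signal <- function(x, ...) {
  cat(sprintf("<scalar_signal> %d samples @ %g Hz [%s], %d gap(s)\n",
              length(x$values), x$sample_rate, x$units, sum(x$gap_mask)))
  invisible(x)
}
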