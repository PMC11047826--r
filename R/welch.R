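#' Welch power spectral density estimate
#'
#' Averaged modified periodogram: the signal is cut into segments of
#' `window_length` samples overlapping by `overlap_fraction`, each segment
#' is mean-detrended, tapered with a Hann window and Fourier transformed,
#' and the squared magnitudes are averaged and scaled to a one-sided power
#' spectral density (units^2/Hz).
#'
#' @param x A gap-free [scalar_signal()] with at least `window_length`
#'   samples.
#' @param window_length Segment length in samples (default 256).
#' @param overlap_fraction Overlap between consecutive segments as a
#'   fraction in `[0, 1)` (default 0.5).
#' @return An object of class `psd_estimate`: list with `freqs` (Hz,
#'   ascending from 0 to Nyquist), `power` (density per bin),
#'   `window_length`, `overlap_fraction`, `sample_rate`.
#' @export
welch_psd <- function(x, window_length = 256L, overlap_fraction = 0.5) {
  stopifnot(inherits(x, "scalar_signal"))
  if (any(x$gap_mask)) stop("welch_psd: signal has gaps; fill_gaps first")
  nwin <- as.integer(window_length)
  if (nwin < 8L) stop("welch_psd: window_length too small")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("welch_psd: overlap_fraction must be in [0, 1)")
  v <- x$values
  n <- length(v)
  if (n < nwin)
    stop(sprintf(paste0(
      "welch_psd: signal of %d samples is shorter than one window (%d); ",
      "record a longer signal"), n, nwin))
  fs <- x$sample_rate
  step <- max(1L, as.integer(round(nwin * (1 - overlap_fraction))))
  starts <- seq.int(1L, n - nwin + 1L, by = step)
  # periodic Hann window
  w <- 0.5 * (1 - cos(2 * pi * (0:(nwin - 1L)) / nwin))
  scale <- fs * sum(w^2)
  nfreq <- nwin %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- v[s:(s + nwin - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- stats::fft(seg)[seq_len(nfreq)]
    acc <- acc + (Re(sp)^2 + Im(sp)^2)
  }
  p <- acc / (length(starts) * scale)
  # one-sided: double everything except DC and (for even nwin) Nyquist
  dbl <- rep(2, nfreq)
  dbl[1] <- 1
  if (nwin %% 2L == 0L) dbl[nfreq] <- 1
  p <- p * dbl
  structure(list(freqs = (0:(nfreq - 1L)) * fs / nwin,
                 power = p,
                 window_length = nwin,
                 overlap_fraction = overlap_fraction,
                 sample_rate = fs),
            class = "psd_estimate")
}

#' Cumulative band power at and above a cut-off frequency
#'
#' Sums the PSD bins from the first frequency at or above `fx` through the
#' last bin of the spectrum. These cumulative high-band sums (e.g. at 5, 10
#' and 15 Hz) are the spectral features fed to the classifiers: they
#' compress the spectrum while preserving how much movement power sits
#' above each cut-off.
#'
#' @param psd A `psd_estimate` from [welch_psd()].
#' @param fx Cut-off frequency in Hz, `0 <= fx`. A cut-off above the
#'   Nyquist frequency selects no bins: the result is 0, with a warning.
#' @return Scalar sum of the selected power bins.
#' @export
band_power_above <- function(psd, fx) {
  stopifnot(inherits(psd, "psd_estimate"))
  if (!is.numeric(fx) || length(fx) != 1L || fx < 0)
    stop("band_power_above: fx must be a nonnegative scalar frequency")
  nyq <- psd$sample_rate / 2
  if (fx > nyq) {
    warning(sprintf(
      "band_power_above: fx = %g Hz exceeds Nyquist (%g Hz); no bins, result 0",
      fx, nyq))
    return(0)
  }
  sum(psd$power[psd$freqs >= fx])
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf(
    "<psd_estimate> %d bins, 0..%g Hz (window %d, overlap %g, fs %g Hz)\n",
    length(x$freqs), max(x$freqs), x$window_length, x$overlap_fraction,
    x$sample_rate))
  invisible(x)
}
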