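#' Window functions
#'
#' Periodic Hann ("Hanning") and Hamming windows of length `n`, as used by
#' the spectral estimators in this package: Hann for the RR-interval
#' tachogram, Hamming for the EEG channels.
#'
#' @param n Window length in samples.
#' @return Numeric vector of length `n`.
#' @keywords internal
#' @name windows
NULL

#' @rdname windows
hann_window <- function(n) {
  stopifnot(n >= 1)
  0.5 - 0.5 * cos(2 * pi * seq_len(n) / n - 2 * pi / n)
}

#' @rdname windows
hamming_window <- function(n) {
  stopifnot(n >= 1)
  0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodogram over overlapping windowed segments.  Each
#' segment is mean-detrended, multiplied by the window, and its one-sided
#' periodogram is scaled as a spectral density (unit^2/Hz), so that
#' `sum(psd) * df` approximates the variance of the signal (Parseval).
#'
#' @param x Numeric vector (or matrix with one column per channel),
#'   uniformly sampled.
#' @param fs Sampling frequency in Hz.
#' @param nperseg Segment length in samples.
#' @param hop Hop between segment starts in samples (`nperseg - overlap`).
#' @param window Numeric window vector of length `nperseg`.
#' @return List with `freq` (Hz, length `nperseg/2 + 1`) and `psd`
#'   (density matrix, one column per channel of `x`).
#' @keywords internal
welch_psd <- function(x, fs, nperseg, hop, window) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < nperseg) {
    stop("signal shorter than one segment (", n, " < ", nperseg, " samples)")
  }
  stopifnot(hop >= 1, length(window) == nperseg)
  starts <- seq(1L, n - nperseg + 1L, by = hop)
  nfreq <- nperseg %/% 2L + 1L
  scale <- 2 / (fs * sum(window^2))
  psd <- matrix(0, nfreq, ncol(x))
  for (ch in seq_len(ncol(x))) {
    # segment matrix: nperseg x nseg, detrend + window, one FFT call
    seg <- matrix(x[outer(seq_len(nperseg) - 1L, starts, "+"), ch],
                  nrow = nperseg)
    seg <- sweep(seg, 2L, colMeans(seg))
    seg <- seg * window
    spec <- Mod(stats::mvfft(seg))^2
    pg <- rowMeans(spec[seq_len(nfreq), , drop = FALSE]) * scale
    # DC and Nyquist bins are not doubled in a one-sided density
    pg[1L] <- pg[1L] / 2
    if (nperseg %% 2L == 0L) pg[nfreq] <- pg[nfreq] / 2
    psd[, ch] <- pg
  }
  list(freq = seq(0, nfreq - 1L) * fs / nperseg, psd = psd)
}

#' Trapezoidal band power
#'
#' Area under a spectral density between two frequencies, by trapezoidal
#' integration over the native grid — the area-under-the-curve band
#' averaging standard in HRV toolboxes.
#'
#' The density is linearly interpolated at the exact band edges, so
#' disjoint sub-bands tile: AUC(lo, mid) + AUC(mid, hi) = AUC(lo, hi).
#'
#' @param freq Frequency grid (Hz, strictly increasing).
#' @param psd Density values on `freq`.
#' @param lo,hi Band edges in Hz.
#' @return Band power in (signal unit)^2.
#' @keywords internal
band_auc <- function(freq, psd, lo, hi) {
  lo <- max(lo, freq[1])
  hi <- min(hi, freq[length(freq)])
  if (hi <= lo) return(0)
  inner <- freq > lo & freq < hi
  f <- c(lo, freq[inner], hi)
  p <- c(stats::approx(freq, psd, lo)$y, psd[inner],
         stats::approx(freq, psd, hi)$y)
  sum(diff(f) * (p[-1] + p[-length(p)]) / 2)
}
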