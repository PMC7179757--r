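#' RR-interval series in device units
#'
#' Beat-to-beat R-to-R intervals as streamed by the chest-strap sensor,
#' in device units of 1/1024 s.  Intervals converting to less than 0.3 s
#' or more than 2.0 s are physiologically implausible and raise a
#' warning (they are kept: the pipeline applies no ectopic-beat
#' filtering).
#'
#' @param intervals Positive integer vector, 1/1024-s units.
#' @param origin Free-text source tag.
#' @return An object of class `rri_series`.
#' @examples
#' rri_series(c(1024, 1024, 1024))
#' @export
rri_series <- function(intervals, origin = "unknown") {
  if (length(intervals) == 0) stop("empty RR-interval series")
  if (any(!is.finite(intervals)) || any(intervals <= 0)) {
    stop("all RR intervals must be positive")
  }
  intervals <- as.integer(round(intervals))
  secs <- intervals / 1024
  n_out <- sum(secs < 0.3 | secs > 2.0)
  if (n_out > 0) {
    warning(n_out, " interval(s) outside the physiologic [0.3, 2.0] s range")
  }
  structure(list(intervals = intervals, origin = origin), class = "rri_series")
}

#' Convert RR intervals from device units to seconds
#'
#' @param rri An [rri_series].
#' @return Numeric vector of intervals in seconds (device value / 1024).
#' @examples
#' rri_to_seconds(rri_series(c(512, 2048)))  # 0.5, 2.0
#' @export
rri_to_seconds <- function(rri) {
  stopifnot(inherits(rri, "rri_series"))
  rri$intervals / 1024
}

#' Time-domain HRV summary
#'
#' Mean heart rate plus the two standard time-domain HRV statistics:
#' SDNN, the sample (n-1) standard deviation of the intervals, and
#' RMSSD, the root mean square of successive interval differences — the
#' latter indexing parasympathetic (vagal) activity.
#'
#' @param rri An [rri_series] with at least 3 intervals.
#' @return Named list: `mean_hr` (BPM), `sdnn` (ms), `rmssd` (ms).
#' @examples
#' rr_ms <- c(800, 900, 800, 900, 800)
#' time_domain_summary(rri_series(round(rr_ms * 1.024)))
#' @export
time_domain_summary <- function(rri) {
  rr_s <- rri_to_seconds(rri)
  if (length(rr_s) < 3) stop("need at least 3 intervals for RMSSD")
  rr_ms <- rr_s * 1000
  list(mean_hr = 60 / mean(rr_s),
       sdnn = stats::sd(rr_ms),
       rmssd = sqrt(mean(diff(rr_ms)^2)))
}

#' Frequency-domain HRV summary
#'
#' The interval tachogram (interval value against its beat time) is
#' resampled evenly by cubic interpolation, mean-detrended, and fed to a
#' Welch estimator with Hann windows at 50% overlap.  Band powers are the
#' trapezoidal area under the density over the canonical HRV bands:
#' VLF 0.0033-0.04 Hz, LF 0.04-0.15 Hz, HF 0.15-0.40 Hz, in ms^2.
#' VLF is reported even for 3-min blocks, which is too short to resolve
#' the band properly; consumers should treat short-block VLF as
#' indicative only.
#'
#' @param rri An [rri_series] spanning at least 120 s.
#' @param resample_hz Even-resampling rate in Hz (default 4, standard
#'   HRV practice).
#' @param seg_len Welch segment length in samples (default 256, i.e. 64 s
#'   at 4 Hz).
#' @return Named list: `vlf`, `lf`, `hf` in ms^2.
#' @export
spectral_summary <- function(rri, resample_hz = 4, seg_len = 256) {
  rr_s <- rri_to_seconds(rri)
  beat_t <- cumsum(rr_s)
  span <- beat_t[length(beat_t)] - beat_t[1]
  if (span < 120) stop("recording spans ", round(span, 1),
                       " s; need >= 120 s for spectral HRV")
  if (resample_hz < 1) stop("resample_hz must be >= 1")
  grid <- seq(beat_t[1], beat_t[length(beat_t)], by = 1 / resample_hz)
  tach <- stats::spline(beat_t, rr_s * 1000, xout = grid, method = "fmm",
                        ties = "ordered")$y
  if (length(tach) < seg_len) {
    stop("resampled tachogram (", length(tach),
         " samples) shorter than seg_len = ", seg_len)
  }
  tach <- tach - mean(tach)
  est <- welch_psd(tach, fs = resample_hz, nperseg = seg_len,
                   hop = seg_len %/% 2L, window = hann_window(seg_len))
  list(vlf = band_auc(est$freq, est$psd[, 1], 0.0033, 0.04),
       lf = band_auc(est$freq, est$psd[, 1], 0.04, 0.15),
       hf = band_auc(est$freq, est$psd[, 1], 0.15, 0.40))
}

#' Full HRV summary for one recording block
#'
#' @param rri An [rri_series].
#' @param ... Passed to [spectral_summary()].
#' @return One-row data.frame: `mean_hr`, `sdnn`, `rmssd`, `vlf`, `lf`,
#'   `hf`.
#' @export
hrv_summary <- function(rri, ...) {
  td <- time_domain_summary(rri)
  fd <- spectral_summary(rri, ...)
  as.data.frame(c(td, fd))
}
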