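#' EEG rhythm band definitions
#'
#' Band edges in Hz: delta 1-4, theta 4-8, alpha 8-12, beta 12-30,
#' gamma 30-100.  Band membership throughout the package is half-open
#' `[lo, hi)`, so a shared edge (e.g. 4 Hz) is never counted twice.
#'
#' @return data.frame with columns `band`, `lo`, `hi`.
#' @export
eeg_bands <- function() {
  data.frame(band = c("delta", "theta", "alpha", "beta", "gamma"),
             lo = c(1, 4, 8, 12, 30),
             hi = c(4, 8, 12, 30, 100))
}

#' @rdname eeg_bands
#' @export
eeg_channels <- function() c("TP9", "Fp1", "Fp2", "TP10")

#' Multichannel EEG recording
#'
#' Uniformly sampled voltage series from the four headband electrodes
#' TP9, Fp1, Fp2 and TP10 (10-20 positions).
#'
#' @param samples Numeric matrix, time x channel, in uV; column names
#'   must match the channel set.
#' @param fs Sampling frequency in Hz (> 0).
#' @param channels Channel names, in column order of `samples`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, fs, channels = eeg_channels()) {
  samples <- as.matrix(samples)
  if (!is.null(colnames(samples))) channels <- colnames(samples)
  if (!setequal(channels, eeg_channels())) {
    stop("channels must be exactly {", paste(eeg_channels(), collapse = ", "), "}")
  }
  samples <- samples[, eeg_channels(), drop = FALSE]
  if (any(!is.finite(samples))) stop("EEG samples must be finite")
  if (!is.finite(fs) || fs <= 0) stop("fs must be positive")
  structure(list(fs = fs, channels = eeg_channels(), samples = samples),
            class = "eeg_recording")
}

#' Windowed power spectral density of an EEG recording
#'
#' Welch-style average of Hamming-windowed 256-sample segments at 90%
#' overlap.  90% of 256 is 230.4 samples; the hop is fixed at 26 samples
#' (overlap 230) so the segmentation is reproducible.  The grid is
#' truncated to 0-110 Hz.
#'
#' @param rec An [eeg_recording] with at least `nperseg` samples.
#' @param nperseg Segment length in samples (default 256).
#' @param hop Segment hop in samples (default 26).
#' @param fmax Upper frequency cut in Hz (default 110).
#' @return An object of class `psd_frame`: list with `freq` (Hz) and
#'   `power` (uV^2/Hz, one column per channel).
#' @export
compute_psd <- function(rec, nperseg = 256, hop = 26, fmax = 110) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$samples) < nperseg) {
    stop("recording shorter than one window (", nrow(rec$samples), " < ",
         nperseg, " samples)")
  }
  est <- welch_psd(rec$samples, fs = rec$fs, nperseg = nperseg, hop = hop,
                   window = hamming_window(nperseg))
  keep <- est$freq <= fmax
  power <- est$psd[keep, , drop = FALSE]
  colnames(power) <- rec$channels
  structure(list(freq = est$freq[keep], power = power,
                 channels = rec$channels),
            class = "psd_frame")
}

#' Absolute log bandpowers per channel
#'
#' For each band, the PSD bins whose center lies in `[lo, hi)` are
#' summed; the absolute bandpower is `log10` of that sum (Bels).  The
#' frontal value of each band is the arithmetic mean of the Fp1 and Fp2
#' entries — log powers for the log fields, linear sums for the linear
#' fields (which feed the ratio indexes).
#'
#' @param psd A [psd_frame] covering all band edges.
#' @return An object of class `bandpower_set`: `log` and `linear`
#'   band x channel matrices plus `frontal_log` and `frontal_linear`
#'   per-band vectors.
#' @export
absolute_bandpowers <- function(psd) {
  stopifnot(inherits(psd, "psd_frame"))
  bands <- eeg_bands()
  if (max(psd$freq) < max(bands$hi)) {
    stop("PSD grid (max ", max(psd$freq), " Hz) does not cover the band edges")
  }
  linear <- matrix(NA_real_, nrow(bands), length(psd$channels),
                   dimnames = list(bands$band, psd$channels))
  for (b in seq_len(nrow(bands))) {
    sel <- psd$freq >= bands$lo[b] & psd$freq < bands$hi[b]
    linear[b, ] <- colSums(psd$power[sel, , drop = FALSE])
  }
  logp <- suppressWarnings(log10(linear))
  frontal <- c("Fp1", "Fp2")
  structure(list(log = logp, linear = linear,
                 frontal_log = rowMeans(logp[, frontal, drop = FALSE]),
                 frontal_linear = rowMeans(linear[, frontal, drop = FALSE])),
            class = "bandpower_set")
}

#' Derived EEG indexes
#'
#' Three classic indexes over the frontal electrodes:
#' * engagement = beta / (alpha + theta), on frontal-averaged linear
#'   band powers;
#' * frontal alpha asymmetry = alpha(Fp2) - alpha(Fp1), on log powers
#'   (right minus left, the asymmetry-literature convention);
#' * theta/beta ratio = theta / beta, on frontal-averaged linear powers.
#'
#' Ratios on log powers are scale artifacts, hence the linear default;
#' set `use_log_ratios = TRUE` to reproduce log-ratio variants.
#' A zero denominator yields `NA` with a warning rather than an error.
#'
#' @param bp A [bandpower_set].
#' @param use_log_ratios Compute engagement and theta/beta on log powers
#'   instead of linear sums.
#' @return Named list: `engagement`, `asymmetry` (Bels), `theta_beta`.
#' @export
derived_indexes <- function(bp, use_log_ratios = FALSE) {
  stopifnot(inherits(bp, "bandpower_set"))
  pw <- if (use_log_ratios) bp$frontal_log else bp$frontal_linear
  ratio <- function(num, den) {
    if (!is.finite(den) || den == 0) {
      warning("zero or non-finite denominator in EEG index; returning NA")
      return(NA_real_)
    }
    unname(num / den)
  }
  list(engagement = ratio(pw[["beta"]], pw[["alpha"]] + pw[["theta"]]),
       asymmetry = bp$log["alpha", "Fp2"] - bp$log["alpha", "Fp1"],
       theta_beta = ratio(pw[["theta"]], pw[["beta"]]))
}

#' One-row EEG feature summary for a recording block
#'
#' Runs PSD -> bandpowers -> indexes and returns the frontal log
#' bandpowers together with the three indexes.
#'
#' @param rec An [eeg_recording].
#' @param ... Passed to [compute_psd()].
#' @return One-row data.frame with columns `frontal_delta` ..
#'   `frontal_gamma` (Bels), `engagement`, `asymmetry`, `theta_beta`.
#' @export
eeg_feature_summary <- function(rec, ...) {
  bp <- absolute_bandpowers(compute_psd(rec, ...))
  idx <- derived_indexes(bp)
  out <- as.list(stats::setNames(bp$frontal_log,
                                 paste0("frontal_", names(bp$frontal_log))))
  as.data.frame(c(out, idx))
}
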