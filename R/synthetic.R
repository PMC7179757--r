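#' Condition profile for the synthetic trainee
#'
#' A `state_profile` describes one psychophysiological condition: the mean
#' heart rate and the depth of its low-frequency (0.1 Hz) and
#' high-frequency (0.25 Hz, respiratory) modulation, plus the amplitude of
#' each EEG rhythm per channel.  Profiles are the knobs of the synthetic
#' cohort: harder conditions carry a higher `hr_mean` and a lower frontal
#' theta amplitude, the two axes of the psychophysiological model the
#' adaptation rule is built on.
#'
#' @param label Condition tag: `"baseline"`, `"easy"`, `"medium"`,
#'   `"hard"` or `"custom"`.
#' @param hr_mean Mean heart rate in beats/min; must lie in \[30, 220\].
#' @param lf_amp,hf_amp Dimensionless modulation depths of the
#'   instantaneous heart rate at 0.1 Hz and 0.25 Hz; each in \[0, 0.5).
#' @param band_amps Named numeric vector or 5 x 4 matrix of EEG band
#'   amplitudes (uV RMS) for bands delta, theta, alpha, beta, gamma; a
#'   vector is recycled across the four channels TP9, Fp1, Fp2, TP10.
#' @param noise_sd Broadband EEG noise standard deviation in uV.
#' @param rri_noise Fractional white-noise level on the instantaneous
#'   beat rate (dimensionless).
#' @return An object of class `state_profile`.
#' @examples
#' p <- state_profile("easy", hr_mean = 88)
#' p$hr_mean
#' @export
state_profile <- function(label = "custom",
                          hr_mean = 75,
                          lf_amp = 0.05,
                          hf_amp = 0.08,
                          band_amps = c(delta = 20, theta = 10, alpha = 10,
                                        beta = 5, gamma = 2),
                          noise_sd = 2,
                          rri_noise = 0.05) {
  label <- match.arg(label, c("baseline", "easy", "medium", "hard", "custom"))
  if (!is.finite(hr_mean) || hr_mean < 30 || hr_mean > 220) {
    stop("hr_mean must lie in [30, 220] BPM, got ", hr_mean)
  }
  for (a in c(lf_amp, hf_amp)) {
    if (!is.finite(a) || a < 0 || a >= 0.5) {
      stop("modulation depths must lie in [0, 0.5)")
    }
  }
  bands <- eeg_bands()$band
  chans <- eeg_channels()
  if (is.matrix(band_amps)) {
    stopifnot(nrow(band_amps) == length(bands), ncol(band_amps) == length(chans))
    amps <- band_amps
  } else {
    stopifnot(length(band_amps) == length(bands))
    if (!is.null(names(band_amps))) band_amps <- band_amps[bands]
    amps <- matrix(unname(band_amps), length(bands), length(chans))
  }
  dimnames(amps) <- list(bands, chans)
  if (any(!is.finite(amps)) || any(amps < 0)) stop("band_amps must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (rri_noise < 0) stop("rri_noise must be >= 0")
  structure(list(label = label, hr_mean = hr_mean, lf_amp = lf_amp,
                 hf_amp = hf_amp, band_amps = amps, noise_sd = noise_sd,
                 rri_noise = rri_noise),
            class = "state_profile")
}

#' Default condition profiles for the four-block session
#'
#' Encodes the observed trend across difficulty: heart rate rises with
#' difficulty while frontal theta amplitude falls.  The absolute levels
#' are package choices (the source trends are qualitative): baseline at a
#' resting 75 BPM rising to 105 BPM under the hard block, and frontal
#' theta amplitude shrinking from 12 to 7 uV RMS.
#'
#' @param hr_levels Named numeric vector of mean HR per condition (BPM).
#' @param theta_levels Named numeric vector of frontal theta amplitude per
#'   condition (uV RMS).
#' @return Named list of four [state_profile] objects.
#' @export
condition_profiles <- function(hr_levels = c(baseline = 75, easy = 88,
                                             medium = 96, hard = 105),
                               theta_levels = c(baseline = 12, easy = 10,
                                                medium = 8.5, hard = 7)) {
  conds <- c("baseline", "easy", "medium", "hard")
  stopifnot(all(conds %in% names(hr_levels)), all(conds %in% names(theta_levels)))
  out <- lapply(conds, function(cond) {
    amps <- c(delta = 20, theta = unname(theta_levels[cond]), alpha = 10,
              beta = 5, gamma = 2)
    state_profile(cond, hr_mean = unname(hr_levels[cond]), band_amps = amps)
  })
  names(out) <- conds
  out
}

#' Generate an RR-interval series by integral pulse frequency modulation
#'
#' The IPFM model emits a beat each time the integral of the instantaneous
#' beat rate crosses a unit threshold.  The rate is
#' `m(t) = (hr_mean/60) * (1 + lf_amp sin(2 pi 0.1 t + phi1)
#'                           + hf_amp sin(2 pi 0.25 t + phi2))`
#' plus white noise, so the spectral content of the resulting tachogram is
#' constructible by design: the LF (0.04-0.15 Hz) and HF (0.15-0.40 Hz)
#' modulations land in the standard HRV analysis bands.  Intervals are
#' returned in device units of 1/1024 s.
#'
#' @param profile A [state_profile].
#' @param duration Recording length in seconds (>= 30).
#' @param seed Integer seed; the generator is a pure function of
#'   `(profile, duration, seed)`.
#' @param grid_hz Integration grid in Hz (default 256).
#' @return An [rri_series] with intervals in 1/1024-s units.
#' @examples
#' rri <- generate_rri(state_profile(hr_mean = 60, lf_amp = 0, hf_amp = 0,
#'                                   rri_noise = 0), 60, seed = 1)
#' length(rri$intervals)
#' @export
generate_rri <- function(profile, duration, seed, grid_hz = 256) {
  stopifnot(inherits(profile, "state_profile"))
  if (!is.finite(duration) || duration < 30) {
    stop("duration must be >= 30 s, got ", duration)
  }
  withr::with_seed(seed, {
    phi <- stats::runif(2, 0, 2 * pi)
    tt <- seq(0, duration, by = 1 / grid_hz)
    base <- profile$hr_mean / 60
    m <- base * (1 + profile$lf_amp * sin(2 * pi * 0.1 * tt + phi[1]) +
                     profile$hf_amp * sin(2 * pi * 0.25 * tt + phi[2]))
    if (profile$rri_noise > 0) {
      m <- m + stats::rnorm(length(tt), 0, profile$rri_noise * base)
    }
    m <- pmax(m, 1e-6)
    # cumulative trapezoid integral of the rate; beats at unit crossings
    integ <- c(0, cumsum((m[-1] + m[-length(m)]) / (2 * grid_hz)))
    n_beats <- floor(integ[length(integ)])
    if (n_beats < 2) stop("duration too short for two beats at this rate")
    beat_t <- stats::approx(integ, tt, xout = seq_len(n_beats), ties = "ordered")$y
    rr_units <- round(diff(c(0, beat_t)) * 1024)
    rri_series(pmax(rr_units, 1), origin = paste0("ipfm:", profile$label))
  })
}

#' Generate a band-structured multichannel EEG recording
#'
#' Each channel is the sum of five independent band-limited Gaussian noise
#' components — one per rhythm (delta 1-4, theta 4-8, alpha 8-12,
#' beta 12-30, gamma 30-100 Hz) scaled to the profile's RMS amplitude —
#' plus broadband white noise.  Band limiting is done by FFT masking, so
#' injected power stays inside its band up to windowing leakage in the
#' downstream estimator.
#'
#' @param profile A [state_profile].
#' @param duration Recording length in seconds (>= 10).
#' @param fs Sampling frequency in Hz; must exceed twice the highest band
#'   edge (>= 200 Hz). Default 500 Hz, the headband's advertised rate.
#' @param seed Integer seed.
#' @return An [eeg_recording].
#' @export
generate_eeg <- function(profile, duration, fs = 500, seed = 1) {
  stopifnot(inherits(profile, "state_profile"))
  if (duration < 10) stop("duration must be >= 10 s")
  bands <- eeg_bands()
  if (fs < 2 * max(bands$hi)) {
    stop("fs must be at least twice the highest band edge (>= ",
         2 * max(bands$hi), " Hz)")
  }
  n <- round(duration * fs)
  chans <- eeg_channels()
  withr::with_seed(seed, {
    f_abs <- abs(seq(0, n - 1) * fs / n)
    f_abs <- pmin(f_abs, fs - f_abs)   # aliased (two-sided) frequency
    x <- matrix(0, n, length(chans))
    for (ch in seq_along(chans)) {
      for (b in seq_len(nrow(bands))) {
        amp <- profile$band_amps[b, ch]
        if (amp <= 0) next
        w <- stats::rnorm(n)
        spec <- stats::fft(w)
        spec[!(f_abs >= bands$lo[b] & f_abs < bands$hi[b])] <- 0+0i
        comp <- Re(stats::fft(spec, inverse = TRUE)) / n
        s <- stats::sd(comp)
        if (s > 0) x[, ch] <- x[, ch] + comp * (amp / s)
      }
      if (profile$noise_sd > 0) {
        x[, ch] <- x[, ch] + stats::rnorm(n, 0, profile$noise_sd)
      }
    }
    colnames(x) <- chans
    eeg_recording(x, fs = fs)
  })
}

#' Cohort specification
#'
#' Describes a synthetic repeated-measures cohort: `n_participants`
#' trainees each measured under the four session conditions, with
#' between-subject Gaussian offsets on resting HR (sd 5 BPM) and a
#' multiplicative jitter on theta amplitude (sd 10%).
#'
#' @param n_participants Number of trainees (>= 2); the study cohort is 10.
#' @param condition_effects Named list of [state_profile]s covering
#'   baseline, easy, medium and hard (see [condition_profiles()]).
#' @param block_duration Block length in seconds (>= 60); the session
#'   protocol uses 3-min (180 s) blocks.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 10,
                        condition_effects = condition_profiles(),
                        block_duration = 180,
                        seed = 1) {
  if (n_participants < 2) stop("n_participants must be >= 2")
  if (block_duration < 60) stop("block_duration must be >= 60 s")
  conds <- c("baseline", "easy", "medium", "hard")
  missing <- setdiff(conds, names(condition_effects))
  if (length(missing)) {
    stop("condition_effects missing condition(s): ",
         paste(missing, collapse = ", "))
  }
  structure(list(n_participants = n_participants,
                 condition_effects = condition_effects[conds],
                 block_duration = block_duration,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort of raw physiological recordings
#'
#' Emits one RR-interval series (and optionally one EEG recording) per
#' participant per condition.  Participant-level offsets model
#' between-subject variability; condition effects come from the profiles
#' in the spec.  Deterministic under the spec's seed.
#'
#' @param spec A [cohort_spec].
#' @param signals Which raw signals to synthesize: `"both"` (default),
#'   `"rri"` or `"eeg"`.
#' @param fs EEG sampling frequency in Hz.
#' @param hr_offset_sd Between-subject HR offset sd in BPM.
#' @param theta_jitter_sd Between-subject multiplicative theta-amplitude
#'   jitter sd (fraction).
#' @return A list of class `cohort` with elements `spec` and
#'   `participants`; each participant holds its offsets and a named list
#'   of per-condition recordings (`rri`, `eeg`).
#' @export
generate_cohort <- function(spec, signals = c("both", "rri", "eeg"),
                            fs = 500, hr_offset_sd = 5, theta_jitter_sd = 0.1) {
  stopifnot(inherits(spec, "cohort_spec"))
  signals <- match.arg(signals)
  conds <- names(spec$condition_effects)
  n <- spec$n_participants
  seeds <- withr::with_seed(spec$seed, {
    list(hr_off = stats::rnorm(n, 0, hr_offset_sd),
         th_mult = pmax(stats::rnorm(n, 1, theta_jitter_sd), 0.2),
         sub = matrix(sample.int(.Machine$integer.max - 1L, 2L * n * length(conds)),
                      nrow = 2L))
  })
  participants <- vector("list", n)
  k <- 0L
  for (p in seq_len(n)) {
    recs <- vector("list", length(conds))
    names(recs) <- conds
    for (ci in seq_along(conds)) {
      k <- k + 1L
      prof <- spec$condition_effects[[ci]]
      amps <- prof$band_amps
      amps["theta", ] <- amps["theta", ] * seeds$th_mult[p]
      prof_p <- state_profile(prof$label,
                              hr_mean = min(max(prof$hr_mean + seeds$hr_off[p], 30), 220),
                              lf_amp = prof$lf_amp, hf_amp = prof$hf_amp,
                              band_amps = amps, noise_sd = prof$noise_sd,
                              rri_noise = prof$rri_noise)
      rec <- list()
      if (signals != "eeg") {
        rec$rri <- generate_rri(prof_p, spec$block_duration, seed = seeds$sub[1, k])
      }
      if (signals != "rri") {
        rec$eeg <- generate_eeg(prof_p, spec$block_duration, fs = fs,
                                seed = seeds$sub[2, k])
      }
      recs[[ci]] <- rec
    }
    participants[[p]] <- list(id = p, hr_offset = seeds$hr_off[p],
                              theta_mult = seeds$th_mult[p], conditions = recs)
  }
  structure(list(spec = spec, participants = participants), class = "cohort")
}
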