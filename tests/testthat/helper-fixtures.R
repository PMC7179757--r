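# shared fixtures: small, fast profiles and a direct-periodogram oracle

quiet_profile <- function(hr = 70, lf = 0, hf = 0) {
  state_profile(hr_mean = hr, lf_amp = lf, hf_amp = hf, rri_noise = 0)
}

single_band_profile <- function(band, amp, noise_sd = 0) {
  amps <- c(delta = 0, theta = 0, alpha = 0, beta = 0, gamma = 0)
  amps[band] <- amp
  state_profile(band_amps = amps, noise_sd = noise_sd)
}

# independent oracle: raw one-shot periodogram (no windowing, no Welch
# averaging), one-sided density scaling
direct_periodogram <- function(x, fs) {
  n <- length(x)
  x <- x - mean(x)
  spec <- Mod(stats::fft(x))^2 / (fs * n)
  nfreq <- n %/% 2 + 1
  pg <- spec[seq_len(nfreq)] * 2
  pg[1] <- pg[1] / 2
  if (n %% 2 == 0) pg[nfreq] <- pg[nfreq] / 2
  list(freq = seq(0, nfreq - 1) * fs / n, psd = pg)
}

# small cohort with a strong monotone HR effect, RRI only (fast)
big_effect_spec <- function(seed = 1, n = 10, block = 60) {
  cohort_spec(
    n_participants = n,
    condition_effects = condition_profiles(
      hr_levels = c(baseline = 70, easy = 95, medium = 105, hard = 115)),
    block_duration = block, seed = seed)
}

null_effect_spec <- function(seed, n = 10, block = 60) {
  cohort_spec(
    n_participants = n,
    condition_effects = condition_profiles(
      hr_levels = c(baseline = 80, easy = 80, medium = 80, hard = 80)),
    block_duration = block, seed = seed)
}
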