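test_that("constant-rate IPFM emits metronome beats in device units", {
  rri <- generate_rri(quiet_profile(hr = 60), 60, seed = 1)
  expect_length(rri$intervals, 60)
  expect_true(all(rri$intervals == 1024L))
})

test_that("IPFM beat count and mean HR track the profile", {
  for (hr in c(50, 70, 100)) {
    rri <- generate_rri(quiet_profile(hr = hr), 120, seed = hr)
    expect_lte(abs(length(rri$intervals) - floor(120 * hr / 60)), 1)
  }
  rri <- generate_rri(state_profile(hr_mean = 100), 300, seed = 2)
  est_hr <- 60 / mean(rri_to_seconds(rri))
  expect_lt(abs(est_hr - 100), 2)
})

test_that("IPFM spectral content lands in the modulated band", {
  # HF-only modulation: HF power dominates LF through the full pipeline
  rri_hf <- generate_rri(state_profile(hr_mean = 70, lf_amp = 0,
                                       hf_amp = 0.1, rri_noise = 0),
                         300, seed = 3)
  s <- spectral_summary(rri_hf)
  expect_gt(s$hf, 5 * s$lf)
  expect_gt(s$hf / (s$vlf + s$lf + s$hf), 0.8)
  # LF-only modulation: the mirror check
  rri_lf <- generate_rri(state_profile(hr_mean = 70, lf_amp = 0.1,
                                       hf_amp = 0, rri_noise = 0),
                         300, seed = 4)
  s2 <- spectral_summary(rri_lf)
  expect_gt(s2$lf / (s2$vlf + s2$lf + s2$hf), 0.8)
})

test_that("generators are pure functions of arguments and seed", {
  p <- state_profile(hr_mean = 80)
  expect_identical(generate_rri(p, 60, seed = 7)$intervals,
                   generate_rri(p, 60, seed = 7)$intervals)
  e1 <- generate_eeg(p, 10, fs = 250, seed = 7)
  e2 <- generate_eeg(p, 10, fs = 250, seed = 7)
  expect_identical(e1$samples, e2$samples)
  expect_false(identical(e1$samples,
                         generate_eeg(p, 10, fs = 250, seed = 8)$samples))
})

test_that("generator input validation catches bad arguments", {
  expect_error(state_profile(hr_mean = 250), "30, 220")
  expect_error(state_profile(lf_amp = 0.6), "0.5")
  expect_error(generate_rri(quiet_profile(), 10, seed = 1), ">= 30")
  expect_error(generate_eeg(quiet_profile(), 10, fs = 100, seed = 1), "fs")
  expect_error(generate_eeg(quiet_profile(), 2, fs = 500, seed = 1), ">= 10")
})

test_that("silent EEG profile produces an all-zero recording", {
  p <- state_profile(band_amps = c(delta = 0, theta = 0, alpha = 0,
                                   beta = 0, gamma = 0), noise_sd = 0)
  rec <- generate_eeg(p, 10, fs = 250, seed = 1)
  expect_true(all(rec$samples == 0))
})

test_that("EEG log-bandpower responds to amplitude as amplitude squared", {
  b1 <- absolute_bandpowers(compute_psd(
    generate_eeg(single_band_profile("theta", 5), 30, fs = 500, seed = 4)))
  b2 <- absolute_bandpowers(compute_psd(
    generate_eeg(single_band_profile("theta", 10), 30, fs = 500, seed = 4)))
  expect_equal(b2$frontal_log[["theta"]] - b1$frontal_log[["theta"]],
               log10(4), tolerance = 0.01)
})

test_that("EEG bandpower is monotone in band amplitude with low leakage", {
  bands <- eeg_bands()
  for (band in c("theta", "alpha", "beta")) {
    lo <- absolute_bandpowers(compute_psd(
      generate_eeg(single_band_profile(band, 4), 20, fs = 500, seed = 11)))
    hi <- absolute_bandpowers(compute_psd(
      generate_eeg(single_band_profile(band, 8), 20, fs = 500, seed = 11)))
    expect_gt(hi$linear[band, "Fp1"], lo$linear[band, "Fp1"])
    # generator confinement, judged by the full-length periodogram
    # oracle (resolution 0.05 Hz), not the 2-Hz Welch window: injected
    # power outside the band stays below 10% of the in-band power
    rec <- generate_eeg(single_band_profile(band, 8), 20, fs = 500, seed = 11)
    pg <- direct_periodogram(rec$samples[, "Fp1"], 500)
    b <- bands[bands$band == band, ]
    in_band <- sum(pg$psd[pg$freq >= b$lo & pg$freq < b$hi])
    out_band <- sum(pg$psd) - in_band
    expect_lt(out_band, 0.1 * in_band)
  }
})

test_that("cohort generator applies condition effects and respects bounds", {
  spec <- big_effect_spec(seed = 5, n = 2)
  cohort <- generate_cohort(spec, signals = "rri")
  expect_length(cohort$participants, 2)
  feats <- extract_cohort_features(cohort, spectral = FALSE)
  m <- feature_matrix(feats, "mean_hr")
  # strictly increasing profile means: every participant's HR rises from
  # baseline to hard
  expect_true(all(m[, "hard"] > m[, "baseline"]))
  expect_error(
    cohort_spec(condition_effects = condition_profiles()[c("baseline", "easy")]),
    "missing condition")
  expect_error(cohort_spec(n_participants = 1), ">= 2")
  expect_error(cohort_spec(block_duration = 30), ">= 60")
})

test_that("cohort generation is deterministic under its seed", {
  f1 <- extract_cohort_features(generate_cohort(big_effect_spec(seed = 9, n = 2),
                                                signals = "rri"),
                                spectral = FALSE)
  f2 <- extract_cohort_features(generate_cohort(big_effect_spec(seed = 9, n = 2),
                                                signals = "rri"),
                                spectral = FALSE)
  expect_identical(f1, f2)
})

test_that("plant converges to the difficulty setpoint without noise", {
  cfg <- difficulty_preset("medium")
  sp <- hr_setpoint(cfg)
  st <- plant_state(hr = 70)
  tau <- 20
  dt <- 1
  for (i in seq_len(10 * tau)) {
    st <- plant_step(st, cfg, dt, noise_sd = 0, theta_noise_sd = 0, tau = tau)
  }
  expect_lt(abs(st$hr - sp), 1e-3)
  # closed form of the iterated linear map after n steps
  n <- 37
  st2 <- plant_state(hr = 70)
  for (i in seq_len(n)) {
    st2 <- plant_step(st2, cfg, dt, noise_sd = 0, theta_noise_sd = 0, tau = tau)
  }
  analytic <- sp + (70 - sp) * (1 - dt / tau)^n
  expect_equal(st2$hr, analytic, tolerance = 1e-6)
})

test_that("harder configurations map to higher HR setpoints", {
  easy <- difficulty_preset("easy")
  hard <- difficulty_preset("hard")
  harder_still <- difficulty_config(n_targets = 20, target_size = 0.5,
                                    target_speed = 3, daylight = 2, rain = 0.8)
  expect_lte(hr_setpoint(easy), hr_setpoint(hard))
  expect_lte(hr_setpoint(hard), hr_setpoint(harder_still))
  # theta runs the opposite way
  expect_gte(theta_setpoint(easy), theta_setpoint(hard))
  expect_error(difficulty_config(target_speed = 6), "range")
  expect_error(plant_step(plant_state(), easy, dt = 0), "positive")
})
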