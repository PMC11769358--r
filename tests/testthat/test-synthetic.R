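# Synthetic cohort generator: template morphology against the closed-form
# envelope, forward-model identities, determinism, label balance, SNR
# bookkeeping and the scalp-visibility detector.

test_that("IED template peaks at the onset sample and scales with amplitude", {
  tm <- ied_template(spike_amplitude = 8)
  w <- render_ied_template(tm, L = 64, rate = 200, onset = 32)
  expect_length(w, 64)
  expect_lte(abs(which.max(abs(w)) - 32), 1)
  expect_equal(w[32], 8)
  z <- render_ied_template(ied_template(spike_amplitude = 0), 64, 200, 32)
  expect_identical(z, rep(0, 64))
  expect_error(render_ied_template(ied_template(spike_width = 0.2), 64, 200, 32),
               "wider than segment")
})

test_that("post-spike oscillation decays with the configured time constant", {
  tau <- 0.08
  amp <- 8
  freq <- 8
  tm <- ied_template(spike_amplitude = amp, oscillation_frequency = freq,
                     oscillation_decay = tau, spike_width = 0.05)
  rate <- 1000 # fine sampling so oscillation extrema are well resolved
  L <- 2048
  onset <- 128
  w <- render_ied_template(tm, L, rate, onset)
  t <- (seq_len(L) - onset) / rate
  # closed-form envelope of the damped sinusoid: 0.4 * amp * exp(-t / tau);
  # at extrema t_k = (k + 1/4)/freq the waveform reaches the envelope
  for (k in 0:3) {
    tk <- (k + 0.25) / freq
    if (tk <= 2 * tm$spike_width) next # spike support
    idx <- which.min(abs(t - tk))
    expect_equal(abs(w[idx]), 0.4 * amp * exp(-tk / tau), tolerance = 0.03)
  }
  # beyond the spike support the waveform never exceeds the envelope
  far <- t > 3 * tm$spike_width
  expect_true(all(abs(w[far]) <= 0.4 * amp * exp(-t[far] / tau) + 1e-9))
})

test_that("identity forward model reproduces the intracranial signal at the scalp", {
  cfg <- simulation_config(n_subjects = 1, segments_per_subject = 20, M = 12,
                           target_visible_fraction = NULL)
  fwd <- forward_model(diag(12), nonlinearity = "identity", noise_sd = 0,
                       attenuation = 1)
  rec <- simulate_subject(cfg, fwd, subject_seed = 3)
  for (k in c(1, 10, 20)) {
    expect_equal(rec$segments[[k]]$scalp$samples,
                 rec$segments[[k]]$intracranial$samples)
  }
})

test_that("linear forward model equals the brute-force matrix product", {
  cfg <- simulation_config(n_subjects = 1, segments_per_subject = 10,
                           target_visible_fraction = NULL)
  W <- default_mixing(20, 12)
  fwd <- forward_model(W, nonlinearity = "identity", noise_sd = 0,
                       attenuation = 0.6)
  rec <- simulate_subject(cfg, fwd, subject_seed = 4)
  comp <- attr(rec, "components")
  for (k in c(1, 6)) {
    y <- rec$segments[[k]]$intracranial$samples * comp$intracranial_scale
    x <- rec$segments[[k]]$scalp$samples * comp$scalp_scale
    expect_equal(x, 0.6 * (y %*% t(W)), tolerance = 1e-12)
  }
})

test_that("cohorts are a pure function of the seed, with exact label balance", {
  cfg <- simulation_config(n_subjects = 2, segments_per_subject = 30,
                           target_visible_fraction = NULL, seed = 17)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$subjects[[2]]$segments[[7]]$scalp$samples,
                   b$subjects[[2]]$segments[[7]]$scalp$samples)
  labs <- vapply(a$subjects[[1]]$segments, function(s) s$label, "")
  expect_identical(sum(labs == "IED"), 15L)
})

test_that("realized scalp SNR matches the configured value within 0.5 dB", {
  cfg <- simulation_config(n_subjects = 1, segments_per_subject = 60,
                           target_visible_fraction = NULL, snr_db = 6)
  rec <- simulate_subject(cfg, forward_model(default_mixing(20, 12)),
                          subject_seed = 8)
  comp <- attr(rec, "components")
  snr <- 10 * log10(mean(comp$signal^2) / mean(comp$noise^2))
  expect_lt(abs(snr - 6), 0.5)
})

test_that("visibility detector saturates at the extremes", {
  # spikes far above background, no noise: every IED visible
  cfg <- simulation_config(n_subjects = 1, segments_per_subject = 40, M = 12,
                           target_visible_fraction = NULL)
  strong <- list(ied_template(spike_amplitude = 15))
  fwd1 <- forward_model(diag(12), nonlinearity = "identity", noise_sd = 0,
                        attenuation = 1)
  rec1 <- simulate_subject(cfg, fwd1, strong, subject_seed = 9)
  expect_equal(measure_visible_fraction(rec1), 1)
  # spike transmission suppressed: (almost) nothing visible; the detector's
  # false-alarm rate on pure background bounds the residual
  cfg2 <- simulation_config(n_subjects = 1, segments_per_subject = 100,
                            target_visible_fraction = NULL, snr_db = 6)
  fwd0 <- forward_model(default_mixing(20, 12), noise_sd = 0.1,
                        attenuation = 1, spike_leakage = 1e-3)
  rec0 <- simulate_subject(cfg2, fwd0, subject_seed = 10)
  expect_lte(measure_visible_fraction(rec0), 0.04)
  expect_error(measure_visible_fraction(
    subject_record("X", list())), "no IED segments")
})

test_that("zero scalp signal power is rejected as an undefined SNR", {
  cfg <- simulation_config(n_subjects = 1, segments_per_subject = 4,
                           target_visible_fraction = NULL)
  fwd <- forward_model(matrix(0, 20, 12), nonlinearity = "identity",
                       noise_sd = 0.1)
  expect_error(simulate_subject(cfg, fwd, subject_seed = 2), "signal power")
})

test_that("continuous simulation feeds segmentation consistently", {
  cfgsim <- simulation_config(n_subjects = 1, target_visible_fraction = NULL)
  cont <- simulate_continuous(duration_s = 30, cfgsim, n_ieds = 8, seed = 12)
  expect_identical(ncol(cont$scalp), 20L)
  expect_identical(ncol(cont$intracranial), 12L)
  expect_true(all(diff(cont$onsets) >= 64))
  pre <- preprocess_recording(cont)
  segs <- extract_segments(pre, cont$onsets, subject_id = "S1", seed = 1)
  expect_length(segs, 2 * length(cont$onsets))
})
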