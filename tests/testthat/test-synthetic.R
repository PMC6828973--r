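test_that("generation is reproducible: same seed gives identical signals", {
  cfg <- test_synth_config(c(control = 1, lbp_frp = 0, lbp_no_frp = 0), seed = 9)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$trials[[1]]$signals, b$trials[[1]]$signals)
  expect_identical(a$trials[[1]]$angle, b$trials[[1]]$angle)
  expect_identical(a$truth$subjects, b$truth$subjects)
})

test_that("angle trace is continuous, rests at zero and peaks in full flexion", {
  coh <- small_cohort()
  cfg <- coh$config
  fs <- cfg$sampling_rate
  for (tr in coh$trials[1:2]) {
    a <- tr$angle
    expect_lt(max(abs(diff(a))), 1)  # no jumps at this sampling rate
    expect_lt(abs(mean(a[1:(fs / 2)])), 0.1)
    # settles back to neutral right at the end of the return movement
    expect_lt(abs(mean(a[(length(a) - round(fs / 50)):length(a)])), 0.5)
    mvf_idx <- round((cfg$baseline_duration + cfg$phase_durations[["flexion"]]) * fs):
      round((cfg$baseline_duration + sum(cfg$phase_durations[1:2])) * fs)
    expect_true(which.max(frpmap:::.moving_avg(a, 21)) %in% mvf_idx)
  }
})

test_that("active-window RMS of clean channels matches the configured amplitude", {
  coh <- small_cohort()
  cfg <- coh$config
  fs <- cfg$sampling_rate
  tr <- coh$trials[[1]]  # control subject
  # 1-s window early in flexion (all channels still active)
  w <- (round((cfg$baseline_duration + 0.2) * fs)):(round((cfg$baseline_duration + 1.2) * fs))
  r <- frpmap:::rms(tr$signals[w, ])
  expect_true(all(abs(r - cfg$envelope_amplitude) / cfg$envelope_amplitude < 0.15))
})

test_that("carrier spectrum stays inside the configured noise band", {
  coh <- small_cohort()
  fs <- coh$config$sampling_rate
  x <- coh$trials[[1]]$signals[, 1:4]
  sp <- Mod(mvfft(sweep(x, 2, colMeans(x))))^2
  f <- (seq_len(nrow(x)) - 1) / nrow(x) * fs
  half <- f > 0 & f <= fs / 2
  inband <- half & f >= test_band[1] & f <= test_band[2]
  expect_true(all(colSums(sp[inband, ]) / colSums(sp[half, ]) > 0.9))
})

test_that("control subjects carry FRP truth on every channel, no-FRP none", {
  coh <- small_cohort()
  tru <- coh$truth
  controls <- tru$subjects$subject[tru$subjects$group == "control"]
  for (s in controls) {
    per_trial <- subset(tru$onsets, subject == s & repetition == 1)
    expect_equal(nrow(per_trial), 59L)
    expect_true(all(is.finite(per_trial$true_onset_pct)))
  }
  nofrp <- tru$subjects$subject[tru$subjects$group == "lbp_no_frp"]
  expect_false(any(tru$onsets$subject %in% nofrp))
})

test_that("degenerate dispersion yields identical true onsets on all channels", {
  cfg <- test_synth_config(c(control = 1, lbp_frp = 1, lbp_no_frp = 0), seed = 2,
                           onset_between_subject_sd = 1e-9,
                           onset_spatial_gradient = c(control = 0, lbp_frp = 0),
                           onset_channel_jitter_sd = 0)
  coh <- generate_cohort(cfg)
  for (s in unique(coh$truth$onsets$subject)) {
    p <- subset(coh$truth$onsets, subject == s)$true_onset_pct
    expect_lt(diff(range(p)), 1e-6)
  }
})

test_that("fault injection follows the floor count rule and is recorded", {
  coh <- small_cohort()
  expect_identical(inject_channel_faults(coh, 0)$trials[[1]]$signals,
                   coh$trials[[1]]$signals)
  cohF <- inject_channel_faults(coh, 0.1, seed = 3)
  per_trial <- table(cohF$truth$faults$trial)
  expect_true(all(per_trial == floor(0.1 * 64)))  # 6 electrodes per grid
  expect_true(all(cohF$truth$fault_channels$channel %in% 1:59))
})

test_that("near-zero faulted electrodes have tiny envelope-band RMS", {
  coh <- small_cohort()
  cohF <- inject_channel_faults(coh, 0.15, seed = 4)
  fz <- subset(cohF$truth$faults, fault_type == "near_zero")
  expect_gt(nrow(fz), 0)
  k <- fz$trial[1]
  sig <- cohF$trials[[k]]$signals
  fs <- cohF$config$sampling_rate
  band_rms <- frpmap:::rms(zero_phase_butter(sig, fs, test_band, type = "pass"))
  bad_k <- subset(cohF$truth$faults, trial == k)
  clean <- setdiff(seq_len(ncol(sig)), bad_k$electrode)
  expect_true(all(band_rms[bad_k$electrode[bad_k$fault_type == "near_zero"]] <
                    0.1 * median(band_rms[clean])))
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(n_per_group = c(control = 0, lbp_frp = 0,
                                                lbp_no_frp = 0)), "positive")
  expect_error(synthetic_config(baseline_duration = -1), "positive")
  expect_error(synthetic_config(true_onset_mean = c(control = 120, lbp_frp = 68)),
               "0, 100")
  expect_error(synthetic_config(sampling_rate = 512), "Nyquist")
})
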