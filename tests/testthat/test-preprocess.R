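make_flat_trial <- function(signals, fs = test_fs) {
  n <- nrow(signals)
  angle <- numeric(n)  # angle irrelevant for derivation tests
  monopolar_trial(signals, fs, angle, grid_layout())
}

test_that("bipolar derivation yields 59 channels and rejects common mode", {
  set.seed(1)
  fs <- test_fs
  n <- 4 * fs
  common <- frpmap:::band_limited_noise(n, 1L, fs, test_band)
  tr <- make_flat_trial(matrix(common, n, 64))
  bip <- derive_bipolar(tr, band = test_band)
  expect_equal(ncol(bip$signals), 59L)
  expect_lt(max(abs(bip$signals)), 1e-9 * sd(common))
})

test_that("opposite-sign adjacent electrodes give twice the filtered signal", {
  set.seed(2)
  fs <- test_fs
  n <- 4 * fs
  s <- frpmap:::band_limited_noise(n, 1L, fs, test_band)
  sig <- matrix(0, n, 64)
  ch <- enumerate_bipolar_channels(grid_layout())
  pick <- ch[ch$channel == 7, ]
  sig[, pick$elec_caudal] <- s
  sig[, pick$elec_cranial] <- -s
  bip <- derive_bipolar(make_flat_trial(sig), band = test_band)
  # oracle: apply the same filter to 2s directly
  ref <- zero_phase_butter(2 * as.vector(s), fs, test_band, type = "pass")
  expect_lt(max(abs(bip$signals[, 7] - ref)), 1e-8 * sd(ref))
})

test_that("bipolar output order matches the channel enumeration", {
  coh <- small_cohort()
  tr <- coh$trials[[1]]
  bip <- derive_bipolar(tr, band = test_band)
  ch <- enumerate_bipolar_channels(tr$layout)
  expect_equal(bip$channels, ch)
  # spot-check: channel k is the filtered caudal-minus-cranial difference
  for (k in c(1, 25, 59)) {
    ref <- zero_phase_butter(
      tr$signals[, ch$elec_caudal[k]] - tr$signals[, ch$elec_cranial[k]],
      tr$sampling_rate, test_band, type = "pass")
    expect_lt(max(abs(bip$signals[, k] - ref)), 1e-8 * max(1e-12, sd(ref)))
  }
})

test_that("too-short trials and mismatched channel counts are rejected", {
  fs <- test_fs
  expect_error(derive_bipolar(make_flat_trial(matrix(0, fs / 2, 64))), "short")
  expect_error(monopolar_trial(matrix(0, fs, 60), fs, numeric(fs)), "expected 64")
  expect_error(monopolar_trial(matrix(0, fs, 64), fs, numeric(10)), "same number")
})

test_that("rectified envelope of a pure tone approaches its rectified mean", {
  fs <- test_fs
  n <- 4 * fs
  t <- (seq_len(n) - 1) / fs
  A <- 3
  ch <- enumerate_bipolar_channels(grid_layout())
  sig <- matrix(0, n, 64)
  sig[, ch$elec_caudal[1]] <- A * sin(2 * pi * 150 * t)
  bip <- derive_bipolar(make_flat_trial(sig), band = test_band)
  env <- emg_envelope(bip)
  mid <- (fs):(n - fs)
  expect_equal(mean(env$envelopes[mid, 1]), 2 * A / pi, tolerance = 0.02)
  expect_true(all(env$envelopes >= 0))
  # zero signal -> zero envelope
  expect_equal(max(env$envelopes[, 30]), 0)
})

test_that("a sigmoid deactivation's envelope midpoint lands on time", {
  # no channel jitter or gradient: both electrodes of every pair share one
  # onset, so the bipolar envelope carries a single clean sigmoid drop
  cfg <- test_synth_config(c(control = 1, lbp_frp = 0, lbp_no_frp = 0), seed = 21,
                           onset_channel_jitter_sd = 0,
                           onset_spatial_gradient = c(control = 0, lbp_frp = 0))
  coh <- generate_cohort(cfg)
  tr <- coh$trials[[1]]
  fs <- cfg$sampling_rate
  seg <- segment_phases(tr$angle, fs)
  env <- emg_envelope(derive_bipolar(tr, band = test_band))
  tru <- coh$truth$onsets
  for (chan in c(5, 30)) {
    p <- tru$true_onset_pct[tru$channel == chan]
    # map the true onset percent to time: first sample at which the angle
    # reaches that fraction of the maximal flexion angle
    t_on <- (which(tr$angle - seg$angle_offset >=
                     p / 100 * seg$max_flexion_angle)[1] - 1) / fs
    # smooth the envelope further (zero-phase moving average) so stochastic
    # dips of the EMG amplitude do not trip the crossing search
    e <- frpmap:::.moving_avg(env$envelopes[, chan], round(0.1 * fs))
    act <- median(e[(seg$flexion[1] + fs / 2):(seg$flexion[1] + fs)])
    rel <- median(e[seg$mvf[1]:(seg$mvf[1] + fs)])
    below <- frpmap:::.run_length_forward(e < (act + rel) / 2)
    from <- seg$flexion[1] + fs / 2
    cross <- (which(below >= round(0.05 * fs) &
                      seq_along(e) > from)[1] - 1) / fs
    expect_lt(abs(cross - (t_on - cfg$transition_s / 2)), 0.03)
  }
})

test_that("quality screening flags faulted channels and spares clean ones", {
  tp <- 0; ntrue <- 0; fp <- 0; nclean <- 0
  for (seed in 1:6) {
    coh <- generate_cohort(test_synth_config(
      c(control = 1, lbp_frp = 1, lbp_no_frp = 1), seed = 100 + seed))
    cohF <- inject_channel_faults(coh, 0.1, seed = seed)
    for (k in seq_along(cohF$trials)) {
      tr <- cohF$trials[[k]]
      seg <- segment_phases(tr$angle, tr$sampling_rate)
      bip <- quality_screen(derive_bipolar(tr, band = test_band), seg)
      truth_ch <- subset(cohF$truth$fault_channels, trial == k)$channel
      flg <- bip$excluded$channel
      tp <- tp + sum(truth_ch %in% flg); ntrue <- ntrue + length(truth_ch)
      clean <- setdiff(bip$channels$channel, truth_ch)
      fp <- fp + sum(clean %in% flg); nclean <- nclean + length(clean)
    }
  }
  expect_gte(tp / ntrue, 0.9)
  expect_lte(fp / nclean, 0.05)
})

test_that("clean trials pass screening untouched; dead channels are low_snr", {
  res <- small_processed()
  expect_equal(nrow(res$bipolar$excluded), 0L)
  # kill one bipolar channel entirely (both electrodes flat)
  coh <- small_cohort()
  tr <- coh$trials[[1]]
  ch <- enumerate_bipolar_channels(grid_layout())
  tr$signals[, c(ch$elec_caudal[10], ch$elec_cranial[10])] <- 0
  seg <- segment_phases(tr$angle, tr$sampling_rate)
  bip <- quality_screen(derive_bipolar(tr, band = test_band), seg)
  expect_true(10 %in% bip$excluded$channel)
  expect_match(bip$excluded$reason[bip$excluded$channel == 10], "low_snr")
})
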