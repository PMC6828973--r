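test_that("baseline statistics summarise the quiet-standing window", {
  fs <- 100
  stub <- stub_env(matrix(2.5, 6 * fs, 3), fs)
  bs <- baseline_stats(stub$env, stub$seg, 1)
  expect_equal(bs$mean, 2.5)
  expect_equal(bs$sd, 0)
  # alternating a, b
  e <- matrix(rep(c(1, 3), length.out = 6 * fs), 6 * fs, 1)
  stub2 <- stub_env(e, fs)
  expect_equal(baseline_stats(stub2$env, stub2$seg, 1)$mean, 2)
  # too-short window errors
  seg_short <- stub$seg
  seg_short$baseline <- c(1L, 10L)
  expect_error(baseline_stats(stub$env, seg_short, 1), "0.25")
})

test_that("a constructed step offset is detected at the step", {
  fs <- 100
  n <- 6 * fs
  e <- matrix(10, n, 1)
  # baseline level 1 with sd ~0.1; drop to 0 at mid-flexion (t = 2 s in phase)
  set.seed(1)
  e[1:(1 * fs), 1] <- 1 + 0.1 * sin(seq_len(fs))
  step_at <- 2 * fs + 1L  # half-way through the 2 s flexion phase
  e[step_at:n, 1] <- 0
  stub <- stub_env(e, fs)
  det <- detect_channel_offset(stub$env, stub$seg, 1,
                               det_config(axis = "time"))
  expect_true(det$present)
  expect_equal(det$onset_sample, step_at)
  expect_equal(det$onset_pct, 50, tolerance = 1)
  expect_false(det$never_active)
  # never drops -> absent
  e2 <- e; e2[, 1] <- 10; e2[1:fs, 1] <- e[1:fs, 1]
  stub2 <- stub_env(e2, fs)
  det2 <- detect_channel_offset(stub2$env, stub2$seg, 1, det_config())
  expect_false(det2$present)
  expect_true(is.na(det2$onset_sample))
})

test_that("an always-quiescent channel is flagged never_active at 0%", {
  fs <- 100
  # baseline 0.5 with a small ripple (so SD > 0), then strictly lower from
  # flexion onward: below threshold for the entire flexion phase
  e <- matrix(0.4, 6 * fs, 1)
  e[1:fs, 1] <- 0.5 + 0.01 * sin(seq_len(fs) / 3)
  stub <- stub_env(e, fs)
  det <- detect_channel_offset(stub$env, stub$seg, 1, det_config())
  expect_true(det$present)
  expect_true(det$never_active)
  expect_equal(det$onset_sample, stub$seg$flexion[1])
  expect_lt(det$onset_pct, 1)
})

test_that("detection matches the brute-force scan on random envelopes", {
  # randomly wandering envelopes around the threshold exercise the hold rule
  set.seed(33)
  fs <- 100
  n <- 6 * fs
  cfg <- det_config()
  hold <- round(cfg$hold_s * fs)
  for (rep_i in 1:60) {
    e <- matrix(pmax(0, 1 + cumsum(rnorm(n, 0, 0.2))), n, 1)
    stub <- stub_env(e, fs)
    bs <- baseline_stats(stub$env, stub$seg, 1)
    thr <- bs$mean + cfg$k * bs$sd
    oracle <- brute_force_offset(e[, 1], thr, stub$seg$flexion[1],
                                 stub$seg$flexion[2], hold)
    det <- detect_channel_offset(stub$env, stub$seg, 1, cfg)
    if (is.na(oracle)) {
      expect_false(det$present)
    } else {
      expect_equal(det$onset_sample, oracle)
    }
  }
})

test_that("raising the threshold multiplier never delays the onset", {
  coh <- small_cohort()
  res <- small_processed()
  for (chan in seq(1, 59, by = 7)) {
    d3 <- detect_channel_offset(res$envelope, res$seg, chan, det_config(k = 3))
    d4 <- detect_channel_offset(res$envelope, res$seg, chan, det_config(k = 4))
    if (d3$present && d4$present)
      expect_lte(d4$onset_sample, d3$onset_sample)
  }
})

test_that("the >50% presence rule is strict at its boundary", {
  fs <- 100
  n <- 6 * fs
  make_map <- function(n_relax, n_total = 59, n_excluded = 0) {
    e <- matrix(10, n, n_total)
    set.seed(4)
    e[1:fs, ] <- 1 + matrix(0.05 * rnorm(fs * n_total), fs)
    if (n_relax > 0) e[(3 * fs):n, seq_len(n_relax)] <- 0  # drop in flexion
    excl <- if (n_excluded > 0) n_total - seq_len(n_excluded) + 1L else NULL
    stub <- stub_env(e, fs, excluded = excl)
    build_onset_map(stub$env, stub$seg)
  }
  expect_true(make_map(30)$frp_present)    # 30/59 > 0.5
  expect_false(make_map(29)$frp_present)   # 29/59 < 0.5
  # exactly 0.5: 29 of 58 usable channels (one excluded) -> absent
  m <- make_map(29, n_excluded = 1)
  expect_equal(m$fraction_channels_with_frp, 0.5)
  expect_false(m$frp_present)
  # QC-excluded channels leave the denominator
  expect_equal(sum(!m$channels$excluded), 58L)
})

test_that("onset maps of synthetic subjects follow their group", {
  res <- small_processed()  # control subject
  expect_true(res$map$frp_present)
  expect_equal(res$map$fraction_channels_with_frp, 1.0)
  coh <- small_cohort()
  nofrp_idx <- which(vapply(coh$trials, function(tr)
    tr$meta$group == "lbp_no_frp", logical(1)))[1]
  res2 <- analyze_trial(coh$trials[[nofrp_idx]], test_pipeline_config())
  expect_false(res2$map$frp_present)
})

test_that("repetition aggregation averages onsets with majority presence", {
  res <- small_processed()
  m <- res$map
  agg1 <- aggregate_repetitions(list(m, m, m))
  expect_equal(agg1$channels$onset_pct, m$channels$onset_pct)
  expect_equal(agg1$frp_present, m$frp_present)
  # constructed three-repetition channel: 40, 50, 60 -> 50
  m1 <- m; m2 <- m; m3 <- m
  m1$channels$onset_pct[1] <- 40
  m2$channels$onset_pct[1] <- 50
  m3$channels$onset_pct[1] <- 60
  agg2 <- aggregate_repetitions(list(m1, m2, m3))
  expect_equal(agg2$channels$onset_pct[1], 50)
  # one absent, two present at 45/55 -> present at 50
  m1$channels$present[2] <- FALSE; m1$channels$onset_pct[2] <- NA
  m2$channels$onset_pct[2] <- 45
  m3$channels$onset_pct[2] <- 55
  agg3 <- aggregate_repetitions(list(m1, m2, m3))
  expect_true(agg3$channels$present[2])
  expect_equal(agg3$channels$onset_pct[2], 50)
})

test_that("side pooling averages subjects and runs the paired check", {
  d <- data.frame(subject = rep(sprintf("S%d", 1:5), each = 2),
                  group = "control",
                  side = rep(c("R", "L"), 5),
                  mean_onset_pct = c(50, 52, 55, 54, 60, 61, 45, 44, 58, 57))
  pooled <- pool_sides(d, "mean_onset_pct")
  expect_equal(nrow(pooled), 5L)
  expect_equal(pooled$mean_onset_pct[pooled$subject == "S1"], 51)
  # systematic side shift triggers the warning but still pools
  d2 <- d; d2$mean_onset_pct[d2$side == "L"] <- d2$mean_onset_pct[d2$side == "R"] + 5
  expect_warning(p2 <- pool_sides(d2, "mean_onset_pct"), "side difference")
  expect_equal(nrow(p2), 5L)
})
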