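# Shared fixtures for the test suite. Simulations run at a reduced sampling
# rate (512 Hz, carrier band 20-220 Hz) so the whole suite stays fast; the
# processing chain is sampling-rate agnostic.

.fix_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fix_cache)) assign(name, expr, envir = .fix_cache)
  get(name, envir = .fix_cache)
}

test_fs <- 512
test_band <- c(20, 220)

test_synth_config <- function(n_per_group, seed = 1L, ...) {
  synthetic_config(n_per_group = n_per_group, sampling_rate = test_fs,
                   noise_band = test_band, n_repetitions = 1, sides = "R",
                   seed = seed, ...)
}

test_pipeline_config <- function(...) {
  pipeline_config(filter_band = test_band, ...)
}

# one small mixed cohort reused across files
small_cohort <- function() {
  cached("small_cohort", generate_cohort(
    test_synth_config(c(control = 2, lbp_frp = 2, lbp_no_frp = 1), seed = 5)))
}

# a processed trial of the small cohort (control subject)
small_processed <- function() {
  cached("small_processed", {
    coh <- small_cohort()
    analyze_trial(coh$trials[[1]], test_pipeline_config())
  })
}

# hand-built segmentation covering an envelope stub laid out as:
# 1 s baseline | 2 s flexion | 2 s mvf | 1 s extension  (fs samples/s)
stub_seg <- function(fs = 100, max_angle = 90) {
  structure(list(
    baseline = c(1L, 1L * fs + 1L),
    flexion = c(1L * fs + 1L, 3L * fs + 1L),
    mvf = c(3L * fs + 1L, 5L * fs + 1L),
    extension = c(5L * fs + 1L, 6L * fs + 1L),
    max_flexion_angle = max_angle,
    flexion_duration = 2,
    angle_offset = 0,
    sampling_rate = fs), class = "phase_segmentation")
}

# envelope stub: angle ramps linearly 0 -> max over the flexion interval
stub_env <- function(env_mat, fs = 100, max_angle = 90,
                     channels = NULL, excluded = NULL) {
  n <- nrow(env_mat)
  seg <- stub_seg(fs, max_angle)
  angle <- numeric(n)
  f1 <- seg$flexion[1]; f2 <- seg$flexion[2]
  angle[f1:(f2 - 1L)] <- seq(0, max_angle, length.out = f2 - f1)
  angle[f2:n] <- max_angle
  if (is.null(channels)) {
    ch <- enumerate_bipolar_channels(grid_layout())[seq_len(ncol(env_mat)), ]
    ch$channel <- seq_len(ncol(env_mat))
  } else ch <- channels
  env <- structure(list(
    envelopes = env_mat, channels = ch,
    excluded = if (is.null(excluded))
      data.frame(channel = integer(0), reason = character(0))
    else data.frame(channel = excluded, reason = "low_snr"),
    sampling_rate = fs, angle = angle, layout = grid_layout(),
    meta = list()), class = "envelope_trial")
  list(env = env, seg = seg)
}

# independent brute-force EMG-offset oracle: sliding-window sum formulation
# (the implementation uses run-length encoding)
brute_force_offset <- function(e, thr, f1, f2, hold) {
  below <- as.integer(e < thr)
  cs <- c(0, cumsum(below))
  for (i in f1:(f2 - 1L)) {
    if (i + hold - 1L > length(e)) break
    if (cs[i + hold] - cs[i] == hold) return(i)
  }
  NA_integer_
}
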