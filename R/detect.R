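#' Detection configuration for the FRP onset (EMG offset)
#'
#' @param k Threshold multiplier: the offset threshold is
#'   `baseline mean + k * baseline SD` (default 3).
#' @param hold_s Seconds the envelope must stay below threshold continuously
#'   for a crossing to count as the offset (debounce against transient dips).
#' @param axis How the onset is expressed as percent of trunk flexion:
#'   `"angle"` (percent of maximal flexion angle, the default) or `"time"`
#'   (percent of elapsed flexion-phase time).
#' @param baseline_s Seconds of the quiet-standing window used for baseline
#'   statistics (taken from the end of the segmentation's baseline window).
#' @return A list of class `det_config`.
#' @export
det_config <- function(k = 3, hold_s = 0.25, axis = c("angle", "time"),
                       baseline_s = 1) {
  axis <- match.arg(axis)
  structure(list(k = k, hold_s = hold_s, axis = axis, baseline_s = baseline_s),
            class = "det_config")
}

#' Baseline envelope statistics during quiet standing
#'
#' @param env An `envelope_trial` from [emg_envelope()].
#' @param seg A [segment_phases()] result.
#' @param channel Bipolar channel index.
#' @param window_s Window length (s), taken from the end of the baseline
#'   interval; must be at least 0.25 s.
#' @return A list with `mean`, `sd` and the sample `window` used.
#' @export
baseline_stats <- function(env, seg, channel, window_s = 1) {
  stopifnot(inherits(env, "envelope_trial"), inherits(seg, "phase_segmentation"))
  fs <- env$sampling_rate
  b <- seg$baseline
  w0 <- max(b[1], b[2] - round(window_s * fs))
  if ((b[2] - w0) < 0.25 * fs)
    stop("baseline window shorter than 0.25 s: SD estimate unstable")
  idx <- w0:(b[2] - 1L)
  x <- env$envelopes[idx, channel]
  list(mean = mean(x), sd = sd(x), window = c(w0, b[2]))
}

# forward run length of TRUE values at each position
.run_length_forward <- function(x) {
  r <- rle(x)
  unlist(lapply(seq_along(r$lengths), function(i) {
    if (r$values[i]) rev(seq_len(r$lengths[i])) else rep(0L, r$lengths[i])
  }), use.names = FALSE)
}

#' Detect the per-channel FRP onset (EMG offset)
#'
#' The FRP onset is the first sample within the trunk-flexion phase at which
#' the amplitude envelope falls below the threshold `mean + k * SD` of
#' quiet-standing baseline activity and remains below it for at least
#' `hold_s` continuously (the hold window may extend into the full-flexion
#' phase). Later re-activation does not retract a detection. If the envelope
#' never satisfies the rule within the flexion phase the FRP is absent on
#' that channel.
#'
#' @param env An `envelope_trial`.
#' @param seg A [segment_phases()] result.
#' @param channel Bipolar channel index.
#' @param config A [det_config()].
#' @return A list with `present`, `onset_sample` (NA when absent),
#'   `onset_pct` (percent of trunk flexion on the configured axis),
#'   `threshold`, and `never_active` (TRUE when the envelope lay below
#'   threshold throughout flexion, i.e. the channel was already quiescent).
#' @export
detect_channel_offset <- function(env, seg, channel, config = det_config()) {
  stopifnot(inherits(env, "envelope_trial"))
  fs <- env$sampling_rate
  bs <- baseline_stats(env, seg, channel, window_s = config$baseline_s)
  if (!is.finite(bs$sd)) stop("baseline SD undefined")
  thr <- bs$mean + config$k * bs$sd
  f1 <- seg$flexion[1]; f2 <- seg$flexion[2]
  hold <- max(1L, round(config$hold_s * fs))

  e <- env$envelopes[, channel]
  below <- e < thr
  runs <- .run_length_forward(below[f1:length(e)])
  flex_len <- f2 - f1
  ok <- which(runs[seq_len(flex_len)] >= hold)
  if (!length(ok)) {
    return(list(present = FALSE, onset_sample = NA_integer_,
                onset_pct = NA_real_, threshold = thr, never_active = FALSE))
  }
  onset <- f1 + ok[1] - 1L
  never_active <- all(below[f1:(f2 - 1L)])
  pct <- if (config$axis == "angle") {
    angle_to_flexion_pct(env$angle[onset] - seg$angle_offset, seg)
  } else {
    100 * (onset - f1) / flex_len
  }
  list(present = TRUE, onset_sample = onset, onset_pct = pct,
       threshold = thr, never_active = never_active)
}

#' Build the topographic FRP onset map of one trial
#'
#' Runs [detect_channel_offset()] on every channel that passed quality
#' control, computes the fraction of channels exhibiting the FRP, and applies
#' the presence rule: the FRP is present at the subject/side level when the
#' EMG offset is observed during trunk flexion in strictly more than 50% of
#' the (non-excluded) channels. Channels without an FRP are marked absent
#' and carry no onset value; QC-excluded channels do not enter the
#' denominator.
#'
#' @param env An `envelope_trial`.
#' @param seg A [segment_phases()] result.
#' @param config A [det_config()].
#' @return An object of class `onset_map`: a `channels` data.frame (lattice
#'   position, anatomical position, `excluded`, `present`, `onset_sample`,
#'   `onset_pct`, `never_active`), `fraction_channels_with_frp`,
#'   `frp_present`, `mean_onset_pct`, the onset `axis` and the trial `meta`.
#' @export
build_onset_map <- function(env, seg, config = det_config()) {
  ch <- env$channels
  n_ch <- nrow(ch)
  excluded <- ch$channel %in% env$excluded$channel
  if (sum(!excluded) < n_ch / 2)
    stop("fewer than 50% of channels passed quality control: map unusable")
  present <- rep(NA, n_ch); onset_sample <- rep(NA_integer_, n_ch)
  onset_pct <- rep(NA_real_, n_ch); never_active <- rep(NA, n_ch)
  for (i in which(!excluded)) {
    d <- detect_channel_offset(env, seg, ch$channel[i], config)
    present[i] <- d$present
    onset_sample[i] <- d$onset_sample
    onset_pct[i] <- d$onset_pct
    never_active[i] <- d$never_active
  }
  frac <- mean(present[!excluded])
  map <- data.frame(ch[, c("channel", "lat_row", "lat_col", "x_mm", "y_mm")],
                    excluded = excluded, present = present,
                    onset_sample = onset_sample, onset_pct = onset_pct,
                    never_active = never_active)
  structure(list(channels = map,
                 fraction_channels_with_frp = frac,
                 frp_present = frac > 0.5,
                 mean_onset_pct = if (any(present[!excluded]))
                   mean(onset_pct[!excluded & present]) else NA_real_,
                 axis = config$axis, meta = env$meta),
            class = "onset_map")
}

#' @export
print.onset_map <- function(x, ...) {
  cat(sprintf("FRP onset map: FRP %s (%.0f%% of channels), mean onset %.1f%% (%s axis)\n",
              if (x$frp_present) "present" else "absent",
              100 * x$fraction_channels_with_frp,
              x$mean_onset_pct, x$axis))
  invisible(x)
}

#' Average onset maps (and amplitude profiles) across repetitions
#'
#' Produces a single representative value per subject and side: channel-wise
#' presence by majority across repetitions (ties count as present), onset
#' percent averaged over the repetitions in which the channel showed the
#' FRP, and amplitude epochs averaged element-wise. The presence rule is
#' then re-applied to the aggregated channel map.
#'
#' @param maps List of `onset_map` objects (one per repetition).
#' @param profiles Optional list of [normalize_profile()] results to average
#'   element-wise alongside.
#' @return An `onset_map` (with `n_repetitions`), plus an
#'   `amplitude_profile` element when `profiles` is supplied.
#' @export
aggregate_repetitions <- function(maps, profiles = NULL) {
  stopifnot(length(maps) >= 1)
  chs <- lapply(maps, function(m) m$channels)
  base <- chs[[1]]
  n_ch <- nrow(base)
  pres_mat <- sapply(chs, function(d) d$present)
  pct_mat <- sapply(chs, function(d) d$onset_pct)
  excl_mat <- sapply(chs, function(d) d$excluded)
  pres_mat <- matrix(pres_mat, n_ch); pct_mat <- matrix(pct_mat, n_ch)
  excluded <- apply(matrix(excl_mat, n_ch), 1, all)  # usable in no repetition
  n_obs <- rowSums(!is.na(pres_mat))
  n_pres <- rowSums(pres_mat, na.rm = TRUE)
  present <- ifelse(n_obs > 0, n_pres >= n_obs / 2, NA)  # majority, ties present
  pres_true <- matrix(pres_mat %in% TRUE, n_ch)
  onset_pct <- ifelse(present & n_pres > 0,
                      rowSums(ifelse(pres_true, pct_mat, 0), na.rm = TRUE) /
                        pmax(1, n_pres), NA_real_)
  frac <- mean(present[!excluded], na.rm = TRUE)
  out <- structure(list(
    channels = data.frame(base[, c("channel", "lat_row", "lat_col", "x_mm", "y_mm")],
                          excluded = excluded, present = present,
                          onset_pct = onset_pct, n_repetitions_present = n_pres),
    fraction_channels_with_frp = frac,
    frp_present = frac > 0.5,
    mean_onset_pct = if (any(present[!excluded] %in% TRUE))
      mean(onset_pct[!excluded & (present %in% TRUE)]) else NA_real_,
    axis = maps[[1]]$axis, meta = maps[[1]]$meta,
    n_repetitions = length(maps)), class = "onset_map")
  if (!is.null(profiles)) {
    norm <- rowMeans(sapply(profiles, function(p) p$normalized_pct))
    raw <- rowMeans(sapply(profiles, function(p) p$raw_grid_rms))
    out$amplitude_profile <- data.frame(
      epoch = profiles[[1]]$epochs$epoch, phase = profiles[[1]]$epochs$phase,
      normalized_pct = norm, raw_grid_rms = raw)
  }
  out
}

#' Pool subject-level summaries across sides
#'
#' Averages each subject's side-level values (mean onset percent, channel
#' onset map, amplitude profile) over sides. A paired side-difference check
#' (two-sided paired t-test on subject mean onsets) is run first; pooling
#' proceeds regardless, with a warning when the check indicates a systematic
#' side difference.
#'
#' @param summary_df Data.frame with one row per subject x side containing at
#'   least `subject` and the value columns to pool.
#' @param value_cols Character vector of numeric columns to average.
#' @param alpha Significance level of the side-difference check.
#' @return The pooled data.frame (one row per subject), with attribute
#'   `side_check` holding the test p-value (NA when only one side present).
#' @export
pool_sides <- function(summary_df, value_cols, alpha = 0.05) {
  by_cols <- setdiff(names(summary_df), c("side", value_cols))
  sides <- unique(summary_df$side)
  p_val <- NA_real_
  if (length(sides) == 2 && length(value_cols)) {
    a <- summary_df[summary_df$side == sides[1], c(by_cols, value_cols[1])]
    b <- summary_df[summary_df$side == sides[2], c(by_cols, value_cols[1])]
    w <- merge(a, b, by = by_cols)
    v1 <- w[[length(by_cols) + 1L]]; v2 <- w[[length(by_cols) + 2L]]
    ok <- complete.cases(v1, v2)
    if (sum(ok) >= 3) {
      dif <- v1[ok] - v2[ok]
      p_val <- if (sd(dif) == 0) {
        if (mean(dif) == 0) NA_real_ else 0  # constant nonzero shift
      } else {
        tryCatch(t.test(v1[ok], v2[ok], paired = TRUE)$p.value,
                 error = function(e) NA_real_)
      }
      if (!is.na(p_val) && p_val < alpha)
        warning(sprintf(
          "systematic side difference detected (paired p = %.3f); pooling anyway",
          p_val))
    }
  }
  agg <- stats::aggregate(summary_df[value_cols], by = summary_df[by_cols],
                          FUN = mean, na.rm = TRUE)
  attr(agg, "side_check") <- p_val
  agg
}
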