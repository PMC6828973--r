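#' Epoch-wise RMS amplitude profile of one trial
#'
#' Computes the RMS of every non-excluded band-passed bipolar channel over
#' adjacent, non-overlapping 1-s windows tiled from the detected flexion
#' start, then averages across channels to one grid-mean value per epoch.
#' Epoch counts follow the detected phase durations rounded to the nearest
#' whole second (nominally 4 flexion + 8 full-flexion epochs: segmentation
#' tolerance bands trim a fraction of a second from the nominal 4-s flexion
#' phase, so rounding, not truncation, recovers the nominal epoch count);
#' epochs that would run past the end of the recording are dropped with a
#' warning.
#'
#' @param trial A `bipolar_trial` (after [quality_screen()] if QC exclusions
#'   should be honoured).
#' @param seg A [segment_phases()] result.
#' @return An object of class `amplitude_profile` with `epochs`: a
#'   data.frame (`epoch`, `phase`, `start_s`, `raw_grid_rms`), the per-epoch
#'   per-channel RMS matrix (`channel_rms`), and trial metadata. Normalised
#'   values are added by [normalize_profile()].
#' @export
epoch_rms <- function(trial, seg) {
  stopifnot(inherits(trial, "bipolar_trial"), inherits(seg, "phase_segmentation"))
  fs <- trial$sampling_rate
  keep <- setdiff(trial$channels$channel, trial$excluded$channel)
  if (!length(keep)) stop("no usable channels after quality screening")

  n_flex <- max(0L, round((seg$mvf[1] - seg$flexion[1]) / fs))
  n_mvf <- max(0L, round((seg$mvf[2] - seg$mvf[1]) / fs))
  if (n_flex == 0L) stop("flexion phase shorter than half an epoch")
  n_tot <- n_flex + n_mvf
  starts <- seg$flexion[1] + (seq_len(n_tot) - 1L) * fs
  fit <- starts + fs - 1L <= nrow(trial$signals)
  if (!all(fit)) {
    warning(sprintf("dropping %d epoch(s) running past the end of the recording",
                    sum(!fit)))
    n_tot <- sum(fit); starts <- starts[fit]
    n_mvf <- n_tot - n_flex
  }
  ch_rms <- t(vapply(starts, function(s0)
    rms(trial$signals[s0:(s0 + fs - 1L), keep, drop = FALSE]),
    numeric(length(keep))))
  epochs <- data.frame(
    epoch = seq_len(n_tot),
    phase = rep(c("flexion", "mvf"), c(n_flex, n_mvf)),
    start_s = (starts - 1) / fs,
    raw_grid_rms = rowMeans(ch_rms))
  structure(list(epochs = epochs, channel_rms = ch_rms, channels = keep,
                 n_flexion_epochs = n_flex, n_mvf_epochs = n_mvf,
                 meta = trial$meta), class = "amplitude_profile")
}

#' Normalise an amplitude profile to the extension-phase peak
#'
#' Computes grid-mean RMS over complete 1-s windows of the extension phase
#' the same way as [epoch_rms()]; the normalisation reference is the maximum
#' of those, and every flexion/MVF epoch is expressed as a percentage of it.
#'
#' @param profile An `amplitude_profile` from [epoch_rms()].
#' @param trial The `bipolar_trial` the profile was computed from.
#' @param seg The matching [segment_phases()] result.
#' @return The profile with `normalized_pct` added to `epochs` (and exposed
#'   as `profile$normalized_pct`), plus `normalization_reference`.
#' @export
normalize_profile <- function(profile, trial, seg) {
  stopifnot(inherits(profile, "amplitude_profile"))
  fs <- trial$sampling_rate
  keep <- profile$channels
  e1 <- seg$extension[1]; e2 <- min(seg$extension[2], nrow(trial$signals) + 1L)
  n_ext <- floor((e2 - e1) / fs)
  if (n_ext < 1L) stop("extension phase shorter than 1 s: cannot normalise")
  ext_rms <- vapply(seq_len(n_ext), function(i) {
    s0 <- e1 + (i - 1L) * fs
    mean(rms(trial$signals[s0:(s0 + fs - 1L), keep, drop = FALSE]))
  }, numeric(1))
  ref <- max(ext_rms)
  if (ref <= 0) stop("degenerate trial: extension-phase reference RMS is zero")
  profile$normalization_reference <- ref
  profile$epochs$normalized_pct <- 100 * profile$epochs$raw_grid_rms / ref
  profile$normalized_pct <- profile$epochs$normalized_pct
  profile$raw_grid_rms <- profile$epochs$raw_grid_rms
  profile
}

#' @export
print.amplitude_profile <- function(x, ...) {
  cat(sprintf("Amplitude profile: %d flexion + %d MVF epochs over %d channels\n",
              x$n_flexion_epochs, x$n_mvf_epochs, length(x$channels)))
  if (!is.null(x$epochs$normalized_pct))
    cat("  normalized (%):",
        paste(sprintf("%.1f", x$epochs$normalized_pct), collapse = " "), "\n")
  invisible(x)
}
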