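#' Construct a monopolar HDEMG trial
#'
#' One recorded repetition of the trunk flexion task: a samples-by-electrodes
#' block of monopolar EMG, the electrogoniometer trunk-angle trace, the grid
#' layout, and identifying metadata.
#'
#' @param signals Numeric samples x electrodes matrix (arbitrary EMG units).
#' @param sampling_rate Sampling rate in Hz (EMG and angle share it).
#' @param angle Trunk angle in degrees, one value per sample.
#' @param layout The [grid_layout()] describing the electrode grid.
#' @param meta Named list of trial metadata; recognised fields are `subject`,
#'   `group`, `side`, `repetition`.
#' @return An object of class `monopolar_trial`.
#' @export
monopolar_trial <- function(signals, sampling_rate, angle, layout = grid_layout(),
                            meta = list()) {
  signals <- as.matrix(signals)
  if (length(angle) != nrow(signals))
    stop("angle trace and EMG block must have the same number of samples")
  if (ncol(signals) != n_electrodes(layout))
    stop(sprintf("expected %d electrode signals for this layout, got %d",
                 n_electrodes(layout), ncol(signals)))
  structure(list(signals = signals, sampling_rate = sampling_rate,
                 angle = as.numeric(angle), layout = layout, meta = meta),
            class = "monopolar_trial")
}

#' @export
print.monopolar_trial <- function(x, ...) {
  cat(sprintf("Monopolar HDEMG trial: %d samples x %d electrodes @ %g Hz (%.1f s)\n",
              nrow(x$signals), ncol(x$signals), x$sampling_rate,
              nrow(x$signals) / x$sampling_rate))
  if (length(x$meta))
    cat("  ", paste(names(x$meta), unlist(x$meta), sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Derive band-passed bipolar channels from a monopolar trial
#'
#' Forms along-column adjacent-electrode differences (caudal minus cranial)
#' per [enumerate_bipolar_channels()], then applies a zero-phase Butterworth
#' band-pass. For the default 13 x 5 grid with one absent corner electrode
#' this produces 59 bipolar signals. A low-frequency power fraction is
#' computed on each raw (pre-filter) bipolar difference and stored for
#' quality screening: movement artefact is common mode across the grid and
#' cancels in clean differences, so a large low-frequency residue marks a
#' faulty electrode contact.
#'
#' @param trial A [monopolar_trial()].
#' @param band Band-pass corner frequencies in Hz. Corners at or above the
#'   Nyquist frequency are clamped (with a warning) to 0.45 * sampling rate.
#' @param order One-way Butterworth order.
#' @return An object of class `bipolar_trial`: `signals` (samples x channels,
#'   band-passed), `channels` (the enumeration table), `excluded` (empty
#'   data.frame of QC flags, filled by [quality_screen()]),
#'   `lowfreq_fraction` (per channel, pre-filter), plus sampling rate, angle,
#'   layout and metadata carried over.
#' @export
derive_bipolar <- function(trial, band = c(20, 350), order = 4) {
  stopifnot(inherits(trial, "monopolar_trial"))
  fs <- trial$sampling_rate
  if (nrow(trial$signals) < fs)
    stop("trial shorter than 1 s: too short for stable filtering")
  if (band[2] >= fs / 2) {
    band[2] <- 0.45 * fs
    warning(sprintf("band-pass upper corner clamped to %.0f Hz (Nyquist limit)", band[2]))
  }
  ch <- enumerate_bipolar_channels(trial$layout)
  raw <- trial$signals[, ch$elec_caudal, drop = FALSE] -
         trial$signals[, ch$elec_cranial, drop = FALSE]
  lf <- lowfreq_power_fraction(raw, fs, f_hi = band[1])
  sig <- zero_phase_butter(raw, fs, band, type = "pass", order = order)
  colnames(sig) <- paste0("bip", ch$channel)
  structure(list(signals = sig, channels = ch,
                 excluded = data.frame(channel = integer(0), reason = character(0)),
                 lowfreq_fraction = as.numeric(lf),
                 filter_spec = list(type = "butterworth_bandpass_zero_phase",
                                    band_hz = band, order = order),
                 sampling_rate = fs, angle = trial$angle,
                 layout = trial$layout, meta = trial$meta),
            class = "bipolar_trial")
}

#' @export
print.bipolar_trial <- function(x, ...) {
  cat(sprintf("Bipolar HDEMG trial: %d samples x %d channels @ %g Hz, %d excluded\n",
              nrow(x$signals), ncol(x$signals), x$sampling_rate, nrow(x$excluded)))
  invisible(x)
}

#' Quality-control configuration
#'
#' @param snr_min Minimum acceptable task SNR: band-limited RMS over the
#'   active window (flexion + full flexion) divided by RMS over the
#'   quiet-standing baseline window. Channels below it are flagged
#'   `low_snr`.
#' @param artefact_max Maximum acceptable fraction of pre-filter signal power
#'   below the band-pass low corner. Channels above it are flagged
#'   `artefact`.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(snr_min = 3, artefact_max = 0.5) {
  structure(list(snr_min = snr_min, artefact_max = artefact_max),
            class = "qc_config")
}

#' Screen bipolar channels for poor signal quality
#'
#' Flags channels with a low task signal-to-noise ratio (e.g. dead channels)
#' or with excessive pre-filter low-frequency power (movement artefact or
#' poor skin-electrode contact leaking common-mode drift into the
#' difference). Flagged channels are kept in the trial but carry reason
#' codes and are ignored by downstream averaging and mapping.
#'
#' @param trial A `bipolar_trial` from [derive_bipolar()].
#' @param seg A [segment_phases()] result supplying the baseline and active
#'   windows.
#' @param config A [qc_config()].
#' @return The trial with its `excluded` table filled in (columns `channel`,
#'   `reason`, `snr`, `lowfreq_fraction`).
#' @export
quality_screen <- function(trial, seg, config = qc_config()) {
  stopifnot(inherits(trial, "bipolar_trial"), inherits(seg, "phase_segmentation"))
  bas <- seg$baseline[1]:(seg$baseline[2] - 1L)
  act <- seg$flexion[1]:(seg$mvf[2] - 1L)
  rms_b <- rms(trial$signals[bas, , drop = FALSE])
  rms_a <- rms(trial$signals[act, , drop = FALSE])
  snr <- ifelse(rms_b > 0, rms_a / rms_b, ifelse(rms_a > 0, Inf, 0))
  low_snr <- snr < config$snr_min
  artefact <- trial$lowfreq_fraction > config$artefact_max
  flagged <- which(low_snr | artefact)
  reason <- ifelse(low_snr[flagged] & artefact[flagged], "low_snr;artefact",
                   ifelse(low_snr[flagged], "low_snr", "artefact"))
  trial$excluded <- data.frame(channel = flagged, reason = reason,
                               snr = snr[flagged],
                               lowfreq_fraction = trial$lowfreq_fraction[flagged])
  if (length(flagged) == ncol(trial$signals))
    stop("all channels failed quality screening: trial unusable")
  trial$qc <- list(snr = snr, config = config)
  trial
}

#' Rectified low-pass amplitude envelope
#'
#' Full-wave rectifies each bipolar channel and low-pass filters it
#' (zero-phase Butterworth, 50 Hz by default) to obtain the amplitude
#' envelope used for FRP onset detection. Small negative filter ripple is
#' clipped so envelopes are non-negative everywhere.
#'
#' @param trial A `bipolar_trial`.
#' @param cutoff Envelope low-pass cutoff in Hz.
#' @param order One-way Butterworth order.
#' @return An object of class `envelope_trial` with `envelopes`
#'   (samples x channels), the channel table, QC exclusions carried over,
#'   and a `filter_spec` record.
#' @export
emg_envelope <- function(trial, cutoff = 50, order = 4) {
  stopifnot(inherits(trial, "bipolar_trial"))
  env <- zero_phase_butter(abs(trial$signals), trial$sampling_rate, cutoff,
                           type = "low", order = order)
  env[env < 0] <- 0
  structure(list(envelopes = env, channels = trial$channels,
                 excluded = trial$excluded,
                 filter_spec = list(type = "rectify_lowpass_zero_phase",
                                    cutoff_hz = cutoff, order = order,
                                    source_filter = trial$filter_spec),
                 sampling_rate = trial$sampling_rate, angle = trial$angle,
                 layout = trial$layout, meta = trial$meta),
            class = "envelope_trial")
}
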