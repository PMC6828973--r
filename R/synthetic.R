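#' Configuration for the synthetic HDEMG cohort generator
#'
#' The generator emulates the statistical structure of a trunk-flexion HDEMG
#' study: three groups (pain-free controls, who all show the flexion
#' relaxation phenomenon; an LBP subgroup with a delayed FRP; and an LBP
#' subgroup that never relaxes), a trapezoidal flexion task (4 s flexion,
#' 8 s full flexion, 4 s return), a quiet-standing baseline, 13 x 5 grids
#' with one absent corner electrode, and a cranio-caudal gradient of onset
#' timing (more cranial channels relax later in the LBP-with-FRP group).
#'
#' True onsets are specified on the angle axis (percent of maximal trunk
#' flexion) and mapped to time through each subject's angle trace. The true
#' onset marks the attainment of myoelectric silence: each electrode's
#' envelope completes its sigmoid drop at the true onset time. Extension
#' re-activates all channels at the largest amplitudes of the trial so that
#' amplitude normalisation finds its reference in the extension phase.
#'
#' @param n_per_group Named subject counts `c(control=, lbp_frp=, lbp_no_frp=)`.
#' @param sampling_rate Hz.
#' @param phase_durations Seconds for (flexion, mvf, extension).
#' @param baseline_duration Seconds of quiet standing prepended.
#' @param true_onset_mean Group means of the true FRP onset, percent of trunk
#'   flexion, named `control` and `lbp_frp` (`lbp_no_frp` has none).
#' @param onset_between_subject_sd Between-subject SD of onset (percent).
#' @param onset_spatial_gradient Percent of trunk flexion per electrode row
#'   (positive = cranial rows relax later), named per group.
#' @param onset_channel_jitter_sd Per-electrode onset jitter SD (percent).
#' @param envelope_amplitude RMS scale of active-phase EMG (arbitrary units).
#' @param baseline_amplitude RMS scale of quiet standing (postural tone).
#' @param relaxation_depth Post-offset RMS as a multiple of
#'   `baseline_amplitude` (1 = relaxes fully to baseline level).
#' @param extension_boost Extension-phase RMS as a multiple of
#'   `envelope_amplitude` (> 1 so the normalisation peak lies in extension).
#' @param noise_band Hz band of the Gaussian carrier noise.
#' @param shared_fraction Fraction of carrier variance shared across a grid
#'   (partial spatial correlation; the shared component cancels in bipolar
#'   derivation).
#' @param transition_s Duration of the sigmoid deactivation drop (10-90%).
#' @param corner_s Smoothing (s) of the angle trapezoid's velocity corners.
#' @param max_flexion_angle_mean,max_flexion_angle_sd Degrees; subject
#'   maximal flexion angles are drawn from this normal.
#' @param angle_noise_sd Measurement noise SD (degrees) on the angle trace.
#' @param n_repetitions Repetitions per subject and side.
#' @param sides Character vector of sides to simulate.
#' @param seed Integer random seed; the whole cohort is reproducible from it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_per_group = c(control = 14, lbp_frp = 9, lbp_no_frp = 5),
                             sampling_rate = 2048,
                             phase_durations = c(flexion = 4, mvf = 8, extension = 4),
                             baseline_duration = 2,
                             true_onset_mean = c(control = 55, lbp_frp = 68),
                             onset_between_subject_sd = 5,
                             onset_spatial_gradient = c(control = 0, lbp_frp = 0.5),
                             onset_channel_jitter_sd = 1.5,
                             envelope_amplitude = 1,
                             baseline_amplitude = 0.1,
                             relaxation_depth = 1,
                             extension_boost = 1.5,
                             noise_band = c(20, 350),
                             shared_fraction = 0.5,
                             transition_s = 0.15,
                             corner_s = 0.08,
                             max_flexion_angle_mean = 91.2,
                             max_flexion_angle_sd = 12.4,
                             angle_noise_sd = 0.05,
                             n_repetitions = 3,
                             sides = c("R", "L"),
                             seed = 1L) {
  cfg <- as.list(environment())
  if (any(cfg$n_per_group < 0) || sum(cfg$n_per_group) < 1)
    stop("configuration error: n_per_group must contain positive subject counts")
  if (any(c(cfg$sampling_rate, cfg$phase_durations, cfg$baseline_duration,
            cfg$envelope_amplitude, cfg$baseline_amplitude) <= 0))
    stop("configuration error: durations, rates and amplitudes must be positive")
  if (any(cfg$true_onset_mean <= 0 | cfg$true_onset_mean >= 100))
    stop("configuration error: onset means must lie in (0, 100)")
  if (cfg$noise_band[2] >= cfg$sampling_rate / 2)
    stop("configuration error: noise band must lie below the Nyquist frequency")
  class(cfg) <- "synthetic_config"
  cfg
}

# trapezoidal angle profile with raised-cosine velocity corners, exact peak A
.angle_profile <- function(fs, A, durations, baseline_s, corner_s) {
  ramp <- function(T_phase) {
    n <- round(T_phase * fs)
    t <- (seq_len(n) - 0.5) / fs
    c_s <- min(corner_s, T_phase / 3)
    v <- rep(1, n)
    v[t < c_s] <- 0.5 * (1 - cos(pi * t[t < c_s] / c_s))
    v[t > T_phase - c_s] <- 0.5 * (1 - cos(pi * (T_phase - t[t > T_phase - c_s]) / c_s))
    x <- cumsum(v) / fs
    x / x[n]  # normalised 0 -> 1
  }
  up <- ramp(durations[["flexion"]])
  down <- ramp(durations[["extension"]])
  c(rep(0, round(baseline_s * fs)),
    A * up,
    rep(A, round(durations[["mvf"]] * fs)),
    A * (1 - down))
}

# draw per-subject truth (group, max angle, subject onset mean)
.draw_subjects <- function(config) {
  groups <- rep(names(config$n_per_group), config$n_per_group)
  n <- length(groups)
  id <- sprintf("S%02d", seq_len(n))
  A <- pmin(130, pmax(50, rnorm(n, config$max_flexion_angle_mean,
                                config$max_flexion_angle_sd)))
  onset <- rep(NA_real_, n)
  for (g in names(config$true_onset_mean)) {
    sel <- groups == g
    onset[sel] <- rnorm(sum(sel), config$true_onset_mean[[g]],
                        config$onset_between_subject_sd)
  }
  onset <- pmin(92, pmax(15, onset))
  data.frame(subject = id, group = groups, max_flexion_angle = A,
             subject_onset_pct = onset, stringsAsFactors = FALSE)
}

# per-electrode true onset percentages for one subject (NA if no FRP)
.electrode_onsets <- function(subj, layout, config) {
  if (is.na(subj$subject_onset_pct)) return(NULL)
  grad <- config$onset_spatial_gradient[[subj$group]] %||% 0
  rows <- seq_len(layout$n_rows)
  centre <- (layout$n_rows + 1) / 2
  base <- subj$subject_onset_pct + grad * (rows - centre)
  p <- matrix(NA_real_, layout$n_rows, layout$n_cols)
  for (cc in seq_len(layout$n_cols))
    p[, cc] <- base + rnorm(layout$n_rows, 0, config$onset_channel_jitter_sd)
  pmin(pmax(p, 5), 95)
}

# generate one monopolar trial + its per-bipolar-channel truth
.generate_trial <- function(subj, side, repetition, layout, config,
                            elec_onset_pct) {
  fs <- config$sampling_rate
  A <- subj$max_flexion_angle
  angle <- .angle_profile(fs, A, config$phase_durations,
                          config$baseline_duration, config$corner_s)
  n <- length(angle)
  t <- (seq_len(n) - 1) / fs
  t_flex <- config$baseline_duration
  t_ext <- t_flex + config$phase_durations[["flexion"]] +
    config$phase_durations[["mvf"]]

  # map electrode onset percentages to time through the rising angle limb
  flex_idx <- which(t >= t_flex & t <= t_flex + config$phase_durations[["flexion"]])
  onset_time <- function(pct) {
    approx(angle[flex_idx], t[flex_idx], xout = pct / 100 * A,
           ties = "ordered", rule = 2)$y
  }

  amp_act <- config$envelope_amplitude
  amp_base <- config$baseline_amplitude
  amp_rel <- config$relaxation_depth * amp_base
  amp_ext <- config$extension_boost * amp_act
  tau_d <- config$transition_s / (2 * log(9))  # 10-90% width = transition_s
  tau_r <- 0.05 / (2 * log(9))                 # activation ramps: 50 ms
  lgs <- function(tt, t0, tau) 1 / (1 + exp(-(tt - t0) / tau))

  emap <- electrode_index_map(layout)
  n_el <- n_electrodes(layout)
  env <- matrix(0, n, n_el)
  for (cc in seq_len(layout$n_cols)) {
    for (rr in seq_len(layout$n_rows)) {
      k <- emap[rr, cc]
      if (is.na(k)) next
      e <- amp_base + (amp_act - amp_base) * lgs(t, t_flex, tau_r)
      pre_ext <- amp_act
      if (!is.null(elec_onset_pct)) {
        # drop completes at the true onset time (attained silence)
        t_on <- onset_time(elec_onset_pct[rr, cc])
        e <- e + (amp_rel - amp_act) * lgs(t, t_on - config$transition_s / 2, tau_d)
        pre_ext <- amp_rel
      }
      e <- e + (amp_ext - pre_ext) * lgs(t, t_ext, tau_r)
      env[, k] <- e
    }
  }

  shared <- band_limited_noise(n, 1L, fs, config$noise_band)
  own <- band_limited_noise(n, n_el, fs, config$noise_band)
  w <- config$shared_fraction
  carrier <- sqrt(w) * shared[, rep(1L, n_el)] + sqrt(1 - w) * own
  signals <- env * carrier
  angle_obs <- angle + rnorm(n, 0, config$angle_noise_sd)

  trial <- monopolar_trial(signals, fs, angle_obs, layout,
                           meta = list(subject = subj$subject, group = subj$group,
                                       side = side, repetition = repetition))
  # bipolar-channel truth: the channel falls silent when the later (cranially
  # adjacent) of its two electrodes does
  truth <- NULL
  ch <- enumerate_bipolar_channels(layout)
  if (!is.null(elec_onset_pct)) {
    p_lo <- elec_onset_pct[cbind(ch$row_pair_lo, ch$lat_col)]
    p_hi <- elec_onset_pct[cbind(ch$row_pair_hi, ch$lat_col)]
    truth <- data.frame(subject = subj$subject, group = subj$group, side = side,
                        repetition = repetition, channel = ch$channel,
                        lat_row = ch$lat_row, lat_col = ch$lat_col,
                        true_onset_pct = pmax(p_lo, p_hi))
  }
  phase <- data.frame(subject = subj$subject, side = side, repetition = repetition,
                      flexion_start_s = t_flex,
                      mvf_start_s = t_flex + config$phase_durations[["flexion"]],
                      extension_start_s = t_ext,
                      max_flexion_angle = A)
  list(trial = trial, truth = truth, phase = phase)
}

#' Generate a synthetic HDEMG cohort
#'
#' Draws subjects per group, then simulates every subject x side x repetition
#' trial: a goniometer trace (smooth trapezoid up to the subject's maximal
#' flexion angle) and 64 monopolar EMG channels built as band-limited
#' Gaussian carriers (partially shared across the grid) multiplied by
#' channel-specific amplitude envelopes. Channel deactivation is a smooth
#' sigmoid completing at the channel's true onset; `lbp_no_frp` subjects
#' never deactivate. Fully reproducible from `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @param layout A [grid_layout()].
#' @return A list of class `synthetic_cohort` with `trials` (list of
#'   [monopolar_trial()]), `truth` (list with `subjects`, `onsets` - one row
#'   per trial x channel with the true onset percent - and `phases`), the
#'   `config` and the `layout`.
#' @examples
#' cfg <- synthetic_config(n_per_group = c(control = 1, lbp_frp = 1, lbp_no_frp = 0),
#'                         sampling_rate = 256, noise_band = c(20, 100),
#'                         n_repetitions = 1, sides = "R")
#' coh <- generate_cohort(cfg)
#' length(coh$trials)
#' @export
generate_cohort <- function(config = synthetic_config(), layout = grid_layout()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  subjects <- .draw_subjects(config)
  trials <- list(); onsets <- list(); phases <- list()
  k <- 0L
  for (i in seq_len(nrow(subjects))) {
    subj <- subjects[i, ]
    set.seed((config$seed * 1009L + i * 7L) %% 2147483647L)
    elec <- .electrode_onsets(subj, layout, config)
    for (side in config$sides) {
      for (rep_i in seq_len(config$n_repetitions)) {
        k <- k + 1L
        set.seed((config$seed * 1013L + i * 131L +
                    match(side, c("R", "L")) * 17L + rep_i) %% 2147483647L)
        g <- .generate_trial(subj, side, rep_i, layout, config, elec)
        trials[[k]] <- g$trial
        phases[[k]] <- g$phase
        if (!is.null(g$truth)) onsets[[length(onsets) + 1L]] <- g$truth
      }
    }
  }
  structure(list(trials = trials,
                 truth = list(subjects = subjects,
                              onsets = if (length(onsets)) do.call(rbind, onsets) else NULL,
                              phases = do.call(rbind, phases),
                              faults = NULL),
                 config = config, layout = layout),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic HDEMG cohort: %d subjects (%s), %d trials @ %g Hz\n",
              nrow(x$truth$subjects),
              paste(names(x$config$n_per_group), x$config$n_per_group,
                    sep = "=", collapse = ", "),
              length(x$trials), x$config$sampling_rate))
  invisible(x)
}

#' Inject channel faults into a synthetic cohort
#'
#' Emulates the channel defects that quality control must catch. A common
#' low-frequency movement-artefact drift (identical on every electrode of a
#' grid, hence cancelled by clean bipolar derivation) is added to each trial,
#' and a chosen fraction of electrodes per grid is corrupted with either a
#' near-zero signal (lost skin contact: the electrode records only faint
#' instrumentation noise, and its bipolar differences no longer cancel the
#' common-mode drift) or a large independent low-frequency artefact. The
#' number of corrupted electrodes is `floor(fraction * n_electrodes)`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param fraction Proportion of electrodes to corrupt per grid, in `[0, 1)`.
#' @param seed Integer seed for fault placement.
#' @param drift_amplitude RMS of the common-mode drift, in multiples of
#'   `envelope_amplitude`.
#' @param drift_band Hz band of the drift.
#' @return The cohort with corrupted trials and `truth$faults`: one row per
#'   trial x corrupted electrode, with the affected bipolar channels
#'   recorded in `truth$fault_channels`.
#' @export
inject_channel_faults <- function(cohort, fraction, seed = 1L,
                                  drift_amplitude = 2, drift_band = c(0.5, 5)) {
  stopifnot(inherits(cohort, "synthetic_cohort"), fraction >= 0, fraction < 1)
  if (fraction == 0) return(cohort)
  set.seed(seed)
  layout <- cohort$layout
  cfg <- cohort$config
  n_el <- n_electrodes(layout)
  n_bad <- floor(fraction * n_el)
  ch <- enumerate_bipolar_channels(layout)
  faults <- list(); fch <- list()
  for (k in seq_along(cohort$trials)) {
    tr <- cohort$trials[[k]]
    n <- nrow(tr$signals)
    drift <- band_limited_noise(n, 1L, tr$sampling_rate, drift_band) *
      drift_amplitude * cfg$envelope_amplitude
    tr$signals <- tr$signals + drift[, rep(1L, n_el)]
    if (n_bad > 0) {
      bad <- sort(sample.int(n_el, n_bad))
      type <- sample(c("near_zero", "artefact"), n_bad, replace = TRUE)
      for (j in seq_len(n_bad)) {
        if (type[j] == "near_zero") {
          tr$signals[, bad[j]] <- rnorm(n, 0, 0.01 * cfg$envelope_amplitude)
        } else {
          tr$signals[, bad[j]] <-
            band_limited_noise(n, 1L, tr$sampling_rate, drift_band) *
            3 * cfg$envelope_amplitude +
            rnorm(n, 0, 0.05 * cfg$envelope_amplitude)
        }
      }
      affected <- ch$channel[ch$elec_caudal %in% bad | ch$elec_cranial %in% bad]
      faults[[length(faults) + 1L]] <-
        data.frame(trial = k, subject = tr$meta$subject, side = tr$meta$side,
                   repetition = tr$meta$repetition, electrode = bad,
                   fault_type = type)
      fch[[length(fch) + 1L]] <-
        data.frame(trial = k, subject = tr$meta$subject, side = tr$meta$side,
                   repetition = tr$meta$repetition, channel = affected)
    }
    cohort$trials[[k]] <- tr
  }
  cohort$truth$faults <- if (length(faults)) do.call(rbind, faults) else NULL
  cohort$truth$fault_channels <- if (length(fch)) do.call(rbind, fch) else NULL
  cohort
}
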