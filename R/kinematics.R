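#' Segmentation configuration
#'
#' @param vel_fraction Flexion (extension) start is placed where the smoothed
#'   angular velocity first exceeds this fraction of the peak flexion
#'   (extension) velocity.
#' @param angle_tol Degrees: the full-flexion plateau is the longest run of
#'   samples within `angle_tol` of the maximal flexion angle.
#' @param baseline_s Length (s) of the quiet-standing baseline window; it
#'   ends `baseline_gap_s` before the detected flexion start.
#' @param baseline_gap_s Gap (s) between the baseline window and flexion start.
#' @param smooth_s Width (s) of the moving-average smoother applied to the
#'   angle trace before differentiation.
#' @param vel_smooth_s Width (s) of the heavier smoothing used for the
#'   velocity-threshold event detection (suppresses goniometer noise, which
#'   differencing amplifies).
#' @param min_range Minimum angle excursion (degrees) below which the trace
#'   is considered to contain no movement.
#' @return A list of class `seg_config`.
#' @export
seg_config <- function(vel_fraction = 0.05, angle_tol = 2, baseline_s = 1,
                       baseline_gap_s = 0.5, smooth_s = 0.05,
                       vel_smooth_s = 0.15, min_range = 15) {
  structure(list(vel_fraction = vel_fraction, angle_tol = angle_tol,
                 baseline_s = baseline_s, baseline_gap_s = baseline_gap_s,
                 smooth_s = smooth_s, vel_smooth_s = vel_smooth_s,
                 min_range = min_range),
            class = "seg_config")
}

# centred moving average with edge replication
.moving_avg <- function(x, k) {
  if (k <= 1L) return(x)
  if (k %% 2L == 0L) k <- k + 1L
  h <- (k - 1L) %/% 2L
  xp <- c(rep(x[1], h), x, rep(x[length(x)], h))
  as.numeric(stats::filter(xp, rep(1 / k, k), sides = 2))[(h + 1L):(h + length(x))]
}

#' Segment a trunk-flexion trial from its goniometer trace
#'
#' Divides one repetition into quiet-standing baseline, trunk flexion, full
#' flexion (MVF) and extension phases. Flexion start is the first sample at
#' which the smoothed angular velocity exceeds a fraction (default 5%) of the
#' peak flexion velocity on the rising limb. Flexion end is the first sample
#' at which the angle has entered the `angle_tol` band (default 2 deg) around
#' the maximal flexion angle *and* the angular velocity has fallen back below
#' the same fraction of its peak - i.e. the movement has ceased inside the
#' full-flexion band, symmetric to the start rule. Extension start is the
#' symmetric event on the descending limb. All intervals are half-open
#' `[start, end)` sample index pairs.
#'
#' @param angle Trunk angle trace in degrees (must include a pre-movement
#'   quiet-standing period).
#' @param sampling_rate Hz.
#' @param config A [seg_config()].
#' @return An object of class `phase_segmentation` with fields `baseline`,
#'   `flexion`, `mvf`, `extension` (sample intervals), `max_flexion_angle`
#'   (degrees, relative to the re-referenced standing posture),
#'   `flexion_duration` (s), `angle_offset` (the standing-posture reference
#'   subtracted from the trace) and `sampling_rate`.
#' @export
segment_phases <- function(angle, sampling_rate, config = seg_config()) {
  fs <- sampling_rate
  n <- length(angle)
  if (n < 4 * fs) stop("angle trace too short to segment")
  # re-reference to the initial standing posture
  offset <- median(angle[seq_len(max(8L, round(0.5 * fs)))])
  a <- .moving_avg(angle - offset, max(3L, round(config$smooth_s * fs)))

  amax <- max(a)
  if (amax - min(a[seq_len(round(0.5 * fs))]) < config$min_range)
    stop("segmentation error: no trunk flexion movement found in angle trace")

  # heavier smoothing for the velocity used in event detection
  av <- .moving_avg(angle - offset, max(3L, round(config$vel_smooth_s * fs)))
  vel <- c(0, diff(av)) * fs

  # plateau: longest run of samples within angle_tol of the maximum
  in_band <- a >= amax - config$angle_tol
  r <- rle(in_band)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values)
  if (!length(cand)) stop("segmentation error: no full-flexion plateau found")
  plat <- cand[which.max(r$lengths[cand])]
  plat_start <- starts[plat]; plat_end <- ends[plat]
  if (r$lengths[plat] < round(0.5 * fs))
    stop("segmentation error: full-flexion plateau shorter than 0.5 s")

  # flexion start: last sub-threshold sample on the rising limb
  vpk_up <- max(vel[1:plat_start])
  if (vpk_up <= 0) stop("segmentation error: no rising limb")
  pre <- which(vel[1:plat_start] <= config$vel_fraction * vpk_up)
  i_up <- which.max(vel[1:plat_start])
  pre <- pre[pre < i_up]
  flex_start <- if (length(pre)) max(pre) + 1L else 1L

  # flexion end: movement has ceased (velocity persistently sub-threshold)
  # inside the full-flexion band
  hold_n <- max(1L, round(0.1 * fs))
  run_up <- .run_length_forward(vel <= config$vel_fraction * vpk_up)
  ceased <- which(in_band & seq_len(n) >= i_up & seq_len(n) <= plat_end &
                    run_up >= hold_n)
  flex_end <- if (length(ceased)) ceased[1] else plat_start

  # extension: persistent descending velocity after the plateau
  if (plat_end >= n - round(0.1 * fs))
    stop("segmentation error: angle never returns toward neutral")
  vpk_dn <- min(vel[flex_end:n])
  if (vpk_dn >= 0) stop("segmentation error: no descending limb")
  run_dn <- .run_length_forward(vel < config$vel_fraction * vpk_dn)
  desc <- which(seq_len(n) > flex_end & run_dn >= hold_n)
  ext_start <- if (length(desc)) desc[1] else plat_end + 1L

  # baseline window before flexion start
  b_end <- flex_start - round(config$baseline_gap_s * fs)
  b_start <- b_end - round(config$baseline_s * fs)
  if (b_start < 1L)
    stop("segmentation error: insufficient quiet standing before movement")

  structure(list(
    baseline = c(b_start, b_end),
    flexion = c(flex_start, flex_end),
    mvf = c(flex_end, ext_start),
    extension = c(ext_start, n + 1L),
    max_flexion_angle = amax,
    flexion_duration = (flex_end - flex_start) / fs,
    angle_offset = offset,
    sampling_rate = fs), class = "phase_segmentation")
}

#' @export
print.phase_segmentation <- function(x, ...) {
  fs <- x$sampling_rate
  fmt <- function(iv) sprintf("[%.2f, %.2f) s", (iv[1] - 1) / fs, (iv[2] - 1) / fs)
  cat("Phase segmentation:\n")
  cat("  baseline ", fmt(x$baseline), "\n  flexion  ", fmt(x$flexion),
      sprintf(" (%.2f s)", x$flexion_duration), "\n  MVF      ", fmt(x$mvf),
      "\n  extension", fmt(x$extension), "\n", sep = "")
  cat(sprintf("  max flexion angle %.1f deg\n", x$max_flexion_angle))
  invisible(x)
}

#' Express an angle as percentage of trunk flexion
#'
#' `100 * angle / max_flexion_angle`, clamped to `[0, 100]`. Angles are
#' relative to the re-referenced standing posture (see [segment_phases()]).
#'
#' @param angle_value Angle(s) in degrees.
#' @param seg A `phase_segmentation` (supplies `max_flexion_angle`).
#' @return Percentage(s) of trunk flexion in `[0, 100]`.
#' @examples
#' seg <- structure(list(max_flexion_angle = 91.2), class = "phase_segmentation")
#' angle_to_flexion_pct(45.6, seg) # 50
#' @export
angle_to_flexion_pct <- function(angle_value, seg) {
  if (!is.numeric(seg$max_flexion_angle) || seg$max_flexion_angle <= 0)
    stop("max_flexion_angle must be positive")
  pmin(100, pmax(0, 100 * angle_value / seg$max_flexion_angle))
}
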