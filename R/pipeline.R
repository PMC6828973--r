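#' Pipeline configuration
#'
#' Bundles every tunable parameter of the analysis chain. Defaults mirror
#' the standard processing of lumbar HDEMG flexion trials: 20-350 Hz
#' zero-phase band-pass, 50 Hz rectified-envelope low-pass, baseline + 3 SD
#' offset threshold with a 0.25 s hold, onset expressed as percent of the
#' maximal flexion angle, and 95% Bayesian intervals for group contrasts.
#'
#' @param filter_band Band-pass corners in Hz.
#' @param filter_order One-way Butterworth order of the band-pass.
#' @param envelope_cutoff Envelope low-pass cutoff in Hz.
#' @param qc A [qc_config()].
#' @param seg A [seg_config()].
#' @param det A [det_config()].
#' @param ci_level Confidence level for contrasts, in (0, 1).
#' @param lambda_grid GCV grid for the spline fits.
#' @param seed Seed recorded in the run manifest.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(filter_band = c(20, 350), filter_order = 4,
                            envelope_cutoff = 50,
                            qc = qc_config(), seg = seg_config(),
                            det = det_config(), ci_level = 0.95,
                            lambda_grid = 10^seq(-6, 8, by = 1),
                            seed = 1L) {
  if (ci_level <= 0 || ci_level >= 1) stop("ci_level must lie in (0, 1)")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Process one trial through preprocessing, segmentation and detection
#'
#' @param trial A [monopolar_trial()].
#' @param config A [pipeline_config()].
#' @return A list with the segmentation, the screened `bipolar_trial`, the
#'   `envelope_trial`, the `onset_map` and the normalised
#'   `amplitude_profile`.
#' @export
analyze_trial <- function(trial, config = pipeline_config()) {
  seg <- segment_phases(trial$angle, trial$sampling_rate, config$seg)
  bip <- derive_bipolar(trial, band = config$filter_band,
                        order = config$filter_order)
  bip <- quality_screen(bip, seg, config$qc)
  env <- emg_envelope(bip, cutoff = config$envelope_cutoff)
  map <- build_onset_map(env, seg, config$det)
  prof <- normalize_profile(epoch_rms(bip, seg), bip, seg)
  list(seg = seg, bipolar = bip, envelope = env, map = map, profile = prof)
}

# observed class: controls keep their label, LBP subjects are split by the
# detected FRP presence
.observed_class <- function(group, frp_present) {
  ifelse(group == "control", "control",
         ifelse(frp_present, "lbp_frp", "lbp_no_frp"))
}

#' Run the full analysis over a set of trials
#'
#' Executes preprocessing, segmentation, FRP detection, amplitude profiling,
#' repetition aggregation, side pooling and both smoothing-spline ANOVA
#' models (2D onset-by-space and 1D amplitude-by-time) with their pairwise
#' group contrasts. Trials that fail a stage are logged and skipped; the run
#' fails only if an entire group loses all its subjects.
#'
#' @param trials A list of [monopolar_trial()] objects, a directory path
#'   holding trials written by [write_cohort()], or a `synthetic_cohort`.
#' @param config A [pipeline_config()].
#' @return A list of class `frp_results`: `classification` (one row per
#'   subject: observed class, fraction of channels with FRP, mean onset),
#'   `onset_data` / `amplitude_data` (long tables feeding the models),
#'   `onset_fit`, `onset_contrast`, `amplitude_fit`, `amplitude_contrasts`,
#'   and a `manifest` of warnings and per-trial failures.
#' @export
analyze_cohort <- function(trials, config = pipeline_config()) {
  if (inherits(trials, "synthetic_cohort")) trials <- trials$trials
  if (is.character(trials)) trials <- read_trials(trials)
  failures <- list(); warnings_log <- character(0)

  per_trial <- vector("list", length(trials))
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    res <- withCallingHandlers(
      tryCatch(analyze_trial(tr, config), error = function(e) e),
      warning = function(w) {
        warnings_log <<- c(warnings_log, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        data.frame(subject = tr$meta$subject %||% NA,
                   side = tr$meta$side %||% NA,
                   repetition = tr$meta$repetition %||% NA,
                   error = conditionMessage(res))
      per_trial[[i]] <- NULL
    } else {
      res$meta <- tr$meta
      per_trial[[i]] <- res
    }
  }
  per_trial <- per_trial[!vapply(per_trial, is.null, logical(1))]
  if (!length(per_trial)) stop("no trial could be analysed")

  key <- vapply(per_trial, function(r)
    paste(r$meta$subject, r$meta$side, sep = "|"), character(1))
  agg <- lapply(split(per_trial, key), function(rs) {
    a <- aggregate_repetitions(lapply(rs, `[[`, "map"),
                               lapply(rs, `[[`, "profile"))
    a$meta <- rs[[1]]$meta
    a
  })

  # subject x side summary
  ss <- do.call(rbind, lapply(agg, function(a)
    data.frame(subject = a$meta$subject, group = a$meta$group, side = a$meta$side,
               fraction_frp = a$fraction_channels_with_frp,
               frp_present = a$frp_present,
               mean_onset_pct = a$mean_onset_pct)))
  rownames(ss) <- NULL

  # subject-level classification: fraction pooled over sides, strict > 50%
  cls <- stats::aggregate(ss["fraction_frp"], by = ss[c("subject", "group")],
                          FUN = mean)
  onset_by_subj <- stats::aggregate(ss["mean_onset_pct"],
                                    by = ss[c("subject", "group")],
                                    FUN = mean, na.rm = TRUE)
  cls <- merge(cls, onset_by_subj, by = c("subject", "group"))
  cls$frp_present <- cls$fraction_frp > 0.5
  cls$observed_class <- .observed_class(cls$group, cls$frp_present)
  cls <- cls[order(cls$subject), ]
  rownames(cls) <- NULL

  # long onset table: FRP-positive subjects, per side and channel
  onset_rows <- list()
  for (a in agg) {
    subj_cls <- cls[cls$subject == a$meta$subject, ]
    if (!isTRUE(subj_cls$frp_present)) next
    d <- a$channels
    d <- d[!d$excluded & (d$present %in% TRUE), ]
    if (!nrow(d)) next
    onset_rows[[length(onset_rows) + 1L]] <-
      data.frame(subject = a$meta$subject, group = subj_cls$observed_class,
                 side = a$meta$side, channel = d$channel,
                 lat_row = d$lat_row, lat_col = d$lat_col,
                 x_mm = d$x_mm, y_mm = d$y_mm, onset_pct = d$onset_pct)
  }
  onset_data <- if (length(onset_rows)) do.call(rbind, onset_rows) else NULL

  # amplitude table: all subjects, epochs pooled over sides
  amp_rows <- lapply(agg, function(a) {
    subj_cls <- cls[cls$subject == a$meta$subject, ]
    data.frame(subject = a$meta$subject, group = subj_cls$observed_class,
               side = a$meta$side, epoch = a$amplitude_profile$epoch,
               phase = a$amplitude_profile$phase,
               time_s = a$amplitude_profile$epoch - 0.5,
               normalized_pct = a$amplitude_profile$normalized_pct)
  })
  amp_long <- do.call(rbind, amp_rows)
  amplitude_data <- pool_sides(
    amp_long[c("subject", "group", "side", "epoch", "phase", "time_s",
               "normalized_pct")],
    value_cols = "normalized_pct")
  amplitude_data <- amplitude_data[order(amplitude_data$subject,
                                         amplitude_data$epoch), ]
  rownames(amplitude_data) <- NULL

  # ---- SS-ANOVA models -------------------------------------------------
  onset_fit <- NULL; onset_contrast <- NULL
  od <- onset_data[onset_data$group %in% c("control", "lbp_frp"), ]
  n_grp <- if (!is.null(od)) table(unique(od[c("subject", "group")])$group) else 0
  if (!is.null(od) && length(n_grp) == 2 && all(n_grp >= 2)) {
    facs <- c("group", if (length(unique(od$side)) > 1) "side")
    des <- ssanova_design(smooth = c("x_mm", "y_mm"), kernel = "thin_plate",
                          factors = facs, subject = "subject")
    onset_fit <- fit_ssanova(od, "onset_pct", des,
                             lambda_grid = config$lambda_grid)
    onset_contrast <- contrast_difference(onset_fit, "lbp_frp", "control",
                                          level = config$ci_level)
  } else {
    warnings_log <- c(warnings_log,
                      "onset model skipped: need >= 2 FRP-positive subjects per group")
  }

  amplitude_fit <- NULL; amplitude_contrasts <- NULL
  n_grp_a <- table(unique(amplitude_data[c("subject", "group")])$group)
  if (sum(n_grp_a >= 2) >= 2) {
    keep_grp <- names(n_grp_a)[n_grp_a >= 2]
    ad <- amplitude_data[amplitude_data$group %in% keep_grp, ]
    des_a <- ssanova_design(smooth = "time_s", kernel = "cubic",
                            factors = "group", subject = "subject")
    amplitude_fit <- fit_ssanova(ad, "normalized_pct", des_a,
                                 lambda_grid = config$lambda_grid)
    pairs <- utils::combn(sort(keep_grp), 2, simplify = FALSE)
    amplitude_contrasts <- lapply(pairs, function(pr)
      contrast_difference(amplitude_fit, pr[2], pr[1], level = config$ci_level))
    names(amplitude_contrasts) <- vapply(pairs, function(pr)
      paste(pr[2], "vs", pr[1]), character(1))
  } else {
    warnings_log <- c(warnings_log,
                      "amplitude model skipped: need >= 2 groups with >= 2 subjects")
  }

  structure(list(
    classification = cls,
    subject_side_summary = ss,
    aggregated = agg,
    onset_data = onset_data,
    amplitude_data = amplitude_data,
    onset_fit = onset_fit,
    onset_contrast = onset_contrast,
    amplitude_fit = amplitude_fit,
    amplitude_contrasts = amplitude_contrasts,
    manifest = list(config = config,
                    n_trials = length(trials),
                    n_analysed = length(per_trial),
                    failures = if (length(failures)) do.call(rbind, failures) else NULL,
                    warnings = warnings_log)), class = "frp_results")
}

#' @export
print.frp_results <- function(x, ...) {
  cat("FRP analysis results\n")
  tab <- table(x$classification$observed_class)
  cat("  subjects:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  n_lbp <- sum(x$classification$group != "control")
  if (n_lbp > 0)
    cat(sprintf("  FRP prevalence among LBP: %.1f%%\n",
                100 * frp_prevalence(x)))
  if (!is.null(x$onset_contrast)) {
    cat("  onset "); print(x$onset_contrast)
  }
  invisible(x)
}

#' FRP prevalence among LBP subjects
#'
#' Proportion of subjects with a non-control group label whose detected FRP
#' presence rule was satisfied.
#'
#' @param results An `frp_results` object.
#' @return Proportion in `[0, 1]`.
#' @export
frp_prevalence <- function(results) {
  cls <- results$classification
  lbp <- cls[cls$group != "control", ]
  if (!nrow(lbp)) return(NA_real_)
  mean(lbp$frp_present)
}

#' Generate a synthetic cohort and write it to disk
#'
#' @param config A [synthetic_config()].
#' @param outdir Output directory.
#' @param faults_fraction Optional electrode-fault fraction passed to
#'   [inject_channel_faults()].
#' @return The output directory, invisibly; a `run_manifest.yaml` records
#'   the seed and configuration.
#' @export
run_simulate <- function(config = synthetic_config(), outdir,
                         faults_fraction = 0) {
  cohort <- generate_cohort(config)
  if (faults_fraction > 0)
    cohort <- inject_channel_faults(cohort, faults_fraction,
                                    seed = config$seed)
  write_cohort(cohort, outdir)
  yaml::write_yaml(list(seed = config$seed,
                        config = lapply(unclass(config), function(v)
                          if (is.numeric(v)) as.list(v) else v),
                        n_trials = length(cohort$trials)),
                   file.path(outdir, "run_manifest.yaml"))
  invisible(outdir)
}

#' Analyse a cohort directory and write result tables
#'
#' @param indir Directory of trials (from [run_simulate()] or
#'   [write_cohort()]).
#' @param outdir Directory for result tables.
#' @param config A [pipeline_config()].
#' @return The `frp_results` object, invisibly.
#' @export
run_analyze <- function(indir, outdir, config = pipeline_config()) {
  res <- analyze_cohort(indir, config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(res$classification, file.path(outdir, "classification.csv"))
  if (!is.null(res$onset_data))
    data.table::fwrite(res$onset_data, file.path(outdir, "onset_map_long.csv"))
  data.table::fwrite(res$amplitude_data, file.path(outdir, "amplitude_long.csv"))
  if (!is.null(res$onset_contrast))
    data.table::fwrite(.contrast_table(res$onset_contrast),
                       file.path(outdir, "onset_contrast.csv"))
  if (!is.null(res$amplitude_contrasts))
    for (nm in names(res$amplitude_contrasts))
      data.table::fwrite(.contrast_table(res$amplitude_contrasts[[nm]]),
                         file.path(outdir, paste0("amplitude_contrast_",
                                                  gsub(" ", "_", nm), ".csv")))
  yaml::write_yaml(list(
    n_trials = res$manifest$n_trials, n_analysed = res$manifest$n_analysed,
    warnings = as.list(res$manifest$warnings),
    onset_r2 = if (!is.null(res$onset_fit)) res$onset_fit$r_squared else NA,
    amplitude_r2 = if (!is.null(res$amplitude_fit))
      res$amplitude_fit$r_squared else NA),
    file.path(outdir, "analysis_manifest.yaml"))
  invisible(res)
}

.contrast_table <- function(ct) {
  data.frame(ct$grid, difference = ct$difference,
             ci_lower = ct$ci_lower, ci_upper = ct$ci_upper,
             mean_difference = ct$mean_difference,
             mean_ci_lower = ct$mean_ci[1], mean_ci_upper = ct$mean_ci[2],
             significant = ct$significant)
}

#' Compare estimated subject onsets with generator ground truth
#'
#' @param results An `frp_results` from [analyze_cohort()].
#' @param truth The `truth` element of a [generate_cohort()] cohort.
#' @return A data.frame per subject with estimated and true mean onset
#'   percent, their difference, and attributes `bias` and `rmse`.
#' @export
onset_recovery <- function(results, truth) {
  est <- stats::aggregate(onset_pct ~ subject,
                          data = results$onset_data, FUN = mean)
  tru <- stats::aggregate(true_onset_pct ~ subject, data = truth$onsets,
                          FUN = mean)
  d <- merge(est, tru, by = "subject")
  d$error <- d$onset_pct - d$true_onset_pct
  attr(d, "bias") <- mean(d$error)
  attr(d, "rmse") <- sqrt(mean(d$error^2))
  d
}

#' Summarise an analysis into report tables and figures
#'
#' Emits group counts and FRP prevalence, the group-averaged spatial onset
#' map, amplitude curves, contrast curves, and (when generator truth is
#' supplied) the truth-versus-estimate recovery table.
#'
#' @param results An `frp_results` object.
#' @param outdir Directory for the report files.
#' @param truth Optional cohort `truth` for the recovery table.
#' @param figures Write PNG figures (requires a functional graphics device).
#' @return A list with the report tables, invisibly.
#' @export
run_report <- function(results, outdir, truth = NULL, figures = TRUE) {
  stopifnot(inherits(results, "frp_results"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cls <- results$classification
  counts <- as.data.frame(table(class = cls$observed_class))
  prev <- frp_prevalence(results)
  summary_tab <- data.frame(
    n_subjects = nrow(cls),
    n_lbp = sum(cls$group != "control"),
    frp_prevalence_lbp_pct = 100 * prev)
  data.table::fwrite(counts, file.path(outdir, "group_counts.csv"))
  data.table::fwrite(summary_tab, file.path(outdir, "summary.csv"))

  group_map <- NULL
  if (!is.null(results$onset_data)) {
    group_map <- stats::aggregate(onset_pct ~ group + lat_row + lat_col,
                                  data = results$onset_data, FUN = mean)
    data.table::fwrite(group_map, file.path(outdir, "group_mean_onset_map.csv"))
  }
  amp_curve <- stats::aggregate(normalized_pct ~ group + epoch + phase + time_s,
                                data = results$amplitude_data,
                                FUN = function(v) c(mean = mean(v), sd = sd(v)))
  amp_curve <- do.call(data.frame, amp_curve)
  names(amp_curve) <- c("group", "epoch", "phase", "time_s", "mean_pct", "sd_pct")
  data.table::fwrite(amp_curve, file.path(outdir, "amplitude_group_curves.csv"))

  recovery <- NULL
  if (!is.null(truth) && !is.null(results$onset_data)) {
    recovery <- onset_recovery(results, truth)
    data.table::fwrite(data.frame(recovery, bias = attr(recovery, "bias"),
                                  rmse = attr(recovery, "rmse")),
                       file.path(outdir, "onset_recovery.csv"))
  }

  if (figures) {
    try({
      if (!is.null(group_map))
        ggplot2::ggsave(file.path(outdir, "onset_map.png"),
                        plot_onset_map(results), width = 7, height = 4, dpi = 150)
      ggplot2::ggsave(file.path(outdir, "amplitude_curves.png"),
                      plot_amplitude_curves(results), width = 7, height = 4,
                      dpi = 150)
      if (!is.null(results$onset_contrast))
        ggplot2::ggsave(file.path(outdir, "onset_contrast.png"),
                        plot_contrast(results$onset_contrast), width = 6,
                        height = 4, dpi = 150)
    }, silent = TRUE)
  }
  invisible(list(counts = counts, summary = summary_tab,
                 group_map = group_map, amplitude_curves = amp_curve,
                 recovery = recovery))
}
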