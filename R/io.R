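#' Write a monopolar trial to disk
#'
#' One delimited numeric matrix per trial (columns `time_s`, `angle_deg`,
#' then the monopolar electrode signals in enumeration order) plus a YAML
#' metadata sidecar (`<path>.meta.yaml`) holding the sampling rate, grid
#' layout, subject identifiers and units.
#'
#' @param trial A [monopolar_trial()].
#' @param path Path of the CSV file to write.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "monopolar_trial"))
  n <- nrow(trial$signals)
  d <- data.table::data.table(
    time_s = (seq_len(n) - 1) / trial$sampling_rate,
    angle_deg = trial$angle)
  sig <- data.table::as.data.table(trial$signals)
  data.table::setnames(sig, sprintf("e%02d", seq_len(ncol(trial$signals))))
  data.table::fwrite(cbind(d, sig), path)
  lay <- trial$layout
  meta <- list(
    sampling_rate = trial$sampling_rate,
    units = list(emg = "a.u.", angle = "deg"),
    layout = list(n_rows = lay$n_rows, n_cols = lay$n_cols, ied_mm = lay$ied_mm,
                  missing_corner = as.list(lay$missing_corner),
                  orientation = lay$orientation),
    subject = trial$meta$subject %||% NA,
    group = trial$meta$group %||% NA,
    side = trial$meta$side %||% NA,
    repetition = trial$meta$repetition %||% NA)
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read a monopolar trial written by [write_trial()]
#'
#' @param path Path of the trial CSV (its `.meta.yaml` sidecar must sit next
#'   to it).
#' @return A [monopolar_trial()].
#' @export
read_trial <- function(path) {
  meta_path <- paste0(path, ".meta.yaml")
  if (!file.exists(meta_path)) stop("metadata sidecar not found: ", meta_path)
  meta <- yaml::read_yaml(meta_path)
  d <- data.table::fread(path)
  mc <- meta$layout$missing_corner
  layout <- grid_layout(n_rows = meta$layout$n_rows, n_cols = meta$layout$n_cols,
                        ied_mm = meta$layout$ied_mm,
                        missing_corner = if (length(mc)) unlist(mc) else NULL,
                        orientation = meta$layout$orientation)
  sig <- as.matrix(d[, -(1:2)])
  monopolar_trial(sig, meta$sampling_rate, d$angle_deg, layout,
                  meta = list(subject = meta$subject, group = meta$group,
                              side = meta$side, repetition = meta$repetition))
}

#' Write a synthetic cohort (trials plus ground truth) to a directory
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tr in cohort$trials) {
    fn <- sprintf("%s_%s_rep%d.csv", tr$meta$subject, tr$meta$side,
                  tr$meta$repetition)
    write_trial(tr, file.path(dir, fn))
  }
  data.table::fwrite(cohort$truth$subjects, file.path(dir, "truth_subjects.csv"))
  if (!is.null(cohort$truth$onsets))
    data.table::fwrite(cohort$truth$onsets, file.path(dir, "truth_onsets.csv"))
  data.table::fwrite(cohort$truth$phases, file.path(dir, "truth_phases.csv"))
  if (!is.null(cohort$truth$faults))
    data.table::fwrite(cohort$truth$faults, file.path(dir, "truth_faults.csv"))
  invisible(dir)
}

#' Read all trials of a directory written by [write_cohort()]
#'
#' @param dir Directory holding `*.csv` trials with `.meta.yaml` sidecars.
#' @return A list of [monopolar_trial()] objects.
#' @export
read_trials <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  files <- files[!grepl("^truth_", basename(files))]
  if (!length(files)) stop("no trial files found in ", dir)
  lapply(files, read_trial)
}
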