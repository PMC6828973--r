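#' Group-averaged topographic map of the FRP onset
#'
#' Heatmap of the mean onset percent on the bipolar lattice, one panel per
#' group, caudal rows at the bottom.
#'
#' @param results An `frp_results` object with `onset_data`.
#' @return A ggplot object.
#' @export
plot_onset_map <- function(results) {
  d <- results$onset_data
  if (is.null(d)) stop("no onset data to plot")
  m <- stats::aggregate(onset_pct ~ group + lat_row + lat_col, data = d,
                        FUN = mean)
  ggplot2::ggplot(m, ggplot2::aes(x = .data$lat_col, y = .data$lat_row,
                                  fill = .data$onset_pct)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~group) +
    ggplot2::scale_fill_viridis_c(name = "onset\n(% flexion)") +
    ggplot2::labs(x = "lattice column", y = "lattice row (caudal -> cranial)",
                  title = "FRP onset, group mean") +
    ggplot2::theme_minimal()
}

#' Group mean amplitude curves across the flexion task
#'
#' Normalised grid-mean EMG amplitude (mean and SD ribbon per group) for the
#' 12 one-second epochs spanning trunk flexion and full flexion.
#'
#' @param results An `frp_results` object.
#' @return A ggplot object.
#' @export
plot_amplitude_curves <- function(results) {
  d <- results$amplitude_data
  s <- stats::aggregate(normalized_pct ~ group + time_s, data = d,
                        FUN = function(v) c(m = mean(v), s = sd(v)))
  s <- do.call(data.frame, s)
  names(s) <- c("group", "time_s", "m", "s")
  s$s[is.na(s$s)] <- 0
  ggplot2::ggplot(s, ggplot2::aes(x = .data$time_s, y = .data$m,
                                  colour = .data$group, fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$m - .data$s,
                                      ymax = .data$m + .data$s),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "time since flexion start (s)",
                  y = "EMG amplitude (% of extension peak)",
                  title = "Normalised amplitude across the flexion task") +
    ggplot2::theme_minimal()
}

#' Plot a group contrast with its Bayesian confidence band
#'
#' @param contrast An `ssanova_contrast` from [contrast_difference()].
#' @return A ggplot object.
#' @export
plot_contrast <- function(contrast) {
  g <- contrast$grid
  xcol <- names(g)[1]
  d <- data.frame(x = g[[xcol]], est = contrast$difference,
                  lo = contrast$ci_lower, hi = contrast$ci_upper)
  if (ncol(g) > 1) d <- stats::aggregate(cbind(est, lo, hi) ~ x, data = d,
                                         FUN = mean)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$est)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = xcol,
                  y = sprintf("difference: %s - %s", contrast$levels[1],
                              contrast$levels[2]),
                  title = sprintf("Mean difference %.1f (%.0f%% CI %.1f to %.1f)",
                                  contrast$mean_difference, 100 * contrast$level,
                                  contrast$mean_ci[1], contrast$mean_ci[2])) +
    ggplot2::theme_minimal()
}
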