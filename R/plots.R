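# ggplot2 quick-look plots for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a position-map
#'
#' @param object A `position_map` from [position_map()].
#' @param ... Unused.
#' @return A ggplot: occupancy heat map, pseudo-colored by visit count.
#' @export
autoplot.position_map <- function(object, ...) {
  df <- as_tibble(as.data.frame(object))
  ggplot2::ggplot(df[df$count > 0, ],
                  ggplot2::aes(.data$x_nm, .data$y_nm, fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = "occupancy") +
    ggplot2::labs(x = "x (nm)", y = "y (nm)") +
    ggplot2::theme_minimal()
}

#' Plot a simulated trajectory as a position-map
#'
#' @param object A `tpm_trajectory` from [simulate_tpm()].
#' @param bin_width Histogram bin width (nm).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tpm_trajectory <- function(object, bin_width = 5, ...) {
  autoplot(position_map(object, bin_width = bin_width))
}

#' Plot an MSD curve on log-log axes
#'
#' @param object An `msd_curve` from [track_msd()] or [msd_ensemble()].
#' @param fit Optional `power_law_fit` overlaid as a dashed line.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.msd_curve <- function(object, fit = NULL, ...) {
  df <- as_tibble(as.data.frame(object))
  df <- df[df$lag_s > 0 & df$msd_nm2 > 0, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$lag_s, .data$msd_nm2)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "lag time (s)", y = expression(MSD ~ (nm^2))) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    w <- fit$window
    tt <- df$lag_s[df$lag_s > w["t_min"] & df$lag_s <= w["t_max"]]
    if (length(tt) >= 2) {
      fl <- tibble(lag_s = tt, msd_nm2 = fit$A * tt^fit$alpha)
      p <- p + ggplot2::geom_line(data = fl, linetype = "dashed",
                                  color = "red")
    }
  }
  p
}

#' Plot a force-distance curve
#'
#' @param object An fd-curve data frame (e.g. from [synth_fd_curve()]).
#' @param peaks Optional peak table from [detect_adhesion_peaks()] drawn as
#'   points.
#' @param ... Unused.
#' @return A ggplot: force vs separation, colored by segment.
#' @export
autoplot.fd_curve <- function(object, peaks = NULL, ...) {
  df <- as_tibble(as.data.frame(object))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$separation_nm, .data$force_nN,
                                        color = .data$segment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "separation (nm)", y = "force (nN)") +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks) > 0) {
    p <- p + ggplot2::geom_point(
      data = peaks, ggplot2::aes(.data$separation_nm, .data$force_nN),
      inherit.aes = FALSE, color = "red", shape = 4, size = 2)
  }
  p
}

#' Amplitude-versus-force plot of a sweep
#'
#' @param sweep Output of [sweep_adhesion_force()].
#' @return A ggplot: per-force mean amplitude with SD error bars.
#' @export
plot_sweep <- function(sweep) {
  s <- summarize_sweep(sweep)
  ggplot2::ggplot(s, ggplot2::aes(.data$mean_amplitude_nm,
                                  .data$force_N * 1e12)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data$mean_amplitude_nm - .data$sd_amplitude_nm,
      xmax = .data$mean_amplitude_nm + .data$sd_amplitude_nm),
      height = 0) +
    ggplot2::labs(x = "vibration amplitude (nm)",
                  y = "tether adhesion force (pN)") +
    ggplot2::theme_minimal()
}
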