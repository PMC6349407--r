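#' Polar histogram of trajectory angles
#'
#' Rose plot of an angle collection with 0 degrees (the midline axis)
#' pointing up and 90 degrees (lateral) to the right.
#'
#' @param angles Numeric vector of angles in degrees.
#' @param n_bins Number of bins.
#' @return A ggplot object.
#' @export
plot_polar_histogram <- function(angles, n_bins = 24) {
  h <- polar_histogram(angles, n_bins)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_mid, y = .data$fraction)) +
    ggplot2::geom_col(width = 360 / n_bins, fill = "seagreen",
                      colour = "grey30", linewidth = 0.2) +
    ggplot2::coord_polar(start = pi, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(-180, 180),
                                breaks = seq(-180, 135, by = 45)) +
    ggplot2::labs(x = "trajectory angle (deg, 0 = midline, 90 = lateral)",
                  y = "fraction of cells") +
    ggplot2::theme_minimal()
}

#' Soma speed profile of one cell
#'
#' Instantaneous speed over time with the rest cutoff marked, the kind of
#' per-cell profile in which rare fast spurts stand out over a
#' rest-dominated baseline.
#'
#' @param pop A [population()].
#' @param cell_id Cell to plot.
#' @param bands A [speed_bands()].
#' @return A ggplot object.
#' @export
plot_speed_profile <- function(pop, cell_id, bands = speed_bands()) {
  pos <- track_positions(pop, cell_id)
  sp <- instantaneous_speeds(pos, pop$dt)
  d <- tibble(t_hr = seq_along(sp) * pop$dt, speed = sp)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t_hr, y = .data$speed)) +
    ggplot2::geom_line(colour = "grey20") +
    ggplot2::geom_hline(yintercept = bands$rest_max, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::geom_hline(yintercept = mean(sp), linetype = "dotted") +
    ggplot2::labs(x = "time (hr)", y = "soma speed (um/hr)",
                  title = cell_id) +
    ggplot2::theme_minimal()
}
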