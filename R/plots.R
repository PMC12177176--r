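# ggplot2 views of the result tables: the 2D projection map of the eye,
# gaze sweeps on the virtual sphere, and the pitch-versus-speed curve.

#' Plot the 2D projection map of an eye
#'
#' Azimuth-elevation scatter of all ommatidial visual axes, coloured by
#' the per-facet mean interommatidial angle, shaped by eye section.
#'
#' @param map An [eye_map()] tibble (or `eye_report$map`).
#' @return A ggplot object.
#' @export
plot_eye_map <- function(map) {
  ggplot2::ggplot(map, ggplot2::aes(
    x = .data$azimuth, y = .data$elevation,
    colour = .data$interommatidial_angle, shape = .data$section)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_colour_viridis_c(name = "interommatidial\nangle (deg)") +
    ggplot2::labs(x = "azimuth (deg)", y = "elevation (deg)") +
    ggplot2::theme_minimal()
}

#' Plot gaze sweeps on the virtual sphere
#'
#' Mean-gaze azimuth/elevation trajectories per eye section as the body
#' rotates about one or more axes.
#'
#' @param sweeps A [gaze_sweep()] tibble (possibly several axes bound
#'   together, as in `eye_report$sweeps`).
#' @return A ggplot object.
#' @export
plot_gaze_sweep <- function(sweeps) {
  ggplot2::ggplot(dplyr::filter(sweeps, !.data$flagged),
                  ggplot2::aes(x = .data$azimuth, y = .data$elevation,
                               colour = .data$angle,
                               group = .data$section)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_grid(section ~ axis) +
    ggplot2::scale_colour_viridis_c(name = "body angle (deg)") +
    ggplot2::labs(x = "azimuth (deg)", y = "elevation (deg)") +
    ggplot2::theme_minimal()
}

#' Plot the speed-binned body-pitch curve
#'
#' @param binned A [bin_pitch_by_speed()] tibble (or
#'   `flight_report$binned`).
#' @return A ggplot object.
#' @export
plot_pitch_speed <- function(binned) {
  ggplot2::ggplot(binned, ggplot2::aes(x = .data$bin_center,
                                       y = .data$pitch_mean)) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$pitch_mean - .data$pitch_sd,
      ymax = .data$pitch_mean + .data$pitch_sd), width = 0.4, na.rm = TRUE) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "forward speed (cm/s)", y = "body pitch (deg)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot methods for pipeline reports
#'
#' An `eye_report` plots its 2D projection map; a `flight_report` its
#' speed-binned pitch curve.
#'
#' @param object An `eye_report` or `flight_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot eye_report
#' @export
autoplot.eye_report <- function(object, ...) {
  plot_eye_map(object$map)
}

#' @rdname autoplot.eye_report
#' @method autoplot flight_report
#' @export
autoplot.flight_report <- function(object, ...) {
  plot_pitch_speed(object$binned)
}
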