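# ggplot2 displays for scenarios and assessment results.

#' Plot a scenario map
#'
#' Lake perimeter, hydrophone array and stationary trial sites coloured by
#' habitat.
#'
#' @param object An `apt_scenario`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot apt_scenario
#' @export
autoplot.apt_scenario <- function(object, ...) {
  st <- object$trials %>% filter(.data$kind == "stationary")
  ggplot2::ggplot() +
    ggplot2::geom_polygon(data = object$lake$perimeter,
                          ggplot2::aes(x = .data$x, y = .data$y),
                          fill = "aliceblue", colour = "steelblue4") +
    ggplot2::geom_point(data = st,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$habitat), size = 1.6) +
    ggplot2::geom_point(data = object$hydrophones,
                        ggplot2::aes(x = .data$x, y = .data$y),
                        shape = 17, size = 2.5) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "east (m)", y = "north (m)",
                  title = sprintf("scenario '%s'", object$name),
                  colour = "habitat") +
    ggplot2::theme_minimal()
}

#' Plot per-habitat performance distributions
#'
#' Raw vs filtered per-trial values by habitat, the customary side-by-side
#' display for stationary performance tests.
#'
#' @param object An `apt_assessment`.
#' @param response `"efficiency"`, `"accuracy_m"`, `"precision_m"` or
#'   `"false_movement_m"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot apt_assessment
#' @export
autoplot.apt_assessment <- function(object, response = "efficiency", ...) {
  d <- object$performance %>%
    filter(is.finite(.data[[response]]))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$habitat, y = .data[[response]],
                                  fill = .data$variant)) +
    ggplot2::geom_boxplot(position = ggplot2::position_dodge(width = 0.8),
                          outlier.size = 0.6) +
    ggplot2::labs(x = "habitat", y = response, fill = NULL,
                  title = sprintf("scenario '%s': %s by habitat",
                                  object$scenario_name, response)) +
    ggplot2::theme_minimal()
}

#' Plot a tow trial against its truth track
#'
#' @param assessment An `apt_assessment`.
#' @param simdata The matching `apt_simdata`.
#' @param trial_id Tow trial id.
#' @return A ggplot.
#' @export
plot_tow <- function(assessment, simdata, trial_id) {
  truth <- simdata$truth_tracks %>% filter(.data$trial_id == !!trial_id)
  est <- assessment$fixes %>% filter(.data$transmitter_id == !!trial_id)
  ggplot2::ggplot() +
    ggplot2::geom_path(data = truth,
                       ggplot2::aes(x = .data$dgps_x_m, y = .data$dgps_y_m),
                       colour = "grey50") +
    ggplot2::geom_point(data = est,
                        ggplot2::aes(x = .data$x_m, y = .data$y_m),
                        colour = "firebrick", size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "east (m)", y = "north (m)", title = trial_id) +
    ggplot2::theme_minimal()
}

#' Plot the depth-sensor calibration
#'
#' Reported versus true depth with the fitted no-intercept line.
#'
#' @param assessment An `apt_assessment` with a depth fit.
#' @return A ggplot.
#' @export
plot_depth_calibration <- function(assessment) {
  stopifnot(!is.null(assessment$depth_table))
  d <- assessment$depth_table
  g <- ggplot2::ggplot(d, ggplot2::aes(x = .data$reported_m, y = .data$true_m)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "reported depth (m)", y = "true depth (m)") +
    ggplot2::theme_minimal()
  if (!is.null(assessment$depth_fit)) {
    g <- g + ggplot2::geom_abline(slope = assessment$depth_fit$slope,
                                  intercept = 0, colour = "firebrick")
  }
  g
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
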