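# Per-trial performance statistics: efficiency (data yield), accuracy,
# precision, false movement, tow-track accuracy and track-length bias, and
# depth-sensor calibration inputs.

#' Stationary-trial accuracy and precision
#'
#' Accuracy is the mean Euclidean distance between estimated positions and
#' the true (fixed) position; precision is the sample standard deviation
#' (n - 1) of those distances.
#'
#' @param positions Tibble with `x_m`, `y_m`.
#' @param truth_x,truth_y True transmitter position (m).
#' @return Tibble `accuracy_m`, `precision_m`, `n_positions`. Accuracy is
#'   `NA` with no positions; precision is `NA` with fewer than 2.
#' @export
stationary_accuracy <- function(positions, truth_x, truth_y) {
  n <- nrow(positions)
  if (n == 0) {
    return(tibble(accuracy_m = NA_real_, precision_m = NA_real_,
                  n_positions = 0L))
  }
  d <- sqrt((positions$x_m - truth_x)^2 + (positions$y_m - truth_y)^2)
  tibble(
    accuracy_m = mean(d),
    precision_m = if (n >= 2) sd(d) else NA_real_,
    n_positions = n
  )
}

#' System efficiency (data yield)
#'
#' The percentage of emitted acoustic signals that resulted in an estimated
#' position, after deduplication to at most one position per emission.
#'
#' @param n_positions Number of positions (deduplicated).
#' @param n_emitted Number of emitted acoustic signals (> 0).
#' @return Efficiency in percent.
#' @export
efficiency <- function(n_positions, n_emitted) {
  stopifnot(all(n_emitted > 0), all(n_positions <= n_emitted))
  100 * n_positions / n_emitted
}

#' False movement of a stationary transmitter
#'
#' Positioning error makes a stationary transmitter appear to move; the false
#' movement rate is the mean Euclidean distance between consecutive
#' (time-sorted) positions.
#'
#' @param positions Tibble with `timestamp_s`, `x_m`, `y_m`.
#' @return Metres per position step; `NA` with fewer than 2 positions.
#' @export
false_movement <- function(positions) {
  if (nrow(positions) < 2) return(NA_real_)
  p <- positions %>% arrange(.data$timestamp_s)
  mean(sqrt(diff(p$x_m)^2 + diff(p$y_m)^2))
}

#' Accumulated false movement over a period
#'
#' Extrapolates the per-position false movement rate to the apparent distance
#' a stationary animal would accumulate over `duration`: expected positions =
#' `(duration / burst_interval) * (2/3 if radio_skip) * efficiency/100`,
#' times the per-position rate.
#'
#' @param rate False movement (m per position).
#' @param efficiency_pct Efficiency (%).
#' @param burst_interval Burst interval (s).
#' @param radio_skip Whether every third emission is non-acoustic.
#' @param duration Period (s), e.g. 3600 for the one-hour convention.
#' @return Accumulated apparent distance (m).
#' @export
accumulate_false_movement <- function(rate, efficiency_pct, burst_interval,
                                      radio_skip, duration) {
  stopifnot(burst_interval > 0, duration > 0)
  n_expected <- (duration / burst_interval) *
    (if (radio_skip) 2 / 3 else 1) * efficiency_pct / 100
  rate * n_expected
}

#' Tow-trial accuracy and precision against the DGPS trajectory
#'
#' Per estimated position, the distance is the minimum point-to-segment
#' distance to the ground-truth polyline (exact segment projection, not
#' nearest vertex); accuracy is the mean and precision the standard
#' deviation of these minima.
#'
#' @param positions Tibble with `x_m`, `y_m`.
#' @param truth Truth track tibble with `x_m`, `y_m` (>= 2 vertices).
#' @return Tibble `accuracy_m`, `precision_m`, `n_positions`.
#' @export
tow_accuracy <- function(positions, truth) {
  stopifnot(nrow(truth) >= 2)
  n <- nrow(positions)
  if (n == 0) {
    return(tibble(accuracy_m = NA_real_, precision_m = NA_real_,
                  n_positions = 0L))
  }
  d <- dist_to_polyline(positions$x_m, positions$y_m, truth$x_m, truth$y_m)
  tibble(
    accuracy_m = mean(d),
    precision_m = if (n >= 2) sd(d) else NA_real_,
    n_positions = n
  )
}

#' Total track length of a position sequence
#'
#' @param positions Tibble with `timestamp_s`, `x_m`, `y_m`; sorted by time
#'   before summing consecutive Euclidean distances.
#' @return Length (m); 0 with fewer than 2 positions.
#' @export
track_length <- function(positions) {
  if (nrow(positions) < 2) return(0)
  p <- positions %>% arrange(.data$timestamp_s)
  polyline_length(p$x_m, p$y_m)
}

#' Depth-sensor calibration table
#'
#' Converts raw 0-100 pressure readings to metres with the transmitter's
#' scale factor and pairs the per-trial mean reported depth with the true
#' deployment depth, with the within-trial spread.
#'
#' @param readings Tibble (`transmitter_id`, `raw`).
#' @param truth_depths Tibble (`transmitter_id`, `depth`) of true deployment
#'   depths (m).
#' @param sensor_scale Raw units per metre.
#' @return Tibble per trial: `transmitter_id`, `reported_m` (mean),
#'   `within_sd_m`, `true_m`, `n_readings`.
#' @export
depth_calibration_table <- function(readings, truth_depths, sensor_scale) {
  stopifnot(sensor_scale > 0)
  readings %>%
    mutate(reported = .data$raw / sensor_scale) %>%
    group_by(.data$transmitter_id) %>%
    summarise(reported_m = mean(.data$reported),
              within_sd_m = sd(.data$reported),
              n_readings = n(), .groups = "drop") %>%
    left_join(truth_depths %>% select("transmitter_id", true_m = "depth"),
              by = "transmitter_id")
}

# One position per emission for efficiency accounting: when synthetic
# emission ids are present use them; otherwise collapse by timestamp.
dedup_positions <- function(positions) {
  if ("emission_index" %in% names(positions) &&
      !all(is.na(positions$emission_index))) {
    positions %>%
      group_by(.data$emission_index) %>%
      slice(1) %>%
      ungroup()
  } else {
    positions %>%
      group_by(.data$timestamp_s) %>%
      slice(1) %>%
      ungroup()
  }
}
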