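# Synthetic-data generators: transmitter emission schedules, habitat-dependent
# acoustic detection with multipath outliers, tow tracks, pressure-sensor
# readings and clock-sync beacons.

#' Acoustic emission times of a transmitter
#'
#' Emissions occur on a fixed burst-interval schedule starting at `t_start`;
#' the window is half-open on the right in the sense that emission `k` is
#' included iff `t_start + k * burst_interval <= t_end`. For combined
#' acoustic-radio transmitters (`radio_skip = TRUE`) every third signal is
#' relayed as a radio signal instead of an acoustic one and never reaches the
#' hydrophones: with 1-based emission indices, indices divisible by 3 are
#' dropped from the acoustic schedule.
#'
#' @param burst_interval Seconds between consecutive emissions (> 0).
#' @param t_start,t_end Window in seconds, `t_end >= t_start`.
#' @param radio_skip If `TRUE`, every third emission is non-acoustic.
#' @return Tibble with `emission_index` (1-based, over all emissions including
#'   skipped ones) and `t_emit` (s), acoustic emissions only.
#' @examples
#' simulate_emissions(9.2, 0, 27.6, radio_skip = TRUE)
#' @export
simulate_emissions <- function(burst_interval, t_start, t_end,
                               radio_skip = FALSE) {
  stopifnot(burst_interval > 0, t_end >= t_start)
  k <- 0:floor((t_end - t_start) / burst_interval + 1e-9)
  out <- tibble(emission_index = k + 1L,
                t_emit = t_start + k * burst_interval)
  if (radio_skip) out <- out[out$emission_index %% 3L != 0L, ]
  out
}

# Expected acoustic emission count in a window (bookkeeping identity).
n_acoustic_emissions <- function(burst_interval, t_start, t_end,
                                 radio_skip = FALSE) {
  n_total <- floor((t_end - t_start) / burst_interval + 1e-9) + 1
  n_total - if (radio_skip) floor(n_total / 3) else 0
}

#' Default acoustic propagation / detection model
#'
#' Detection of an emission at a hydrophone is Bernoulli with a logistic
#' range response `p = 1 / (1 + exp((r - r50[habitat]) / slope_k))` where `r`
#' is horizontal range and `r50` the habitat-specific 50%-detection range
#' (shorter in structurally complex vegetated habitats, reflecting signal
#' attenuation). Detected times of arrival carry Gaussian jitter plus, with
#' probability `p_outlier`, a positive exponential multipath delay — the
#' heavy-tailed error component that motivates t-distributed observation
#' noise in the track smoother.
#'
#' @param r50 Named numeric vector, 50%-detection range (m) per habitat code.
#' @param slope_k Logistic steepness (m).
#' @param toa_jitter_sd Gaussian time-of-arrival jitter sd (s).
#' @param p_outlier Probability of a multipath outlier per detection.
#' @param outlier_mean_delay Mean of the exponential multipath delay (s).
#' @return A list of class `apt_propagation`.
#' @export
propagation_model <- function(r50, slope_k = 25, toa_jitter_sd = 1e-4,
                              p_outlier = 0.05, outlier_mean_delay = 5e-3) {
  stopifnot(all(r50 > 0), slope_k > 0, toa_jitter_sd >= 0,
            p_outlier >= 0, p_outlier < 1, outlier_mean_delay > 0)
  structure(list(r50 = r50, slope_k = slope_k, toa_jitter_sd = toa_jitter_sd,
                 p_outlier = p_outlier, outlier_mean_delay = outlier_mean_delay),
            class = "apt_propagation")
}

detection_prob <- function(model, r, habitat) {
  r50 <- model$r50[habitat]
  if (anyNA(r50)) stop("no r50 for habitat(s): ",
                       paste(unique(habitat[is.na(r50)]), collapse = ", "),
                       call. = FALSE)
  1 / (1 + exp((r - unname(r50)) / model$slope_k))
}

#' Simulate per-hydrophone detections of a trial's emissions
#'
#' For each (emission, hydrophone) pair, a detection is drawn independently
#' with the logistic range probability of [propagation_model()]; detected TOA
#' is emission time plus 3-D slant range over the speed of sound, plus
#' Gaussian jitter, plus (with probability `p_outlier`) an exponential
#' multipath delay. Wireless hydrophones additionally shift every TOA by
#' their clock offset and linear drift.
#'
#' @param emissions Tibble from [simulate_emissions()].
#' @param trial One row of a trial plan: needs `trial_id`, `habitat`,
#'   `depth` and either fixed `x`,`y` (stationary) or a `truth` track.
#' @param truth Optional truth track tibble (`time_s`, `x_m`, `y_m`) for tow
#'   trials; for stationary trials leave `NULL` and supply `trial$x`,
#'   `trial$y`.
#' @param hydrophones Tibble with `hydrophone_id`, `x`, `y`, `depth`, `mode`,
#'   and for wireless mode `clock_offset0` (s), `drift_rate` (s/s).
#' @param model An [propagation_model()].
#' @param c_sound Speed of sound (m/s).
#' @param seed Mandatory integer seed.
#' @return Tibble `hydrophone_id`, `transmitter_id`, `emission_index`,
#'   `toa_s` (one row per detection; at most one per hydrophone-emission).
#' @export
simulate_detections <- function(emissions, trial, hydrophones, model,
                                c_sound, seed, truth = NULL) {
  require_seed(seed)
  withr::local_seed(seed)
  n_e <- nrow(emissions)
  n_h <- nrow(hydrophones)
  if (n_e == 0) {
    return(tibble(hydrophone_id = character(), transmitter_id = character(),
                  emission_index = integer(), toa_s = numeric()))
  }
  if (is.null(truth)) {
    sx <- rep(trial$x, n_e); sy <- rep(trial$y, n_e)
  } else {
    sx <- approx(truth$time_s, truth$x_m, xout = emissions$t_emit,
                 rule = 2)$y
    sy <- approx(truth$time_s, truth$y_m, xout = emissions$t_emit,
                 rule = 2)$y
  }
  # matrices n_e x n_h
  dx <- outer(sx, hydrophones$x, "-")
  dy <- outer(sy, hydrophones$y, "-")
  r_h <- sqrt(dx^2 + dy^2)
  dz <- trial$depth - rep(hydrophones$depth, each = n_e)
  r_3d <- sqrt(r_h^2 + dz^2)
  p <- detection_prob(model, as.vector(r_h), trial$habitat)
  det <- runif(n_e * n_h) < p
  idx <- which(det)
  if (length(idx) == 0) {
    return(tibble(hydrophone_id = character(), transmitter_id = character(),
                  emission_index = integer(), toa_s = numeric()))
  }
  e_i <- ((idx - 1) %% n_e) + 1
  h_i <- ((idx - 1) %/% n_e) + 1
  toa <- emissions$t_emit[e_i] + r_3d[idx] / c_sound +
    rnorm(length(idx), 0, model$toa_jitter_sd)
  is_out <- runif(length(idx)) < model$p_outlier
  toa[is_out] <- toa[is_out] + rexp(sum(is_out), 1 / model$outlier_mean_delay)
  wireless <- hydrophones$mode[h_i] == "wireless"
  if (any(wireless)) {
    hw <- h_i[wireless]
    toa[wireless] <- toa[wireless] + hydrophones$clock_offset0[hw] +
      hydrophones$drift_rate[hw] * toa[wireless]
  }
  tibble(
    hydrophone_id = hydrophones$hydrophone_id[h_i],
    transmitter_id = rep(trial$trial_id, length(idx)),
    emission_index = emissions$emission_index[e_i],
    toa_s = toa
  ) %>% arrange(.data$toa_s)
}

#' Simulate a boat tow with DGPS ground truth
#'
#' The boat follows the piecewise-linear waypoint path at constant speed;
#' truth positions are sampled at 1 Hz. The DGPS observation of each truth
#' position carries isotropic Gaussian error (`dgps_sd`, default 0.2 m, the
#' nominal DGPS accuracy bound).
#'
#' @param waypoints Tibble/data frame with columns `x`, `y` (>= 2 rows).
#' @param speed Boat speed (m/s, > 0).
#' @param seed Mandatory integer seed.
#' @param dgps_sd DGPS error sd (m).
#' @param t_start Start time (s).
#' @return Tibble `time_s`, `x_m`, `y_m` (truth), `dgps_x_m`, `dgps_y_m`.
#' @export
simulate_tow <- function(waypoints, speed, seed, dgps_sd = 0.2, t_start = 0) {
  stopifnot(nrow(waypoints) >= 2, speed > 0, dgps_sd >= 0)
  require_seed(seed)
  withr::local_seed(seed)
  total <- polyline_length(waypoints$x, waypoints$y)
  times <- seq(0, floor(total / speed + 1e-9))
  pts <- interp_along_path(waypoints$x, waypoints$y, times * speed)
  n <- length(times)
  tibble(
    time_s = t_start + times,
    x_m = pts$x, y_m = pts$y,
    dgps_x_m = pts$x + rnorm(n, 0, dgps_sd),
    dgps_y_m = pts$y + rnorm(n, 0, dgps_sd)
  )
}

#' Simulate pressure-sensor readings
#'
#' Transmitter pressure sensors report unitless values on a 0-100 scale;
#' the raw reading is `depth * sensor_scale` plus Gaussian sensor noise,
#' clamped to `[0, 100]`.
#'
#' @param trial One trial row with `trial_id` and `depth` (m).
#' @param times Reading times (s).
#' @param sensor_scale Raw units per metre of depth.
#' @param sensor_noise_sd Sensor noise sd in raw units.
#' @param seed Mandatory integer seed.
#' @return Tibble `transmitter_id`, `time_s`, `raw` in `[0, 100]`.
#' @export
simulate_depth_readings <- function(trial, times, sensor_scale,
                                    sensor_noise_sd, seed) {
  require_seed(seed)
  withr::local_seed(seed)
  raw <- trial$depth * sensor_scale + rnorm(length(times), 0, sensor_noise_sd)
  tibble(
    transmitter_id = rep(trial$trial_id, length(times)),
    time_s = times,
    raw = pmin(pmax(raw, 0), 100)
  )
}

#' Simulate a depth-sensor calibration data set
#'
#' Paired (reported, true) depths for the no-intercept calibration
#' regression: true deployment depths are uniform over `depth_range`; the
#' transmitter-reported depth is `true / slope` plus Gaussian error with sd
#' `noise_sd` (the within-trial spread of the sensor), so the regression of
#' true on reported has generating slope `slope`.
#'
#' @param n Number of trials (pairs).
#' @param slope Generating calibration slope.
#' @param noise_sd Reported-depth error sd (m).
#' @param depth_range True-depth range (m).
#' @param seed Mandatory integer seed.
#' @return Tibble `transmitter_id`, `reported_m`, `true_m`.
#' @export
simulate_depth_calibration <- function(n = 155, slope = 1.01,
                                       noise_sd = 0.06,
                                       depth_range = c(0.5, 7.5), seed) {
  require_seed(seed)
  withr::local_seed(seed)
  true <- runif(n, depth_range[1], depth_range[2])
  tibble(
    transmitter_id = sprintf("D%03d", seq_len(n)),
    reported_m = true / slope + rnorm(n, 0, noise_sd),
    true_m = true
  )
}

# Beacon detections for wireless clock synchronisation: each beacon sits at a
# known position and emits on a known schedule; every hydrophone records the
# beacon with the same jitter and clock error as ordinary detections (no
# detection loss — beacons are engineered for reliable reception).
simulate_beacon_log <- function(beacons, beacon_times, hydrophones, model,
                                c_sound, seed) {
  require_seed(seed)
  withr::local_seed(seed)
  if (!"clock_offset0" %in% names(hydrophones)) hydrophones$clock_offset0 <- 0
  if (!"drift_rate" %in% names(hydrophones)) hydrophones$drift_rate <- 0
  grid <- tidyr::expand_grid(beacon_id = beacons$beacon_id,
                             t_emit = beacon_times)
  grid <- grid %>%
    left_join(beacons, by = "beacon_id") %>%
    tidyr::expand_grid(hydrophone_id = hydrophones$hydrophone_id) %>%
    left_join(hydrophones %>%
                select("hydrophone_id", hx = "x", hy = "y", hdepth = "depth",
                       "mode", "clock_offset0", "drift_rate"),
              by = "hydrophone_id")
  r3 <- sqrt((grid$x - grid$hx)^2 + (grid$y - grid$hy)^2 +
               (grid$depth - grid$hdepth)^2)
  toa <- grid$t_emit + r3 / c_sound + rnorm(nrow(grid), 0, model$toa_jitter_sd)
  wireless <- grid$mode == "wireless"
  toa[wireless] <- toa[wireless] + grid$clock_offset0[wireless] +
    grid$drift_rate[wireless] * toa[wireless]
  tibble(
    hydrophone_id = grid$hydrophone_id,
    beacon_id = grid$beacon_id,
    t_emit = grid$t_emit,
    x = grid$x, y = grid$y, depth = grid$depth,
    toa_s = toa
  )
}
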