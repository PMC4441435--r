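# End-to-end scenario runner: positioning -> filtering/smoothing -> per-trial
# metrics -> habitat statistics.

#' Position all detections of a simulated scenario
#'
#' Applies the wireless clock model (when the array is wireless), then runs
#' sub-array TDOA positioning over the full detection log.
#'
#' @param scenario An [build_scenario()] object.
#' @param simdata An [apt_simulate()] result.
#' @return Fix tibble (see [position_all()]); clock fits are attached as
#'   attribute `"clock_fits"`.
#' @export
apt_position <- function(scenario, simdata) {
  log <- simdata$detections
  clock_fits <- tibble()
  if (any(scenario$hydrophones$mode == "wireless")) {
    cc <- apply_clock_model(log, simdata$beacon_log, scenario$hydrophones,
                            scenario$c_sound)
    log <- cc$log
    clock_fits <- cc$clock_fits
  }
  bbox <- c(range(scenario$lake$perimeter$x), range(scenario$lake$perimeter$y))
  fixes <- position_all(log, scenario$subarrays, scenario$hydrophones,
                        scenario$c_sound,
                        toa_jitter_sd = scenario$propagation$toa_jitter_sd,
                        bbox = bbox)
  attr(fixes, "clock_fits") <- clock_fits
  fixes
}

# Local masked grid around a cloud of fixes: full-lake grids are wastefully
# large for a single trial, so the grid covers the fixes' bounding box
# (padded) clipped to the lake perimeter.
local_grid <- function(lake, fixes, spacing, pad = 20) {
  # clip to the lake extent: gross outlier fixes far outside the lake must
  # not blow the grid up (the posterior lives on the lake mask anyway)
  lx <- range(lake$perimeter$x); ly <- range(lake$perimeter$y)
  xr <- c(max(min(fixes$x_m) - pad, lx[1]), min(max(fixes$x_m) + pad, lx[2]))
  yr <- c(max(min(fixes$y_m) - pad, ly[1]), min(max(fixes$y_m) + pad, ly[2]))
  if (diff(xr) < 2 * spacing) xr <- mean(xr) + c(-1, 1) * max(pad, 2 * spacing)
  if (diff(yr) < 2 * spacing) yr <- mean(yr) + c(-1, 1) * max(pad, 2 * spacing)
  rect <- tibble(x = c(xr[1], xr[2], xr[2], xr[1]),
                 y = c(yr[1], yr[1], yr[2], yr[2]))
  g <- build_grid(rect, spacing)
  inside <- matrix(point_in_polygon(
    rep(g$gx, times = length(g$gy)),
    rep(g$gy, each = length(g$gx)), lake$perimeter),
    nrow = length(g$gx))
  g$mask <- g$mask & inside
  if (!any(g$mask)) g$mask <- matrix(TRUE, length(g$gx), length(g$gy))
  g
}

#' Assess a simulated scenario end to end
#'
#' Runs the full pipeline: positioning, two-stage filtering (permissive
#' "raw" and strict + HMM "filtered"), per-trial performance metrics for
#' stationary and tow trials, habitat GLS models with post-hoc letters and
#' back-transformed summaries, false-movement accumulation, and the
#' depth-sensor calibration regression.
#'
#' @param scenario An [build_scenario()] object.
#' @param simdata An [apt_simulate()] result.
#' @param fixes Optional precomputed fixes from [apt_position()].
#' @param smoother_stationary,smoother_tow [smoother_params()] for the two
#'   trial kinds (stationary tags need little process variance; tows move).
#' @param use_variance_structure Passed to [fit_gls()].
#' @return Object of class `apt_assessment`.
#' @export
apt_assess <- function(scenario, simdata, fixes = NULL,
                       smoother_stationary = smoother_params(D = 0.05,
                                                             sigma = 1, nu = 3),
                       smoother_tow = smoother_params(D = 2, sigma = 1, nu = 3),
                       use_variance_structure = "auto") {
  stopifnot(inherits(scenario, "apt_scenario"), inherits(simdata, "apt_simdata"))
  cfg <- scenario$config
  if (is.null(fixes)) fixes <- apt_position(scenario, simdata)
  perimeter <- if (scenario$name == "lake1") scenario$lake$perimeter else NULL
  raw_spec <- raw_filter_spec(perimeter)
  strict_spec <- strict_filter_spec(perimeter)
  recon_tol <- cfg$burst_interval / 4
  perf <- list(); towperf <- list()
  for (i in seq_len(nrow(scenario$trials))) {
    trial <- scenario$trials[i, ]
    tf <- fixes %>% filter(.data$transmitter_id == trial$trial_id)
    n_emitted <- simdata$emissions$n_emitted[
      simdata$emissions$trial_id == trial$trial_id]
    params <- if (trial$kind == "stationary") smoother_stationary
              else smoother_tow
    if (nrow(tf) == 0) {
      variants <- list(raw = tf, filtered = tf)
    } else {
      grid <- local_grid(scenario$lake, tf, cfg$grid_spacing)
      variants <- run_filter_pipeline(tf, raw_spec, strict_spec, grid,
                                      params, recon_tol)
    }
    for (v in c("raw", "filtered")) {
      pos <- variants[[v]]
      pos_dedup <- if (nrow(pos) > 0) dedup_positions(pos) else pos
      eff <- efficiency(min(nrow(pos_dedup), n_emitted), n_emitted)
      if (trial$kind == "stationary") {
        acc <- stationary_accuracy(pos_dedup, trial$dgps_x, trial$dgps_y)
        perf[[paste(trial$trial_id, v)]] <- tibble(
          trial_id = trial$trial_id, habitat = trial$habitat, variant = v,
          n_emitted = n_emitted, n_positions = acc$n_positions,
          efficiency = eff, accuracy_m = acc$accuracy_m,
          precision_m = acc$precision_m,
          false_movement_m = false_movement(pos_dedup)
        )
      } else {
        truth <- simdata$truth_tracks %>%
          filter(.data$trial_id == trial$trial_id)
        ta <- tow_accuracy(pos_dedup,
                           truth %>% select(x_m = "dgps_x_m", y_m = "dgps_y_m"))
        est_len <- track_length(pos_dedup)
        true_len <- polyline_length(truth$dgps_x_m, truth$dgps_y_m)
        towperf[[paste(trial$trial_id, v)]] <- tibble(
          trial_id = trial$trial_id, variant = v,
          n_emitted = n_emitted, n_positions = ta$n_positions,
          efficiency = eff, accuracy_m = ta$accuracy_m,
          precision_m = ta$precision_m,
          est_length_m = est_len, true_length_m = true_len,
          length_ratio = ifelse(true_len > 0, est_len / true_len, NA_real_)
        )
      }
    }
  }
  performance <- bind_rows(perf)
  tow_performance <- bind_rows(towperf)
  stats <- assess_statistics(performance, use_variance_structure)
  # false-movement accumulation over one hour, per habitat (filtered data)
  fm <- performance %>%
    filter(.data$variant == "filtered", is.finite(.data$false_movement_m)) %>%
    group_by(.data$habitat) %>%
    summarise(rate = mean(.data$false_movement_m),
              efficiency = mean(.data$efficiency), .groups = "drop") %>%
    mutate(accumulated_1h_m = accumulate_false_movement(
      .data$rate, .data$efficiency, cfg$burst_interval, cfg$radio_skip, 3600))
  # depth calibration from simulated sensor readings vs true depths
  depth_fit <- NULL; depth_table <- NULL
  if (nrow(simdata$depth_readings) > 0) {
    truth_depths <- scenario$trials %>%
      filter(.data$kind == "stationary") %>%
      select(transmitter_id = "trial_id", "depth")
    depth_table <- depth_calibration_table(simdata$depth_readings,
                                           truth_depths,
                                           cfg$sensor_scale_nominal)
    if (nrow(depth_table) >= 3) {
      depth_fit <- depth_regression(depth_table %>%
                                      rename(true_m = "true_m"))
    }
  }
  structure(list(
    scenario_name = scenario$name, seed = scenario$seed,
    performance = performance, tow_performance = tow_performance,
    gls = stats$fits, posthoc = stats$posthoc, summaries = stats$summaries,
    false_movement = fm, depth_table = depth_table, depth_fit = depth_fit,
    fixes = fixes
  ), class = "apt_assessment")
}

# Habitat GLS models for efficiency / accuracy / precision, raw and filtered.
assess_statistics <- function(performance, use_variance_structure = "auto") {
  fits <- list(); posthoc <- list(); summaries <- list()
  for (v in unique(performance$variant)) {
    pv <- performance %>% filter(.data$variant == v)
    # efficiency: all trials, arcsine sqrt of the proportion
    d_eff <- pv %>%
      mutate(y = transform_response(.data$efficiency / 100, "arcsine"))
    if (length(unique(d_eff$habitat)) >= 2) {
      key <- paste0("efficiency_", v)
      fits[[key]] <- try(fit_gls(d_eff, "y", "habitat",
                                 use_variance_structure,
                                 transform = "arcsine"), silent = TRUE)
    }
    for (resp in c("accuracy_m", "precision_m")) {
      d <- pv %>%
        exclude_sparse_levels(resp) %>%
        mutate(y = transform_response(.data[[resp]], "log_offset"))
      key <- paste0(sub("_m$", "", resp), "_", v)
      if (length(unique(d$habitat)) >= 2) {
        fits[[key]] <- try(fit_gls(d, "y", "habitat", use_variance_structure,
                                   transform = "log_offset"), silent = TRUE)
      }
    }
  }
  fits <- fits[!vapply(fits, inherits, logical(1), "try-error")]
  for (key in names(fits)) {
    posthoc[[key]] <- posthoc_pairwise(fits[[key]])
    summaries[[key]] <- backtransform_summary(fits[[key]])
  }
  list(fits = fits, posthoc = posthoc, summaries = summaries)
}

#' @export
print.apt_assessment <- function(x, ...) {
  cat(sprintf("<apt_assessment '%s'> seed %d\n", x$scenario_name, x$seed))
  ov <- x$performance %>%
    group_by(.data$variant) %>%
    summarise(
      n_trials = dplyr::n_distinct(.data$trial_id),
      mean_efficiency = mean(.data$efficiency),
      median_accuracy_m = median(.data$accuracy_m, na.rm = TRUE),
      median_precision_m = median(.data$precision_m, na.rm = TRUE),
      .groups = "drop")
  cat("stationary trials, overall:\n")
  print(ov)
  if (nrow(x$tow_performance) > 0) {
    tw <- x$tow_performance %>%
      filter(.data$variant == "filtered") %>%
      summarise(n_tows = n(), mean_efficiency = mean(.data$efficiency),
                mean_accuracy_m = mean(.data$accuracy_m, na.rm = TRUE),
                mean_length_ratio = mean(.data$length_ratio, na.rm = TRUE))
    cat("tow trials (filtered):\n")
    print(tw)
  }
  if (!is.null(x$depth_fit)) print(x$depth_fit)
  invisible(x)
}

#' Per-habitat performance report table
#'
#' The customary display: back-transformed mean with the minus/plus-sd band
#' in brackets, per habitat and response, for the chosen variant.
#'
#' @param assessment An [apt_assess()] result.
#' @param variant `"filtered"` (default) or `"raw"`.
#' @return Tibble `response`, `habitat`, `mean`, `lower`, `upper`, `label`.
#' @export
performance_report <- function(assessment, variant = "filtered") {
  keys <- grep(paste0("_", variant, "$"), names(assessment$summaries),
               value = TRUE)
  purrr::map_dfr(keys, function(k) {
    assessment$summaries[[k]] %>%
      mutate(response = sub(paste0("_", variant, "$"), "", k),
             label = sprintf("%.1f (%.1f-%.1f)", .data$mean, .data$lower,
                             .data$upper)) %>%
      select("response", habitat = "level", "mean", "lower", "upper", "label",
             "n")
  })
}
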