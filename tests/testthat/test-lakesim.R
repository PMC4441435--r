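# Synthetic-data generator: emission schedules, detection model, tows,
# sensors, scenarios.

test_that("sound speed matches the fresh-water polynomial and is monotone", {
  # frozen values computed independently from the polynomial coefficients
  expect_equal(sound_speed(17.1), 1473.120, tolerance = 1e-4)
  expect_equal(sound_speed(5.4), 1427.954, tolerance = 1e-4)
  expect_identical(sound_speed(0), 1402.385)
  temps <- seq(0, 30, by = 0.5)
  expect_true(all(diff(sound_speed(temps)) > 0))
  expect_error(sound_speed(-1), "0, 35")
  expect_error(sound_speed(40), "0, 35")
})

test_that("emission schedule follows burst interval and radio skip", {
  em <- simulate_emissions(9.2, 0, 27.6, radio_skip = TRUE)
  expect_equal(em$t_emit, c(0, 9.2, 27.6))      # index 3 (t = 18.4) is radio
  expect_equal(em$emission_index, c(1L, 2L, 4L))
  em2 <- simulate_emissions(2.56, 0, 10)
  expect_equal(em2$t_emit, c(0, 2.56, 5.12, 7.68))
  expect_equal(simulate_emissions(5, 100, 100)$t_emit, 100)
})

test_that("acoustic emission counts satisfy the bookkeeping identity", {
  set.seed(11)
  for (i in 1:50) {
    burst <- runif(1, 0.5, 20)
    t0 <- runif(1, 0, 100)
    t1 <- t0 + runif(1, 0, 2000)
    skip <- i %% 2 == 0
    em <- simulate_emissions(burst, t0, t1, skip)
    n_total <- floor((t1 - t0) / burst + 1e-9) + 1
    n_skip <- if (skip) floor(n_total / 3) else 0
    expect_identical(nrow(em), as.integer(n_total - n_skip))
  }
})

test_that("noise-free wired detections carry exactly geometric TOAs", {
  hyd <- tibble::tibble(hydrophone_id = c("a", "b", "c"),
                        x = c(0, 50, 0), y = c(0, 0, 50),
                        depth = 1, mode = "wired")
  model <- propagation_model(r50 = c(OD = 1e6), slope_k = 1,
                             toa_jitter_sd = 0, p_outlier = 0)
  trial <- tibble::tibble(trial_id = "t1", habitat = "OD",
                          x = 10, y = 20, depth = 2)
  em <- simulate_emissions(5, 0, 20)
  det <- simulate_detections(em, trial, hyd, model, 1450, seed = 3)
  expect_equal(nrow(det), nrow(em) * nrow(hyd))   # certain detection
  hyd_idx <- match(det$hydrophone_id, hyd$hydrophone_id)
  r3 <- sqrt((10 - hyd$x[hyd_idx])^2 + (20 - hyd$y[hyd_idx])^2 +
               (2 - hyd$depth[hyd_idx])^2)
  t_emit <- em$t_emit[match(det$emission_index, em$emission_index)]
  expect_equal(det$toa_s, t_emit + r3 / 1450, tolerance = 1e-12)
})

test_that("empirical detection rate matches the logistic model", {
  hyd <- tibble::tibble(hydrophone_id = "a", x = 0, y = 0,
                        depth = 0, mode = "wired")
  model <- propagation_model(r50 = c(OD = 60), slope_k = 10,
                             toa_jitter_sd = 0, p_outlier = 0)
  em <- simulate_emissions(1, 0, 9999)   # 10^4 Bernoulli trials
  for (r in c(40, 60, 90)) {
    trial <- tibble::tibble(trial_id = "t", habitat = "OD",
                            x = r, y = 0, depth = 0)
    det <- simulate_detections(em, trial, hyd, model, 1450, seed = 7)
    p <- 1 / (1 + exp((r - 60) / 10))
    expect_lt(abs(nrow(det) / nrow(em) - p),
              3 * sqrt(p * (1 - p) / nrow(em)))
  }
})

test_that("detection rate is monotone in range and habitat complexity", {
  hyd <- tibble::tibble(hydrophone_id = "a", x = 0, y = 0,
                        depth = 0, mode = "wired")
  model <- propagation_model(r50 = c(OD = 60, OS = 60, EL = 35, ED = 15),
                             slope_k = 10, toa_jitter_sd = 0, p_outlier = 0)
  em <- simulate_emissions(1, 0, 1999)
  rate <- function(r, hab) {
    trial <- tibble::tibble(trial_id = "t", habitat = hab,
                            x = r, y = 0, depth = 0)
    nrow(simulate_detections(em, trial, hyd, model, 1450, seed = 5)) / nrow(em)
  }
  by_range <- vapply(c(20, 50, 80), rate, numeric(1), hab = "OD")
  expect_true(all(diff(by_range) <= 0))
  by_hab <- vapply(c("OD", "EL", "ED"), rate, numeric(1), r = 40)
  expect_true(all(diff(by_hab) <= 0))
})

test_that("detection simulation demands a seed and is reproducible", {
  hyd <- tibble::tibble(hydrophone_id = "a", x = 0, y = 0,
                        depth = 0, mode = "wired")
  model <- propagation_model(r50 = c(OD = 60))
  trial <- tibble::tibble(trial_id = "t", habitat = "OD",
                          x = 30, y = 0, depth = 0)
  em <- simulate_emissions(1, 0, 50)
  expect_error(simulate_detections(em, trial, hyd, model, 1450),
               "seed")
  d1 <- simulate_detections(em, trial, hyd, model, 1450, seed = 9)
  d2 <- simulate_detections(em, trial, hyd, model, 1450, seed = 9)
  expect_identical(d1, d2)
})

test_that("tow simulation samples the path at 1 Hz at constant speed", {
  wp <- tibble::tibble(x = c(0, 60), y = c(0, 0))
  tow <- simulate_tow(wp, speed = 0.6, seed = 2)
  expect_identical(nrow(tow), 101L)
  expect_equal(c(tow$x_m[101], tow$y_m[101]), c(60, 0))
  # speeds between samples are constant
  expect_equal(diff(tow$x_m), rep(0.6, 100))
  tow0 <- simulate_tow(wp, speed = 0.6, seed = 2, dgps_sd = 0)
  expect_equal(tow0$dgps_x_m, tow0$x_m)
  expect_equal(tow0$dgps_y_m, tow0$y_m)
})

test_that("tow truth length equals the waypoint polyline length", {
  set.seed(21)
  for (i in 1:5) {
    # segment lengths are whole multiples of the per-second step so the 1 Hz
    # samples hit every vertex and the polyline length is recovered exactly
    speed <- runif(1, 0.3, 1)
    seg <- sample(20:60, 3) * speed
    ang <- runif(3, 0, 2 * pi)
    wp <- tibble::tibble(x = cumsum(c(0, seg * cos(ang))),
                         y = cumsum(c(0, seg * sin(ang))))
    tow <- simulate_tow(wp, speed, seed = i, dgps_sd = 0)
    len_out <- polyline_length(tow$x_m, tow$y_m)
    len_wp <- polyline_length(wp$x, wp$y)
    expect_equal(len_out, len_wp, tolerance = 1e-6)
    # and with vertices off the sampling times, chord cutting can only
    # shorten the recovered length
    tow2 <- simulate_tow(wp, speed * 1.07, seed = i, dgps_sd = 0)
    expect_lte(polyline_length(tow2$x_m, tow2$y_m), len_wp + 1e-6)
  }
})

test_that("depth readings scale, clamp and carry the set noise level", {
  trial <- tibble::tibble(trial_id = "t", depth = 2)
  r <- simulate_depth_readings(trial, times = 1:5, sensor_scale = 10,
                               sensor_noise_sd = 0, seed = 1)
  expect_equal(r$raw, rep(20, 5))
  deep <- tibble::tibble(trial_id = "t", depth = 20)
  r2 <- simulate_depth_readings(deep, 1:5, 10, 0, seed = 1)
  expect_equal(r2$raw, rep(100, 5))
  r3 <- simulate_depth_readings(trial, seq_len(500), 10, 0.6, seed = 4)
  expect_gt(sd(r3$raw), 0.5)
  expect_lt(sd(r3$raw), 0.7)
})

test_that("scenarios match their lake descriptions and are deterministic", {
  sc2 <- small_lake2_scenario(seed = 5)
  expect_identical(nrow(sc2$hydrophones), 8L)
  expect_true(all(sc2$hydrophones$mode == "wired"))
  expect_false(any(c("SA", "SD") %in% sc2$trials$habitat))
  sc1 <- build_scenario("lake1", seed = 5, trial_duration = 50,
                        stationary_counts = c(OD = 2), n_tows = 0)
  expect_identical(nrow(sc1$hydrophones), 20L)
  expect_true(all(sc1$hydrophones$mode == "wireless"))
  spacing <- mean(dist(cbind(sc1$hydrophones$x, sc1$hydrophones$y)))
  expect_gt(spacing, 272 / 2)
  expect_lt(spacing, 272 * 2)
  expect_identical(length(unique(sc1$subarrays$subarray_id)), 13L)
  expect_true(all(table(sc1$subarrays$subarray_id) <= 8))
  # determinism: identical scenario and identical simulated streams
  sc2b <- small_lake2_scenario(seed = 5)
  expect_equal(sc2, sc2b)
  s1 <- apt_simulate(sc2); s2 <- apt_simulate(sc2b)
  expect_identical(s1$detections, s2$detections)
  expect_identical(s1$truth_tracks, s2$truth_tracks)
  expect_identical(s1$depth_readings, s2$depth_readings)
})

test_that("trial sites lie inside the lake in their declared habitat", {
  sc <- small_lake2_scenario(seed = 8)
  st <- sc$trials[sc$trials$kind == "stationary", ]
  expect_true(all(point_in_polygon(st$x, st$y, sc$lake$perimeter)))
  expect_identical(lake_habitat(sc$lake, st$x, st$y), st$habitat)
  expect_true(all(lake_depth(sc$lake, st$x, st$y) >= 0))
  expect_true(all(point_in_polygon(sc$hydrophones$x, sc$hydrophones$y,
                                   sc$lake$perimeter)))
})

test_that("unknown scenario name is refused, seed is mandatory", {
  expect_error(build_scenario("lake3", seed = 1))
  expect_error(build_scenario("lake2"), "seed")
})
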