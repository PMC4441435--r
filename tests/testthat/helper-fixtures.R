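# Shared fixtures: random solver geometries and small synthetic lakes,
# generated in code at test time.

# Random non-degenerate TDOA geometry: n_h hydrophones in a 100 m square,
# source in the central region (inside the hull with high probability).
# Four or more hydrophones: three-hydrophone TDOA fixes are generically
# two-fold ambiguous, which is a property of the geometry, not the solver.
random_geometry <- function(n_h = 5, seed = 1) {
  stopifnot(n_h >= 4)
  set.seed(seed)
  repeat {
    hyd <- tibble::tibble(
      hydrophone_id = sprintf("h%d", seq_len(n_h)),
      x = runif(n_h, 0, 100), y = runif(n_h, 0, 100)
    )
    M <- cbind(hyd$x - mean(hyd$x), hyd$y - mean(hyd$y))
    sv <- svd(M, nu = 0, nv = 0)$d
    if (sv[2] <= 10) next   # demand comfortably non-collinear geometry
    src <- c(runif(1, 30, 70), runif(1, 30, 70))
    # keep the source clear of every hydrophone: the TDOA model is singular
    # at a hydrophone position
    if (min(sqrt((src[1] - hyd$x)^2 + (src[2] - hyd$y)^2)) > 5) break
  }
  list(hyd = hyd, src = src)
}

exact_toas <- function(geom, c_sound = 1450, t_emit = 0) {
  r <- sqrt((geom$src[1] - geom$hyd$x)^2 + (geom$src[2] - geom$hyd$y)^2)
  tibble::tibble(hydrophone_id = geom$hyd$hydrophone_id,
                 toa_s = t_emit + r / c_sound)
}

square_lake <- function(half = 50) {
  tibble::tibble(x = c(-half, half, half, -half),
                 y = c(-half, -half, half, half))
}

# Fixes of a stationary tag with t-like error: Gaussian core plus a fraction
# of gross outliers (positive exponential displacement in a random direction).
stationary_fixes <- function(n = 200, truth = c(0, 0), sd = 1,
                             p_outlier = 0.1, outlier_scale = 15,
                             dt = 10, seed = 1) {
  set.seed(seed)
  x <- truth[1] + rnorm(n, 0, sd)
  y <- truth[2] + rnorm(n, 0, sd)
  out <- runif(n) < p_outlier
  n_out <- sum(out)
  if (n_out > 0) {
    th <- runif(n_out, 0, 2 * pi)
    d <- rexp(n_out, 1 / outlier_scale)
    x[out] <- x[out] + d * cos(th)
    y[out] <- y[out] + d * sin(th)
  }
  tibble::tibble(timestamp_s = dt * (seq_len(n) - 1), x_m = x, y_m = y)
}

# Tiny lake2-like scenario used by several pipeline tests.
small_lake2_scenario <- function(seed = 42, duration = 80,
                                 counts = c(OS = 3, OD = 4, EL = 2, ED = 2),
                                 n_tows = 1, ...) {
  build_scenario("lake2", seed = seed, trial_duration = duration,
                 stationary_counts = counts, n_tows = n_tows, ...)
}
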