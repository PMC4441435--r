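# Grid-based hidden Markov model track smoothing.
#
# The lake is discretised into grid cells (masked to the perimeter); the
# transmitter's movement is a Gaussian random walk with per-axis variance
# 2 * D * dt between consecutive observation timestamps, and each fix is an
# observation of the true cell with isotropic bivariate t-distributed error —
# heavy tails absorb the multipath outliers that contaminate TDOA fixes.
# Forward-backward smoothing yields a posterior distribution per timestamp;
# its mean is the smoothed ("filtered") position. Smoothing never changes
# the number of positions: one output per distinct input timestamp.

#' Smoother parameters
#'
#' @param D Diffusion coefficient of the movement prior (m^2/s, >= 0).
#' @param sigma Observation error scale (m, > 0).
#' @param nu Degrees of freedom of the t observation error (> 0; `Inf` gives
#'   the Gaussian limit). Default 3: strong heavy tail.
#' @return List of class `apt_smoother_params`.
#' @export
smoother_params <- function(D = 0.05, sigma = 1, nu = 3) {
  stopifnot(D >= 0, sigma > 0, nu > 0)
  structure(list(D = D, sigma = sigma, nu = nu),
            class = "apt_smoother_params")
}

#' Build a masked positioning grid over a lake
#'
#' Regular cell centres cover the perimeter's bounding box at the given
#' spacing; cells whose centres fall outside the perimeter are masked out.
#'
#' @param perimeter Polygon tibble (`x`, `y`).
#' @param spacing Cell size (m, > 0); pick it below the accuracy you care
#'   about.
#' @return List of class `apt_grid`: `gx`, `gy` (cell-centre coordinates),
#'   `mask` (logical `length(gx)` x `length(gy)` matrix, `TRUE` inside),
#'   `spacing`.
#' @export
build_grid <- function(perimeter, spacing) {
  stopifnot(spacing > 0)
  xr <- range(perimeter$x); yr <- range(perimeter$y)
  if (spacing > diff(xr) || spacing > diff(yr)) {
    stop("`spacing` exceeds the lake extent", call. = FALSE)
  }
  gx <- seq(xr[1] + spacing / 2, xr[2], by = spacing)
  gy <- seq(yr[1] + spacing / 2, yr[2], by = spacing)
  pts <- expand.grid(x = gx, y = gy)
  mask <- matrix(point_in_polygon(pts$x, pts$y, perimeter),
                 nrow = length(gx), ncol = length(gy))
  if (!any(mask)) stop("no grid cells inside the perimeter", call. = FALSE)
  structure(list(gx = gx, gy = gy, mask = mask, spacing = spacing),
            class = "apt_grid")
}

# 1-D Gaussian transition kernel between cell centres, column-normalised so
# the operator conserves probability mass (reflecting at the bounding box).
transition_kernel_1d <- function(centres, sd) {
  n <- length(centres)
  if (sd <= 0) return(diag(n))
  K <- outer(centres, centres, function(a, b) {
    exp(-(a - b)^2 / (2 * sd^2))
  })
  sweep(K, 2, colSums(K), "/")
}

# Diffuse a probability matrix P (nx x ny) by one time gap and truncate to
# the lake mask. Mass diffusing out of the lake is absorbed (sub-stochastic
# operator); the forward scaling constants account for it, so the smoother is
# exact for the shore-truncated movement model.
diffuse_mask <- function(P, Kx, Ky, mask) {
  Q <- Kx %*% P %*% Ky
  Q[!mask] <- 0
  Q
}

# Observation likelihood over the grid for all fixes sharing one timestamp:
# product of isotropic bivariate t (or Gaussian when nu = Inf) densities.
obs_likelihood <- function(xs, ys, grid, params) {
  nx <- length(grid$gx); ny <- length(grid$gy)
  logL <- matrix(0, nx, ny)
  for (i in seq_along(xs)) {
    D2 <- outer((grid$gx - xs[i])^2, (grid$gy - ys[i])^2, "+")
    if (is.infinite(params$nu)) {
      logL <- logL - D2 / (2 * params$sigma^2)
    } else {
      logL <- logL - (params$nu + 2) / 2 *
        log1p(D2 / (params$nu * params$sigma^2))
    }
  }
  L <- exp(logL - max(logL[grid$mask]))
  L[!grid$mask] <- 0
  if (!is.infinite(params$nu)) {
    reach <- 6 * params$sigma * sqrt(params$nu)
    dmin <- sqrt(min(outer((grid$gx - mean(xs))^2,
                           (grid$gy - mean(ys))^2, "+")[grid$mask]))
    if (dmin > reach) {
      warning("fix farther than 6*sigma*sqrt(nu) from every grid cell; ",
              "observation treated as near-uninformative")
      L[grid$mask] <- 1
    }
  }
  L
}

#' Forward-backward HMM smoothing of position fixes on a grid
#'
#' @param fixes Fix tibble with `timestamp_s`, `x_m`, `y_m`; multiple fixes
#'   may share a timestamp (duplicate sub-array fixes after timestamp
#'   reconciliation) and are combined into one observation.
#' @param grid An [build_grid()] grid covering the fixes.
#' @param params An [smoother_params()].
#' @return Tibble `timestamp_s`, `x_m`, `y_m` (posterior means), `sd_m`
#'   (posterior total sd, `sqrt(E||z - mean||^2)`), `n_fixes`; one row per
#'   distinct input timestamp. The forward log-likelihood is attached as
#'   attribute `"loglik"`.
#' @export
hmm_smooth <- function(fixes, grid, params) {
  stopifnot(inherits(grid, "apt_grid"), inherits(params, "apt_smoother_params"))
  if (nrow(fixes) == 0) {
    out <- tibble(timestamp_s = numeric(), x_m = numeric(), y_m = numeric(),
                  sd_m = numeric(), n_fixes = integer())
    attr(out, "loglik") <- 0
    return(out)
  }
  groups <- fixes %>%
    arrange(.data$timestamp_s) %>%
    group_by(.data$timestamp_s) %>%
    summarise(xs = list(.data$x_m), ys = list(.data$y_m),
              n_fixes = n(), .groups = "drop")
  n_t <- nrow(groups)
  Ls <- lapply(seq_len(n_t), function(i) {
    obs_likelihood(groups$xs[[i]], groups$ys[[i]], grid, params)
  })
  dts <- diff(groups$timestamp_s)
  kern <- kernel_cache(grid, params$D, dts)
  # forward pass
  prior <- grid$mask / sum(grid$mask)
  fwd <- vector("list", n_t)
  loglik <- 0
  pred <- prior
  for (t in seq_len(n_t)) {
    if (t > 1) pred <- diffuse_mask(fwd[[t - 1]], kern$Kx[[kern$id[t - 1]]],
                                    kern$Ky[[kern$id[t - 1]]], grid$mask)
    a <- pred * Ls[[t]]
    s <- sum(a)
    if (s <= 0) stop("zero forward probability at timestamp ",
                     groups$timestamp_s[t], call. = FALSE)
    loglik <- loglik + log(s)
    fwd[[t]] <- a / s
  }
  # backward pass
  bwd <- matrix(1, length(grid$gx), length(grid$gy))
  out <- vector("list", n_t)
  for (t in rev(seq_len(n_t))) {
    post <- fwd[[t]] * bwd
    post <- post / sum(post)
    out[[t]] <- posterior_moments(post, grid)
    if (t > 1) {
      bwd <- diffuse_mask_unnorm(Ls[[t]] * bwd, kern$Kx[[kern$id[t - 1]]],
                                 kern$Ky[[kern$id[t - 1]]], grid$mask)
      bwd <- bwd / max(bwd)
    }
  }
  res <- bind_rows(out) %>%
    mutate(timestamp_s = groups$timestamp_s, n_fixes = groups$n_fixes) %>%
    select("timestamp_s", "x_m", "y_m", "sd_m", "n_fixes")
  attr(res, "loglik") <- loglik
  res
}

# Backward messages need the transpose operator without renormalising to a
# probability (scaling is free); kernels are symmetric up to the column
# normalisation, so apply the transposed normalised kernels.
diffuse_mask_unnorm <- function(P, Kx, Ky, mask) {
  P[!mask] <- 0
  Q <- t(Kx) %*% P %*% t(Ky)
  Q
}

posterior_moments <- function(post, grid) {
  px <- rowSums(post); py <- colSums(post)
  mx <- sum(px * grid$gx); my <- sum(py * grid$gy)
  v <- sum(px * (grid$gx - mx)^2) + sum(py * (grid$gy - my)^2)
  tibble(x_m = mx, y_m = my, sd_m = sqrt(max(v, 0)))
}

# Build (and cache by gap) the 1-D kernels for a sequence of time gaps.
kernel_cache <- function(grid, D, dts) {
  if (length(dts) == 0) return(list(Kx = list(), Ky = list(), id = integer()))
  key <- signif(pmax(dts, 0), 8)
  uniq <- unique(key)
  Kx <- lapply(uniq, function(dt) transition_kernel_1d(grid$gx, sqrt(2 * D * dt)))
  Ky <- lapply(uniq, function(dt) transition_kernel_1d(grid$gy, sqrt(2 * D * dt)))
  list(Kx = Kx, Ky = Ky, id = match(key, uniq))
}

#' Forward log-likelihood of fixes under the smoother model
#'
#' @inheritParams hmm_smooth
#' @return Scalar log-likelihood (up to a constant common to all parameter
#'   values on the same grid).
#' @export
hmm_loglik <- function(fixes, grid, params) {
  groups <- fixes %>%
    arrange(.data$timestamp_s) %>%
    group_by(.data$timestamp_s) %>%
    summarise(xs = list(.data$x_m), ys = list(.data$y_m), .groups = "drop")
  n_t <- nrow(groups)
  dts <- diff(groups$timestamp_s)
  kern <- kernel_cache(grid, params$D, dts)
  pred <- grid$mask / sum(grid$mask)
  loglik <- 0
  f_prev <- NULL
  for (t in seq_len(n_t)) {
    if (t > 1) pred <- diffuse_mask(f_prev, kern$Kx[[kern$id[t - 1]]],
                                    kern$Ky[[kern$id[t - 1]]], grid$mask)
    L <- obs_likelihood_raw(groups$xs[[t]], groups$ys[[t]], grid, params)
    a <- pred * L
    s <- sum(a)
    if (s <= 0) return(-Inf)
    loglik <- loglik + log(s)
    f_prev <- a / s
  }
  loglik
}

# Likelihood with proper density normalisation so values are comparable
# across sigma and nu (needed for parameter fitting).
obs_likelihood_raw <- function(xs, ys, grid, params) {
  nx <- length(grid$gx); ny <- length(grid$gy)
  logL <- matrix(0, nx, ny)
  for (i in seq_along(xs)) {
    D2 <- outer((grid$gx - xs[i])^2, (grid$gy - ys[i])^2, "+")
    if (is.infinite(params$nu)) {
      logL <- logL - D2 / (2 * params$sigma^2) - log(2 * pi * params$sigma^2)
    } else {
      # isotropic bivariate t density: (nu/(2*pi*(nu*sigma^2))) is absorbed
      # in the normalising constant 1/(2*pi*sigma^2) * (nu+2-2)/nu ... use
      # the exact constant: f(d) = (1/(2*pi*sigma^2)) * (1 + d^2/(nu sigma^2))^(-(nu+2)/2)
      logL <- logL - (params$nu + 2) / 2 *
        log1p(D2 / (params$nu * params$sigma^2)) -
        log(2 * pi * params$sigma^2)
    }
  }
  L <- exp(logL)
  L[!grid$mask] <- 0
  L
}

#' Fit smoother parameters by maximum likelihood
#'
#' Maximises the forward log-likelihood over the chosen free parameters by a
#' coarse log-scale grid search refined with bounded quasi-Newton
#' (`optim(method = "L-BFGS-B")` on log-parameters); fixed parameters are
#' honoured.
#'
#' @inheritParams hmm_smooth
#' @param free Character subset of `c("D", "sigma", "nu")` to optimise;
#'   empty means return `params` with its likelihood.
#' @param lower,upper Named bounds on the natural scale (defaults: D in
#'   `[1e-4, 10]` m^2/s, sigma in `[0.05, 50]` m, nu in `[0.5, 50]`).
#' @return An `apt_smoother_params` with attributes `"loglik"` and
#'   `"convergence"`.
#' @export
fit_smoother_params <- function(fixes, grid, params = smoother_params(),
                                free = c("D", "sigma"),
                                lower = c(D = 1e-4, sigma = 0.05, nu = 0.5),
                                upper = c(D = 10, sigma = 50, nu = 50)) {
  stopifnot(all(free %in% c("D", "sigma", "nu")))
  if (length(free) == 0) {
    ll <- hmm_loglik(fixes, grid, params)
    attr(params, "loglik") <- ll
    attr(params, "convergence") <- 0L
    return(params)
  }
  if (length(unique(fixes$timestamp_s)) < 20) {
    stop("need >= 20 fixes to fit smoother parameters", call. = FALSE)
  }
  nll <- function(logtheta) {
    p <- params
    p[free] <- exp(logtheta)
    val <- try(hmm_loglik(fixes, grid, p), silent = TRUE)
    if (inherits(val, "try-error") || !is.finite(val)) return(1e10)
    -val
  }
  # coarse grid on log scale
  cand <- lapply(free, function(nm) {
    log(exp(seq(log(lower[[nm]]), log(upper[[nm]]), length.out = 5)))
  })
  grid_cand <- as.matrix(expand.grid(cand))
  vals <- apply(grid_cand, 1, nll)
  start <- grid_cand[which.min(vals), ]
  opt <- optim(start, nll, method = "L-BFGS-B",
               lower = log(unlist(lower[free])),
               upper = log(unlist(upper[free])),
               control = list(factr = 1e9))
  if (!is.finite(opt$value) || opt$value >= 1e10) {
    stop("non-finite likelihood over the whole search range for ",
         paste(free, collapse = ", "), call. = FALSE)
  }
  out <- params
  out[free] <- exp(opt$par)
  attr(out, "loglik") <- -opt$value
  attr(out, "convergence") <- opt$convergence
  out
}

#' Run the two-stage filter + smoother pipeline
#'
#' Stage one (raw positions): permissive quality filter plus optional
#' perimeter filter. Stage two (filtered positions): strict quality filter,
#' timestamp reconciliation of duplicate sub-array fixes, then HMM smoothing;
#' the smoothed posterior means are the filtered positions. Both stages are
#' returned for side-by-side performance assessment.
#'
#' @param fixes Raw fix tibble from [position_all()].
#' @param raw_spec,strict_spec [filter_spec()]s.
#' @param grid [build_grid()] grid.
#' @param params [smoother_params()].
#' @param reconcile_tol Timestamp reconciliation tolerance (s).
#' @return List: `raw` (fix tibble), `filtered` (smoothed tibble).
#' @export
run_filter_pipeline <- function(fixes, raw_spec, strict_spec, grid, params,
                                reconcile_tol = 1) {
  raw <- apply_quality_filter(fixes, raw_spec)$kept
  strict <- apply_quality_filter(fixes, strict_spec)$kept
  if (nrow(strict) == 0) {
    filtered <- tibble(timestamp_s = numeric(), x_m = numeric(),
                       y_m = numeric(), sd_m = numeric(), n_fixes = integer())
  } else {
    strict <- reconcile_timestamps(strict, reconcile_tol)
    filtered <- hmm_smooth(strict, grid, params)
  }
  list(raw = raw, filtered = filtered)
}
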