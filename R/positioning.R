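# Hyperbolic (TDOA) multilateration and per-fix quality metrics.
#
# A position is estimated from the differences in time of arrival of one
# acoustic signal at >= 3 hydrophones of a sub-array. All TDOAs are anchored
# to the earliest-arrival hydrophone (n - 1 independent differences), which
# removes the unknown emission time. The solver minimises the sum of squared
# TDOA residuals by damped Gauss-Newton, initialised from a coarse grid
# search over the lake bounding box (the hyperbolic objective is multimodal).

#' Define sub-arrays over a hydrophone array
#'
#' Positioning software for these systems processes at most eight hydrophones
#' at a time; larger arrays are covered by overlapping ad hoc sub-arrays
#' processed independently. Sub-arrays are built by picking, for each of
#' `n_subarrays` anchor points spread over the array's bounding box, the
#' `max_size` hydrophones nearest that anchor; duplicate member sets are
#' dropped.
#'
#' @param hydrophones Tibble with `hydrophone_id`, `x`, `y`.
#' @param max_size Maximum sub-array size (default 8).
#' @param n_subarrays Number of anchor points (default 13 when the array
#'   exceeds `max_size`, else 1).
#' @return Tibble `subarray_id`, `hydrophone_id` (long format).
#' @export
make_subarrays <- function(hydrophones, max_size = 8, n_subarrays = NULL) {
  stopifnot(max_size >= 3)
  n_h <- nrow(hydrophones)
  if (n_h <= max_size) {
    return(tibble(subarray_id = "A01",
                  hydrophone_id = hydrophones$hydrophone_id))
  }
  if (is.null(n_subarrays)) n_subarrays <- 13
  # anchors: ring + centre over the hydrophone bounding box
  cx <- mean(range(hydrophones$x)); cy <- mean(range(hydrophones$y))
  rx <- diff(range(hydrophones$x)) / 2; ry <- diff(range(hydrophones$y)) / 2
  th <- seq(0, 2 * pi, length.out = n_subarrays)[-n_subarrays]
  ax <- c(cx, cx + 0.6 * rx * cos(th))
  ay <- c(cy, cy + 0.6 * ry * sin(th))
  sets <- lapply(seq_len(n_subarrays), function(i) {
    d <- sqrt((hydrophones$x - ax[i])^2 + (hydrophones$y - ay[i])^2)
    sort(hydrophones$hydrophone_id[order(d)[seq_len(max_size)]])
  })
  sets <- unique(sets)
  bind_rows(lapply(seq_along(sets), function(i) {
    tibble(subarray_id = sprintf("A%02d", i), hydrophone_id = sets[[i]])
  }))
}

#' Group detections of single emissions on a sub-array
#'
#' Detections on the member hydrophones whose TOAs fall within `max_window`
#' of the first detection of the group are taken as one emission; groups with
#' fewer than three hydrophones cannot be positioned and are discarded (they
#' count as unpositioned emissions). At most one detection per hydrophone is
#' kept per group (the earliest).
#'
#' @param log Detection tibble (`hydrophone_id`, `transmitter_id`,
#'   `emission_index`, `toa_s`).
#' @param member_ids Character vector of the sub-array's hydrophone ids.
#' @param max_window Grouping window (s); must be at least the maximum
#'   acoustic travel time across the lake and below the burst interval.
#' @return Tibble like `log` with an added `set_id`; only groups with >= 3
#'   hydrophones are returned.
#' @export
group_detections <- function(log, member_ids, max_window) {
  stopifnot(max_window > 0)
  sub <- log %>%
    filter(.data$hydrophone_id %in% member_ids) %>%
    arrange(.data$transmitter_id, .data$toa_s)
  if (nrow(sub) == 0) return(sub %>% mutate(set_id = integer()))
  out <- sub %>%
    group_by(.data$transmitter_id) %>%
    mutate(set_id = greedy_window_groups(.data$toa_s, max_window)) %>%
    ungroup() %>%
    group_by(.data$transmitter_id, .data$set_id, .data$hydrophone_id) %>%
    slice(1) %>%
    ungroup()
  keep <- out %>%
    dplyr::count(.data$transmitter_id, .data$set_id) %>%
    filter(.data$n >= 3)
  out %>%
    dplyr::semi_join(keep, by = c("transmitter_id", "set_id")) %>%
    arrange(.data$transmitter_id, .data$set_id, .data$toa_s)
}

# Assign group ids by a greedy sweep: a detection starts a new group when its
# TOA is more than `window` after the first TOA of the current group.
greedy_window_groups <- function(toa, window) {
  g <- integer(length(toa))
  cur <- 1L
  start <- toa[1]
  for (i in seq_along(toa)) {
    if (toa[i] - start > window) {
      cur <- cur + 1L
      start <- toa[i]
    }
    g[i] <- cur
  }
  g
}

#' Solve one position by damped Gauss-Newton on anchored TDOA residuals
#'
#' @param detections Tibble with `hydrophone_id`, `toa_s` (one emission, >= 3
#'   hydrophones).
#' @param hydrophones Tibble with `hydrophone_id`, `x`, `y` (positions, m).
#' @param c_sound Speed of sound (m/s).
#' @param init Optional `c(x, y)` starting point; default is a coarse
#'   `grid_n` x `grid_n` search over `bbox`.
#' @param bbox Bounding box `c(xmin, xmax, ymin, ymax)` for the grid search;
#'   default: hydrophone extent padded by 20%.
#' @param grid_n Grid resolution of the initial search (default 20).
#' @param tol Convergence tolerance on the position step (m).
#' @param max_iter Maximum Gauss-Newton iterations.
#' @return A one-row tibble: `x_m`, `y_m`, `t_emit_est`, `rss` (sum of squared
#'   TDOA residuals, s^2), `n_hydrophones`, `converged`, `degenerate`.
#'   Fewer than 3 detections is an error; collinear geometry or
#'   non-convergence is flagged via `degenerate = TRUE`, never silently
#'   returned as a good fix.
#' @export
solve_position <- function(detections, hydrophones, c_sound, init = NULL,
                           bbox = NULL, grid_n = 20, tol = 1e-4,
                           max_iter = 50) {
  d <- detections %>%
    left_join(hydrophones %>% select("hydrophone_id", "x", "y"),
              by = "hydrophone_id")
  n <- nrow(d)
  if (n < 3) stop("insufficient data: need >= 3 detections, got ", n,
                  call. = FALSE)
  if (anyNA(d$x)) stop("unknown hydrophone position", call. = FALSE)
  anchor <- which.min(d$toa_s)
  dt_obs <- d$toa_s[-anchor] - d$toa_s[anchor]   # observed TDOAs (s)
  hx <- d$x; hy <- d$y
  collinear <- {
    M <- cbind(hx - mean(hx), hy - mean(hy))
    s <- svd(M, nu = 0, nv = 0)$d
    s[2] < 1e-9 * max(s[1], 1)
  }
  resid_fn <- function(x, y) {
    r <- sqrt((x - hx)^2 + (y - hy)^2)
    dt_obs - (r[-anchor] - r[anchor]) / c_sound
  }
  gauss_newton <- function(x, y) {
    converged <- FALSE
    rss <- sum(resid_fn(x, y)^2)
    for (iter in seq_len(max_iter)) {
      r <- sqrt((x - hx)^2 + (y - hy)^2)
      r <- pmax(r, 1e-9)
      # Jacobian of predicted TDOA (s) wrt (x, y)
      ux <- (x - hx) / r; uy <- (y - hy) / r
      J <- cbind(ux[-anchor] - ux[anchor], uy[-anchor] - uy[anchor]) / c_sound
      res <- resid_fn(x, y)
      JtJ <- crossprod(J)
      if (rcond_2x2(JtJ) < 1e-14) break
      step <- solve(JtJ, crossprod(J, res))
      lambda <- 1
      repeat {
        x_new <- x + lambda * step[1]; y_new <- y + lambda * step[2]
        rss_new <- sum(resid_fn(x_new, y_new)^2)
        if (rss_new <= rss + 1e-18 || lambda < 1e-6) break
        lambda <- lambda / 2
      }
      moved <- lambda * sqrt(sum(step^2))
      x <- x_new; y <- y_new; rss <- rss_new
      if (moved < tol) { converged <- TRUE; break }
    }
    list(x = x, y = y, rss = rss, converged = converged)
  }
  if (is.null(init)) {
    if (is.null(bbox)) {
      padx <- 0.2 * max(diff(range(hx)), 1)
      pady <- 0.2 * max(diff(range(hy)), 1)
      bbox <- c(min(hx) - padx, max(hx) + padx, min(hy) - pady, max(hy) + pady)
    }
    gx <- seq(bbox[1], bbox[2], length.out = grid_n)
    gy <- seq(bbox[3], bbox[4], length.out = grid_n)
    G <- as.matrix(expand.grid(x = gx, y = gy))
    # vectorised objective over the grid
    D <- sqrt(outer(G[, 1], hx, "-")^2 + outer(G[, 2], hy, "-")^2)
    R <- matrix(dt_obs, nrow(G), n - 1, byrow = TRUE) -
      (D[, -anchor, drop = FALSE] - D[, anchor]) / c_sound
    obj <- rowSums(R^2)
    # multi-start: refine from the best cells of well-separated basins (the
    # hyperbolic objective has shallow secondary minima)
    ord <- order(obj)
    sep <- 2.5 * sqrt((gx[2] - gx[1])^2 + (gy[2] - gy[1])^2)
    starts <- matrix(numeric(0), 0, 2)
    for (k in ord) {
      if (nrow(starts) >= 4) break
      if (nrow(starts) == 0 ||
          all(sqrt((starts[, 1] - G[k, 1])^2 +
                     (starts[, 2] - G[k, 2])^2) > sep)) {
        starts <- rbind(starts, G[k, ])
      }
    }
  } else {
    starts <- matrix(init[1:2], 1, 2)
  }
  x <- starts[1, 1]; y <- starts[1, 2]
  converged <- FALSE
  if (!collinear) {
    best <- NULL
    for (k in seq_len(nrow(starts))) {
      cand <- gauss_newton(starts[k, 1], starts[k, 2])
      if (is.null(best) || cand$rss < best$rss) best <- cand
    }
    x <- best$x; y <- best$y; converged <- best$converged
  }
  r <- sqrt((x - hx)^2 + (y - hy)^2)
  t_emit <- mean(d$toa_s - r / c_sound)
  tibble(
    x_m = x, y_m = y, t_emit_est = t_emit,
    rss = sum(resid_fn(x, y)^2),
    n_hydrophones = n,
    converged = converged,
    degenerate = collinear || !converged
  )
}

rcond_2x2 <- function(M) {
  e <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (max(e) <= 0) return(0)
  min(e) / max(e)
}

#' Per-fix quality metrics: DOP, CN, RN
#'
#' Vendor positioning software ships proprietary quality numbers with each
#' fix; these are documented surrogates with the same filtering semantics:
#'
#' * `dop` — dilution of precision: the exact linear per-axis
#'   error-amplification factor of the anchored-TDOA least-squares
#'   estimator. With `G` the matrix of unit-vector differences (hydrophone
#'   minus anchor, dimensionless), TDOA noise covariance proportional to
#'   `I + 1 1'` (the anchor's jitter is shared by every difference) and
#'   `Cov = (G'G)^-1 G'(I+11')G (G'G)^-1` the unit-noise position
#'   covariance, `dop = sqrt(trace(Cov) / 2)`. The predicted total (2-D)
#'   RMS position scatter under TOA jitter sd `toa_sd` is
#'   `sqrt(2) * dop * c_sound * toa_sd`.
#' * `cn` — condition number: ratio of the largest to smallest singular value
#'   of `G` (geometry stability); `Inf` for collinear geometry.
#' * `rn` — reliability surrogate: detection redundancy `n_hydrophones - 3`,
#'   so the filter thresholds RN > 0 / RN > 1 mean >= 4 / >= 5 hydrophones.
#'
#' @param fix One-row tibble from [solve_position()].
#' @param detections,hydrophones As in [solve_position()].
#' @return Tibble `dop`, `cn`, `rn`.
#' @export
compute_quality <- function(fix, detections, hydrophones) {
  d <- detections %>%
    left_join(hydrophones %>% select("hydrophone_id", "x", "y"),
              by = "hydrophone_id")
  n <- nrow(d)
  anchor <- which.min(d$toa_s)
  r <- sqrt((fix$x_m - d$x)^2 + (fix$y_m - d$y)^2)
  r <- pmax(r, 1e-9)
  ux <- (fix$x_m - d$x) / r; uy <- (fix$y_m - d$y) / r
  G <- cbind(ux[-anchor] - ux[anchor], uy[-anchor] - uy[anchor])
  sv <- svd(G, nu = 0, nv = 0)$d
  # collinear hydrophones cannot resolve the mirror ambiguity: flag outright
  M <- cbind(d$x - mean(d$x), d$y - mean(d$y))
  sh <- svd(M, nu = 0, nv = 0)$d
  if (sh[2] < 1e-9 * max(sh[1], 1) ||
      length(sv) < 2 || sv[2] < 1e-12 * max(sv[1], 1)) {
    return(tibble(dop = Inf, cn = Inf, rn = n - 3L))
  }
  GtG_inv <- solve(crossprod(G))
  m <- n - 1
  S <- diag(m) + matrix(1, m, m)     # anchored-noise covariance / sigma^2
  A <- GtG_inv %*% t(G)
  Cov <- A %*% S %*% t(A)
  tibble(dop = sqrt(sum(diag(Cov)) / 2), cn = sv[1] / sv[2], rn = n - 3L)
}

#' Position every grouped emission on every sub-array
#'
#' Each sub-array is processed independently; one fix is produced per
#' (emission group, sub-array) where the solver succeeds, so the same
#' emission can yield multiple fixes on overlapping sub-arrays (deduplicated
#' downstream by timestamp reconciliation and the HMM).
#'
#' @param log Detection tibble.
#' @param subarrays Tibble from [make_subarrays()].
#' @param hydrophones Hydrophone tibble with positions.
#' @param c_sound Speed of sound (m/s).
#' @param max_window Grouping window (s); default: bounding-box diagonal
#'   travel time plus 6 jitter sd.
#' @param toa_jitter_sd TOA jitter sd used for the default window (s).
#' @param bbox Optional solver search box.
#' @param drop_degenerate Drop flagged (collinear / non-converged) fixes
#'   (default `TRUE`).
#' @return Fix tibble: `transmitter_id`, `timestamp_s`, `x_m`, `y_m`, `dop`,
#'   `cn`, `rn`, `subarray_id`, `n_hydrophones`, plus `emission_index` when
#'   present in `log` (synthetic ground truth bookkeeping).
#' @export
position_all <- function(log, subarrays, hydrophones, c_sound,
                         max_window = NULL, toa_jitter_sd = 1e-4,
                         bbox = NULL, drop_degenerate = TRUE) {
  if (is.null(max_window)) {
    diag_m <- sqrt(diff(range(hydrophones$x))^2 +
                     diff(range(hydrophones$y))^2)
    max_window <- 1.5 * diag_m / c_sound + 6 * toa_jitter_sd
  }
  out <- list()
  for (sid in unique(subarrays$subarray_id)) {
    members <- subarrays$hydrophone_id[subarrays$subarray_id == sid]
    grouped <- group_detections(log, members, max_window)
    if (nrow(grouped) == 0) next
    sets <- split(grouped, interaction(grouped$transmitter_id,
                                       grouped$set_id, drop = TRUE))
    fixes <- lapply(sets, function(s) {
      fix <- solve_position(s, hydrophones, c_sound, bbox = bbox)
      q <- compute_quality(fix, s, hydrophones)
      tibble(
        transmitter_id = s$transmitter_id[1],
        timestamp_s = fix$t_emit_est,
        x_m = fix$x_m, y_m = fix$y_m,
        dop = q$dop, cn = q$cn, rn = q$rn,
        subarray_id = sid,
        n_hydrophones = fix$n_hydrophones,
        degenerate = fix$degenerate,
        emission_index = if ("emission_index" %in% names(s))
          s$emission_index[which.min(s$toa_s)] else NA_integer_
      )
    })
    out[[sid]] <- bind_rows(fixes)
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(transmitter_id = character(), timestamp_s = numeric(),
                  x_m = numeric(), y_m = numeric(), dop = numeric(),
                  cn = numeric(), rn = integer(), subarray_id = character(),
                  n_hydrophones = integer(), degenerate = logical(),
                  emission_index = integer()))
  }
  if (drop_degenerate) res <- res %>% filter(!.data$degenerate)
  res %>% arrange(.data$transmitter_id, .data$timestamp_s)
}

#' Reconcile timestamps of duplicate fixes across sub-arrays
#'
#' Overlapping sub-arrays produce multiple fixes of the same emission whose
#' estimated timestamps differ slightly (clock residuals, different member
#' sets). Fixes of one transmitter within `tol` of each other are assigned
#' one common timestamp — the earliest of the group — so the smoother sees
#' one timestamp per emission.
#'
#' @param fixes Fix tibble (sorted or not).
#' @param tol Grouping tolerance (s); keep below half the burst interval.
#' @return The fix tibble with `timestamp_s` replaced by the group timestamp.
#' @export
reconcile_timestamps <- function(fixes, tol) {
  if (nrow(fixes) == 0) return(fixes)
  fixes %>%
    group_by(.data$transmitter_id) %>%
    arrange(.data$timestamp_s, .by_group = TRUE) %>%
    mutate(.grp = greedy_window_groups(.data$timestamp_s, tol)) %>%
    group_by(.data$transmitter_id, .data$.grp) %>%
    mutate(timestamp_s = min(.data$timestamp_s)) %>%
    ungroup() %>%
    select(-".grp")
}
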