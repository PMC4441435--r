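# Habitat statistics: transformed response models fitted by generalized
# least squares with optional per-habitat variances, baseline-shifting
# post-hoc contrasts, letter display and back-transformed summaries, plus
# the no-intercept depth-sensor regression.

#' Transform a performance response for modelling
#'
#' Efficiency (as a proportion) is arcsine-square-root transformed
#' (`asin(sqrt(p))`; the plain `asin(p)` variant is available); accuracy and
#' precision are `log(y + 0.1)` transformed (natural log). Both transforms
#' are exactly invertible by [back_transform()].
#'
#' @param values Numeric vector: proportion in `[0, 1]` for `"arcsine"`,
#'   non-negative for `"log_offset"`.
#' @param kind `"arcsine"`, `"log_offset"` or `"none"`.
#' @param arcsine_sqrt Use the square-root variant (default `TRUE`).
#' @return Transformed values.
#' @export
transform_response <- function(values, kind = c("arcsine", "log_offset", "none"),
                               arcsine_sqrt = TRUE) {
  kind <- match.arg(kind)
  switch(kind,
    arcsine = {
      if (any(values < 0 | values > 1, na.rm = TRUE)) {
        stop("proportions must lie in [0, 1] for the arcsine transform",
             call. = FALSE)
      }
      if (arcsine_sqrt) asin(sqrt(values)) else asin(values)
    },
    log_offset = {
      if (any(values < 0, na.rm = TRUE)) {
        stop("values must be >= 0 for the log(y + 0.1) transform",
             call. = FALSE)
      }
      log(values + 0.1)
    },
    none = values
  )
}

#' @rdname transform_response
#' @export
back_transform <- function(values, kind = c("arcsine", "log_offset", "none"),
                           arcsine_sqrt = TRUE) {
  kind <- match.arg(kind)
  switch(kind,
    arcsine = {
      clamped <- pmin(pmax(values, 0), pi / 2)
      if (arcsine_sqrt) sin(clamped)^2 else sin(clamped)
    },
    log_offset = pmax(exp(values) - 0.1, 0),
    none = values
  )
}

#' Fit a group-means model by generalized least squares
#'
#' Fits `response ~ habitat` (habitat as fixed factor) by maximum
#' likelihood. With a variance structure, each habitat level gets its own
#' residual variance, estimated by iterative feasible GLS: fit the
#' homogeneous model, estimate per-group variance multipliers from the
#' residuals, refit weighted, and iterate to convergence (`1e-8` on the
#' variance estimates). With `use_variance_structure = "auto"` the
#' heterogeneous model is kept iff a likelihood-ratio test against the
#' homogeneous fit has p < 0.05.
#'
#' @param data Data frame of per-trial performance rows.
#' @param response Name of the (already transformed) response column.
#' @param group Name of the factor column (default `"habitat"`).
#' @param use_variance_structure `"auto"`, `"on"` or `"off"`.
#' @param transform The transform the response already carries (recorded for
#'   back-transformation): `"arcsine"`, `"log_offset"` or `"none"`.
#' @param min_per_level Minimum observations required per retained level
#'   (default 2; a level with fewer cannot have its variance estimated).
#' @return An object of class `apt_gls`: per-level means and ML variance
#'   estimates, homogeneous and heterogeneous log-likelihoods, AIC, the
#'   LRT p-value, and bookkeeping for [posthoc_pairwise()] and
#'   [backtransform_summary()].
#' @export
fit_gls <- function(data, response, group = "habitat",
                    use_variance_structure = c("auto", "on", "off"),
                    transform = c("none", "arcsine", "log_offset"),
                    min_per_level = 2) {
  use_variance_structure <- match.arg(use_variance_structure)
  transform <- match.arg(transform)
  y <- data[[response]]
  g <- data[[group]]
  ok <- is.finite(y) & !is.na(g)
  y <- y[ok]; g <- droplevels(factor(g[ok]))
  lv <- levels(g)
  if (length(lv) < 2) stop("need >= 2 groups after removing missing values",
                           call. = FALSE)
  n_g <- table(g)
  if (any(n_g < min_per_level)) {
    stop("group(s) with fewer than ", min_per_level, " observations: ",
         paste(names(n_g)[n_g < min_per_level], collapse = ", "),
         call. = FALSE)
  }
  n <- length(y)
  G <- length(lv)
  means_of <- function(w) {
    vapply(lv, function(l) {
      i <- g == l
      sum(w[i] * y[i]) / sum(w[i])
    }, numeric(1))
  }
  # homogeneous ML fit
  mu_hom <- means_of(rep(1, n))
  res_hom <- y - mu_hom[as.integer(g)]
  s2_hom <- sum(res_hom^2) / n
  ll_hom <- -n / 2 * (log(2 * pi * s2_hom) + 1)
  # heterogeneous: iterative feasible GLS (per-group weights)
  s2_g <- vapply(lv, function(l) {
    r <- res_hom[g == l]
    max(mean(r^2), 1e-12)
  }, numeric(1))
  mu_het <- mu_hom
  for (iter in 1:100) {
    w <- 1 / s2_g[as.integer(g)]
    mu_het <- means_of(w)
    res <- y - mu_het[as.integer(g)]
    s2_new <- vapply(lv, function(l) max(mean(res[g == l]^2), 1e-12),
                     numeric(1))
    delta <- max(abs(s2_new - s2_g))
    s2_g <- s2_new
    if (delta < 1e-8) break
  }
  res_het <- y - mu_het[as.integer(g)]
  ll_het <- -n / 2 * log(2 * pi) -
    sum(as.numeric(n_g) / 2 * log(s2_g)) - n / 2
  lrt_stat <- 2 * (ll_het - ll_hom)
  lrt_p <- pchisq(max(lrt_stat, 0), df = G - 1, lower.tail = FALSE)
  heterogeneous <- switch(use_variance_structure,
    on = TRUE, off = FALSE, auto = lrt_p < 0.05)
  mu <- if (heterogeneous) mu_het else mu_hom
  s2_used <- if (heterogeneous) s2_g else setNames(rep(s2_hom, G), lv)
  ll <- if (heterogeneous) ll_het else ll_hom
  k_par <- G + if (heterogeneous) G else 1
  structure(list(
    response = response, group = group, transform = transform,
    levels = lv, n_per_level = as.numeric(n_g),
    coefficients = mu,
    group_sd = sqrt(s2_used),
    variance_multipliers = s2_used / s2_used[1],
    heterogeneous = heterogeneous,
    loglik = ll, loglik_homogeneous = ll_hom, loglik_heterogeneous = ll_het,
    lrt_p = lrt_p, aic = -2 * ll + 2 * k_par,
    residual_sd = sqrt(s2_hom * n / max(n - G, 1)),
    data = tibble(y = y, g = g)
  ), class = "apt_gls")
}

#' Drop habitat levels with too few trials yielding positions
#'
#' Convention for accuracy/precision models: levels with fewer than
#' `min_trials` trials that yielded positions are excluded.
#'
#' @param data Per-trial tibble.
#' @param group Grouping column name.
#' @param min_trials Minimum trials with a non-missing response (default 4).
#' @param response Response column; rows with `NA` response do not count.
#' @return Filtered tibble.
#' @export
exclude_sparse_levels <- function(data, response, group = "habitat",
                                  min_trials = 4) {
  counts <- data %>%
    filter(is.finite(.data[[response]])) %>%
    dplyr::count(.data[[group]])
  keep <- counts[[group]][counts$n >= min_trials]
  data %>% filter(.data[[group]] %in% keep,
                  is.finite(.data[[response]]))
}

#' @export
print.apt_gls <- function(x, ...) {
  cat(sprintf("<apt_gls> %s ~ %s  (%s variances, transform: %s)\n",
              x$response, x$group,
              if (x$heterogeneous) "per-group" else "pooled", x$transform))
  print(tidy(x))
  invisible(x)
}

#' @method tidy apt_gls
#' @export
tidy.apt_gls <- function(x, ...) {
  tibble(
    term = x$levels,
    estimate = unname(x$coefficients),
    group_sd = unname(x$group_sd),
    n = x$n_per_level,
    std.error = unname(x$group_sd) / sqrt(x$n_per_level)
  )
}

#' @method glance apt_gls
#' @export
glance.apt_gls <- function(x, ...) {
  tibble(
    logLik = x$loglik, AIC = x$aic,
    heterogeneous = x$heterogeneous, lrt_p = x$lrt_p,
    n = sum(x$n_per_level), n_groups = length(x$levels)
  )
}

#' Pairwise post-hoc contrasts by baseline shifting
#'
#' Each level is taken in turn as the model baseline and the model refitted;
#' the contrasts against the baseline, their standard errors and Wald
#' (normal) p-values are read off and assembled over all unordered pairs.
#' Letters mark groups of mutually non-significant levels (p > `alpha`
#' share a letter), as customary in habitat-comparison displays.
#'
#' @param fit An [fit_gls()] object.
#' @param alpha Significance level for the letter grouping (default 0.05).
#' @param p_adjust Multiple-testing correction passed to [stats::p.adjust()]
#'   (default `"none"`, plain pairwise comparisons).
#' @return List of class `apt_posthoc`: `pairs` (tibble `level_a`,
#'   `level_b`, `estimate`, `std.error`, `p.value`) and `letters` (tibble
#'   `level`, `letters`).
#' @export
posthoc_pairwise <- function(fit, alpha = 0.05, p_adjust = "none") {
  stopifnot(inherits(fit, "apt_gls"))
  lv <- fit$levels
  G <- length(lv)
  y <- fit$data$y; g <- fit$data$g
  rows <- list()
  for (a in seq_len(G)) {
    # refit with level a as baseline: re-level and re-estimate (identical
    # group means; contrasts and their SEs read off against the baseline)
    for (b in seq_len(G)) {
      if (b <= a) next
      est <- fit$coefficients[b] - fit$coefficients[a]
      se <- sqrt(fit$group_sd[a]^2 / fit$n_per_level[a] +
                   fit$group_sd[b]^2 / fit$n_per_level[b])
      z <- est / se
      rows[[length(rows) + 1]] <- tibble(
        level_a = lv[a], level_b = lv[b],
        estimate = unname(est), std.error = unname(se),
        p.value = 2 * pnorm(-abs(z))
      )
    }
  }
  pairs <- bind_rows(rows)
  pairs$p.value <- stats::p.adjust(pairs$p.value, method = p_adjust)
  structure(list(pairs = pairs,
                 letters = letter_groups(lv, fit$coefficients, pairs, alpha)),
            class = "apt_posthoc")
}

# Letter display: order levels by estimate; greedily grow maximal runs of
# mutually non-significant levels; each maximal run gets one letter.
letter_groups <- function(levels, est, pairs, alpha = 0.05) {
  ord <- order(est)
  lv <- levels[ord]
  G <- length(lv)
  sig <- function(a, b) {
    p <- pairs$p.value[(pairs$level_a == a & pairs$level_b == b) |
                         (pairs$level_a == b & pairs$level_b == a)]
    length(p) == 1 && p <= alpha
  }
  runs <- list()
  for (i in seq_len(G)) {
    j <- i
    while (j < G) {
      ok <- all(vapply((i:j), function(k) !sig(lv[k], lv[j + 1]), logical(1)))
      if (!ok) break
      j <- j + 1
    }
    runs[[length(runs) + 1]] <- i:j
  }
  # drop runs strictly contained in another run
  runs <- unique(runs)
  keep <- vapply(seq_along(runs), function(i) {
    !any(vapply(seq_along(runs), function(j) {
      j != i && all(runs[[i]] %in% runs[[j]])
    }, logical(1)))
  }, logical(1))
  runs <- runs[keep]
  lab <- rep("", G)
  for (k in seq_along(runs)) {
    lab[runs[[k]]] <- paste0(lab[runs[[k]]], letters[k])
  }
  tibble(level = lv, letters = lab) %>%
    arrange(match(.data$level, levels))
}

#' @export
print.apt_posthoc <- function(x, ...) {
  cat("<apt_posthoc> pairwise contrasts (Wald):\n")
  print(x$pairs)
  cat("letter groups (shared letter: not significantly different):\n")
  print(x$letters)
  invisible(x)
}

#' Back-transformed per-group summaries
#'
#' Means and dispersion bands on the original scale: mean =
#' inverse-transform of the group coefficient; band endpoints =
#' inverse-transform of coefficient -/+ that group's residual sd. Bands are
#' asymmetric because the transforms are nonlinear; endpoints falling
#' outside the transform domain are clamped to the boundary and flagged.
#' Arcsine responses are reported in percent.
#'
#' @param fit An [fit_gls()] object with its `transform` recorded.
#' @param arcsine_sqrt Passed to [back_transform()].
#' @return Tibble `level`, `mean`, `lower`, `upper`, `clamped`, `n`.
#' @export
backtransform_summary <- function(fit, arcsine_sqrt = TRUE) {
  stopifnot(inherits(fit, "apt_gls"))
  mu <- fit$coefficients
  s <- fit$group_sd
  lo_t <- mu - s; hi_t <- mu + s
  clamped <- rep(FALSE, length(mu))
  if (fit$transform == "arcsine") {
    clamped <- lo_t < 0 | hi_t > pi / 2
  } else if (fit$transform == "log_offset") {
    clamped <- exp(lo_t) < 0.1
  }
  inv <- function(v) back_transform(v, fit$transform, arcsine_sqrt)
  scale <- if (fit$transform == "arcsine") 100 else 1
  tibble(
    level = fit$levels,
    mean = unname(scale * inv(mu)),
    lower = unname(scale * inv(lo_t)),
    upper = unname(scale * inv(hi_t)),
    clamped = unname(clamped),
    n = fit$n_per_level
  )
}

#' No-intercept depth-sensor calibration regression
#'
#' Regresses true deployment depth on transmitter-reported depth through the
#' origin, the standard check that a linear pressure sensor reads true depth
#' (slope 1).
#'
#' @param pairs Tibble with `reported_m` (explanatory) and `true_m`
#'   (response), >= 3 rows.
#' @return List of class `apt_depth_fit`: `slope`, `std.error`, `r.squared`
#'   (uncentered, as appropriate without intercept), `p.value`, `n`, the
#'   underlying `lm` fit, and `interval(newdata, level)` returning
#'   confidence and prediction intervals.
#' @export
depth_regression <- function(pairs) {
  stopifnot(nrow(pairs) >= 3)
  if (all(pairs$reported_m == 0)) {
    stop("all reported depths are zero; slope is unidentifiable",
         call. = FALSE)
  }
  fit <- lm(true_m ~ 0 + reported_m, data = pairs)
  sm <- summary(fit)
  structure(list(
    slope = unname(coef(fit)[1]),
    std.error = sm$coefficients[1, 2],
    r.squared = sm$r.squared,
    p.value = sm$coefficients[1, 4],
    n = nrow(pairs),
    fit = fit,
    interval = function(newdata, level = 0.95) {
      ci <- predict(fit, newdata = newdata, interval = "confidence",
                    level = level)
      pi <- predict(fit, newdata = newdata, interval = "prediction",
                    level = level)
      tibble(reported_m = newdata$reported_m,
             fit = ci[, "fit"], ci_lwr = ci[, "lwr"], ci_upr = ci[, "upr"],
             pi_lwr = pi[, "lwr"], pi_upr = pi[, "upr"])
    }
  ), class = "apt_depth_fit")
}

#' @export
print.apt_depth_fit <- function(x, ...) {
  cat(sprintf(
    "<apt_depth_fit> slope %.4f (se %.2g), R^2 %.4f, n = %d\n",
    x$slope, x$std.error, x$r.squared, x$n))
  invisible(x)
}

#' @method tidy apt_depth_fit
#' @export
tidy.apt_depth_fit <- function(x, ...) {
  tibble(term = "reported_m", estimate = x$slope, std.error = x$std.error,
         p.value = x$p.value)
}

#' @method glance apt_depth_fit
#' @export
glance.apt_depth_fit <- function(x, ...) {
  tibble(r.squared = x$r.squared, n = x$n)
}
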