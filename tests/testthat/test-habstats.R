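# Habitat statistics: transforms, GLS with per-group variances, post-hoc
# contrasts and letters, back-transformed summaries, depth regression.

test_that("response transforms match their definitions and invert exactly", {
  expect_equal(transform_response(0, "arcsine"), 0)
  expect_equal(transform_response(1, "arcsine"), pi / 2)
  expect_equal(transform_response(0, "log_offset"), log(0.1))
  expect_equal(log(0.1), -2.302585, tolerance = 1e-6)
  p <- runif(50)
  expect_equal(back_transform(transform_response(p, "arcsine"), "arcsine"),
               p, tolerance = 1e-12)
  y <- rexp(50)
  expect_equal(back_transform(transform_response(y, "log_offset"),
                              "log_offset"), y, tolerance = 1e-12)
  # the plain arcsine variant
  expect_equal(transform_response(0.5, "arcsine", arcsine_sqrt = FALSE),
               asin(0.5))
  expect_error(transform_response(1.2, "arcsine"), "\\[0, 1\\]")
  expect_error(transform_response(-1, "log_offset"), ">= 0")
})

test_that("homogeneous GLS on balanced groups reduces to group means", {
  set.seed(1)
  d <- tibble::tibble(
    habitat = rep(c("A", "B", "C"), each = 10),
    y = rnorm(30, rep(c(0, 1, 3), each = 10))
  )
  fit <- fit_gls(d, "y", use_variance_structure = "off")
  means <- tapply(d$y, d$habitat, mean)
  expect_equal(unname(fit$coefficients), as.numeric(means[fit$levels]),
               tolerance = 1e-12)
  expect_false(fit$heterogeneous)
})

test_that("GLS with per-group variances matches an established ML fit", {
  skip_if_not_installed("nlme")
  set.seed(2)
  d <- data.frame(
    habitat = factor(rep(c("A", "B", "C"), times = c(12, 15, 20))),
    y = c(rnorm(12, 0, 1), rnorm(15, 1, 1), rnorm(20, 2, 3))
  )
  fit <- fit_gls(d, "y", use_variance_structure = "on")
  ref <- nlme::gls(y ~ habitat, data = d,
                   weights = nlme::varIdent(form = ~ 1 | habitat),
                   method = "ML")
  expect_equal(fit$loglik_heterogeneous, as.numeric(stats::logLik(ref)),
               tolerance = 1e-4)
  ref_means <- coef(ref)
  expect_equal(unname(fit$coefficients["A"]), unname(ref_means[1]),
               tolerance = 1e-5)
  expect_equal(unname(fit$coefficients["B"] - fit$coefficients["A"]),
               unname(ref_means[2]), tolerance = 1e-4)
  # heterogeneous likelihood can never fall below the homogeneous one
  expect_gte(fit$loglik_heterogeneous, fit$loglik_homogeneous - 1e-8)
})

test_that("the variance-structure LRT detects real heteroscedasticity", {
  set.seed(3)
  picks <- replicate(200, {
    d <- tibble::tibble(
      habitat = rep(c("A", "B", "C"), each = 50),
      y = c(rnorm(50, 0, 1), rnorm(50, 0, 1), rnorm(50, 0, 3))
    )
    fit_gls(d, "y", use_variance_structure = "auto")$heterogeneous
  })
  expect_gte(mean(picks), 0.9)
})

test_that("identical groups give a near-zero contrast with large p", {
  d <- tibble::tibble(habitat = rep(c("A", "B"), each = 20),
                      y = rep(rnorm(20, 0, 1), 2))
  fit <- fit_gls(d, "y", use_variance_structure = "off")
  ph <- posthoc_pairwise(fit)
  expect_equal(ph$pairs$estimate, 0, tolerance = 1e-12)
  expect_gt(ph$pairs$p.value, 0.99)
  expect_identical(ph$letters$letters[1], ph$letters$letters[2])
})

test_that("post-hoc contrasts are antisymmetric and letters separate groups", {
  set.seed(4)
  d <- tibble::tibble(
    habitat = rep(c("A", "B", "C"), each = 15),
    y = c(rnorm(15, 0, 0.5), rnorm(15, 0.2, 0.5), rnorm(15, 10, 0.5))
  )
  fit <- fit_gls(d, "y", use_variance_structure = "off")
  ph <- posthoc_pairwise(fit)
  ab <- ph$pairs[ph$pairs$level_a == "A" & ph$pairs$level_b == "B", ]
  expect_equal(ab$estimate,
               unname(fit$coefficients["B"] - fit$coefficients["A"]),
               tolerance = 1e-10)
  # C sits 10 residual sds away: its letter differs from A's and B's
  lt <- setNames(ph$letters$letters, ph$letters$level)
  expect_identical(lt[["A"]], lt[["B"]])
  expect_false(grepl(lt[["C"]], lt[["A"]], fixed = TRUE))
})

test_that("null simulations keep nominal error rates and shared letters", {
  set.seed(5)
  # two equal groups: they share a letter in ~95% of replicates
  shared2 <- replicate(200, {
    d <- tibble::tibble(habitat = rep(c("A", "B"), each = 20), y = rnorm(40))
    ph <- posthoc_pairwise(fit_gls(d, "y", use_variance_structure = "off"))
    length(unique(ph$letters$letters)) == 1
  })
  expect_gte(mean(shared2), 0.9)
  # three equal groups: per-pair rejection stays in the nominal 0.05 band,
  # and a fully shared letter occurs at the matching familywise rate
  res <- replicate(400, {
    d <- tibble::tibble(habitat = rep(c("A", "B", "C"), each = 20),
                        y = rnorm(60))
    ph <- posthoc_pairwise(fit_gls(d, "y", use_variance_structure = "off"))
    c(any_sig = any(ph$pairs$p.value <= 0.05),
      rate = mean(ph$pairs$p.value <= 0.05))
  })
  expect_gt(mean(res["rate", ]), 0.03)
  expect_lt(mean(res["rate", ]), 0.07)
  expect_gte(1 - mean(res["any_sig", ]), 0.8)
})

test_that("back-transformed summaries are asymmetric and correct at sd 0", {
  fit <- structure(list(
    response = "y", group = "habitat", transform = "log_offset",
    levels = c("A", "B"), n_per_level = c(5, 5),
    coefficients = setNames(c(log(1.1), 1), c("A", "B")),
    group_sd = setNames(c(0, 0.5), c("A", "B")),
    heterogeneous = TRUE
  ), class = "apt_gls")
  s <- backtransform_summary(fit)
  expect_equal(s$mean[1], 1)
  expect_equal(s$lower[1], 1)
  expect_equal(s$upper[1], 1)
  # convexity of exp: the plus band is wider than the minus band
  expect_gt(s$upper[2] - s$mean[2], s$mean[2] - s$lower[2])

  fit_arc <- structure(list(
    response = "y", group = "habitat", transform = "arcsine",
    levels = "A", n_per_level = 5,
    coefficients = c(A = pi / 4), group_sd = c(A = 0),
    heterogeneous = FALSE
  ), class = "apt_gls")
  s2 <- backtransform_summary(fit_arc)
  expect_equal(s2$mean, 50)
})

test_that("sparse habitat levels are excluded from accuracy models", {
  d <- tibble::tibble(
    habitat = c(rep("A", 6), rep("B", 3), rep("C", 5)),
    accuracy_m = c(rnorm(6, 5), rnorm(3, 8), c(NA, NA, 1, 2, 3))
  )
  kept <- exclude_sparse_levels(d, "accuracy_m", min_trials = 4)
  expect_setequal(unique(kept$habitat), "A")   # B has 3 trials, C only 3 finite
  expect_true(all(is.finite(kept$accuracy_m)))
})

test_that("no-intercept depth regression recovers slope and intervals", {
  d <- tibble::tibble(reported_m = seq(0.5, 6, by = 0.5))
  d$true_m <- d$reported_m
  fit <- suppressWarnings(depth_regression(d))
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$r.squared, 1, tolerance = 1e-12)
  # scale equivariance: doubling reported halves the slope
  d2 <- d; d2$reported_m <- 2 * d2$reported_m
  fit2 <- suppressWarnings(depth_regression(d2))
  expect_equal(fit2$slope, fit$slope / 2, tolerance = 1e-12)
  iv <- fit$interval(tibble::tibble(reported_m = c(1, 3)))
  expect_true(all(iv$pi_lwr <= iv$fit & iv$fit <= iv$pi_upr))
  expect_error(depth_regression(tibble::tibble(reported_m = c(0, 0, 0),
                                               true_m = 1:3)), "zero")
})

test_that("depth slope is recovered within 3 SE at the calibrated noise", {
  pairs <- simulate_depth_calibration(n = 155, slope = 1.01,
                                      noise_sd = 0.06, seed = 99)
  fit <- depth_regression(pairs)
  expect_lt(abs(fit$slope - 1.01), 3 * fit$std.error)
  expect_gt(fit$r.squared, 0.99)
})

test_that("tidy and glance expose the fit in broom style", {
  set.seed(6)
  d <- tibble::tibble(habitat = rep(c("A", "B"), each = 10), y = rnorm(20))
  fit <- fit_gls(d, "y", use_variance_structure = "off")
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$term, c("A", "B"))
  gl <- glance(fit)
  expect_identical(gl$n, 20)
  expect_true(is.finite(gl$logLik))
})
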