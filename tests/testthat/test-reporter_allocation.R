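test_that("a channel exactly proportional to OD gives f_norm = c, sd = 0", {
  t <- seq(0, 6, by = 1 / 3)
  od <- 0.05 * exp(0.5 * t)
  series <- list(times = t, od = od, GFP = 100 * od)
  fit <- fit_growth_curve(t, od)
  p <- compute_normalized_fluorescence(series, fit = fit)
  expect_equal(p$f_norm, 100, tolerance = 1e-9)
  expect_equal(p$f_norm_sd, 0, tolerance = 1e-9)
})

test_that("an impossible window threshold raises an informative error", {
  t <- seq(0, 6, by = 1 / 3)
  od <- 0.05 * exp(0.5 * t)
  series <- list(times = t, od = od, GFP = 100 * od)
  fit <- fit_growth_curve(t, od)
  expect_error(
    compute_normalized_fluorescence(series, fit = fit, window_frac = 1.01),
    "window_frac")
})

test_that("simulated allocation wells recover the per-strain line", {
  strains <- data.frame(strain = "WT", intercept = 2, slope = 3)
  sim <- simulate_reporter_allocation(strains, seed = 5)
  wells <- sim$truth$well
  f_norm <- vapply(wells, function(w) {
    fit <- fit_growth_curve(sim$series, w)
    compute_normalized_fluorescence(sim$series, w, fit)$f_norm
  }, numeric(1))
  rel <- abs(f_norm - sim$truth$f_norm_true) / sim$truth$f_norm_true
  # per-point 3% multiplicative noise averages down over the window
  expect_lt(mean(rel), 0.03)
  expect_lt(max(rel), 0.06)
})

test_that("an exact line is fitted exactly and preconditions are enforced", {
  pts <- data.frame(mu = seq(0.3, 1.5, length.out = 5),
                    f_norm = 2 + 3 * seq(0.3, 1.5, length.out = 5))
  fit <- suppressWarnings(
    fit_allocation_regression(pts, "WT", require_media = FALSE))
  expect_equal(fit$slope, 3, tolerance = 1e-9)
  expect_equal(fit$intercept, 2, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  expect_error(fit_allocation_regression(pts[1:2, ], require_media = FALSE),
               "3 points")
  same_mu <- data.frame(mu = rep(0.5, 4), f_norm = 1:4)
  expect_error(fit_allocation_regression(same_mu, require_media = FALSE),
               "identical")
  one_medium <- cbind(pts, medium = "M1")
  expect_error(fit_allocation_regression(one_medium), "media")
})

test_that("slope CIs cover the truth at close to nominal rate", {
  covered <- vapply(1:100, function(s) {
    pts <- simulate_allocation_points(2, 3, seed = s)
    fit <- fit_allocation_regression(pts, require_media = FALSE)
    fit$slope_ci[1] <= 3 && 3 <= fit$slope_ci[2]
  }, logical(1))
  expect_gte(sum(covered), 90)
})

test_that("slope comparison: identity gives p = 1; units cancel", {
  pts <- simulate_allocation_points(2, 3, seed = 4)
  a <- fit_allocation_regression(pts, "a", require_media = FALSE)
  self <- compare_slopes(a, a)
  expect_equal(self$estimate, 0)
  expect_equal(self$p, 1)
  expect_false(self$significant)

  pts2 <- simulate_allocation_points(2, 3.6, seed = 9)
  b <- fit_allocation_regression(pts2, "b", require_media = FALSE)
  base <- compare_slopes(a, b)
  pts_scaled <- transform(pts, f_norm = 1000 * f_norm)
  pts2_scaled <- transform(pts2, f_norm = 1000 * f_norm)
  a2 <- fit_allocation_regression(pts_scaled, "a", require_media = FALSE)
  b2 <- fit_allocation_regression(pts2_scaled, "b", require_media = FALSE)
  scaled <- compare_slopes(a2, b2)
  expect_equal(scaled$estimate, 1000 * base$estimate, tolerance = 1e-9)
  expect_equal(scaled$p, base$p, tolerance = 1e-9)
  expect_identical(scaled$significant, base$significant)
})

test_that("pooling identical per-strain lines reproduces the common line", {
  mu <- seq(0.3, 1.5, length.out = 6)
  one <- data.frame(mu = mu, f_norm = 2 + 3 * mu)
  pooled <- suppressWarnings(
    fit_allocation_regression(rbind(one, one, one), "pooled",
                              require_media = FALSE))
  expect_equal(pooled$slope, 3, tolerance = 1e-9)
  expect_equal(pooled$intercept, 2, tolerance = 1e-9)
})
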