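test_that("constant GFP gives PA ~ 0 and an offset leaves PA unchanged", {
  t <- seq(0, 8, by = 1 / 3)
  od <- 0.05 * exp(0.4 * t)
  pa0 <- compute_pa(t, rep(20, length(t)), od)
  expect_lt(max(abs(pa0$pa_t)), 1e-6)

  sim <- simulate_promoter_reporter(seed = 6)
  w <- get_well(sim$series, colnames(sim$series$od)[1])
  pa1 <- compute_pa(w$times, w$GFP, w$od)
  pa2 <- compute_pa(w$times, w$GFP + 500, w$od)
  expect_equal(pa2$pa_t, pa1$pa_t, tolerance = 1e-6)
})

test_that("doubling OD at fixed GFP halves PA pointwise", {
  t <- seq(0, 8, by = 1 / 3)
  od <- 0.05 * exp(0.4 * t)
  gfp <- 5 + cumsum(c(0, diff(t) * od[-1]))
  p1 <- compute_pa(t, gfp, od)
  p2 <- compute_pa(t, gfp, 2 * od)
  expect_equal(p2$pa_t, p1$pa_t / 2, tolerance = 1e-9)
})

test_that("normalization to the curve's own maximum puts the peak at 1", {
  sim <- simulate_promoter_reporter(seed = 2)
  pa <- compute_pa(sim$series, colnames(sim$series$od)[1], normalize = TRUE)
  expect_equal(pa$pa_peak, 1)
  expect_equal(max(pa$pa_t), 1)
})

test_that("an exact triangular PA profile is segmented to its slopes", {
  # rise 0 -> 10 over 5 h then fall to 0 over 2 h, sampled directly
  t <- seq(0, 8, by = 0.1)
  pa_vals <- ifelse(t <= 5, 2 * t, pmax(10 - 5 * (t - 5), 0))
  prof <- structure(list(times = t, pa_t = pa_vals, pa_raw = pa_vals,
                         fine = data.frame(t = t, pa = pa_vals),
                         t_peak = 5, pa_peak = 10, normalized = FALSE,
                         method = "exact"), class = "PAProfile")
  seg <- suppressWarnings(segment_pa(prof))  # exact fit: summary.lm warns
  expect_equal(seg$slope_pre$estimate, 2, tolerance = 1e-9)
  expect_equal(seg$slope_post$estimate, -5, tolerance = 1e-9)
})

test_that("a monotone profile has no interior peak and errors", {
  t <- seq(0, 8, by = 0.1)
  prof <- structure(list(times = t, pa_t = t, pa_raw = t,
                         fine = data.frame(t = t, pa = t),
                         t_peak = 8, pa_peak = 8, normalized = FALSE,
                         method = "exact"), class = "PAProfile")
  expect_error(segment_pa(prof), "interior")
})

test_that("simulated reporter wells recover the generating slopes", {
  sim <- simulate_promoter_reporter(seed = 12)
  pa <- segment_pa(compute_pa(sim$series, colnames(sim$series$od)[1]))
  expect_lt(abs(pa$slope_pre$estimate - sim$truth$rise_rate) /
              sim$truth$rise_rate, 0.10)
  expect_lt(abs(pa$slope_post$estimate - sim$truth$fall_rate) /
              abs(sim$truth$fall_rate), 0.15)
})

test_that("integrating PA * OD reconstructs the GFP gain within 3%", {
  sim <- simulate_promoter_reporter(seed = 3, noise_frac = 0)
  w <- get_well(sim$series, colnames(sim$series$od)[1])
  pa <- compute_pa(w$times, w$GFP, w$od)
  n <- length(w$times)
  integ <- sum((pa$pa_raw[-1] * w$od[-1] + pa$pa_raw[-n] * w$od[-n]) / 2 *
                 diff(w$times))
  expect_lt(abs(integ - (w$GFP[n] - w$GFP[1])) / (w$GFP[n] - w$GFP[1]), 0.03)
})

test_that("Savitzky-Golay fallback agrees with the GP on smooth input", {
  t <- seq(0, 8, by = 1 / 3)
  od <- 0.05 * exp(0.4 * t)
  pa_true <- 4 * exp(-((t - 4) / 3)^2)       # slowly varying smooth pulse
  integrand <- pa_true * od
  gfp <- 1 + c(0, cumsum((integrand[-1] + integrand[-length(t)]) / 2 * diff(t)))
  gp <- compute_pa(t, gfp, od, method = "gp")
  sg <- compute_pa(t, gfp, od, method = "sgolay")
  mid <- t > 1 & t < 7
  ref <- max(abs(gp$pa_t[mid]))
  expect_lt(max(abs(gp$pa_t[mid] - sg$pa_t[mid])) / ref, 0.05)
})

test_that("mutant/WT PA comparison reports identity and planted ratios", {
  wt <- simulate_promoter_reporter(seed = 31)
  pw <- segment_pa(compute_pa(wt$series, colnames(wt$series$od)[1]))
  self <- compare_pa(pw, pw)
  expect_equal(self$pct_pre, 100)
  expect_equal(self$fold_post, 1)

  pcts <- vapply(1:5, function(s) {
    w <- simulate_promoter_reporter(seed = 400 + s)
    m <- simulate_promoter_reporter(rise_rate = 0.85 * 2, seed = 500 + s)
    pws <- segment_pa(compute_pa(w$series, colnames(w$series$od)[1]))
    pms <- segment_pa(compute_pa(m$series, colnames(m$series$od)[1]))
    compare_pa(pms, pws)$pct_pre
  }, numeric(1))
  expect_gt(mean(pcts), 80)
  expect_lt(mean(pcts), 90)
})
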