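test_that("noiseless diauxic OD matches the per-phase log-slope analytically", {
  sim <- simulate_diauxic_growth(noise_sd = 0, seed = 1)
  g <- sim$truth$grid
  # numeric log-slope of the simulated OD against the recorded true mu(t)
  mid <- seq(2, nrow(g) - 1)
  slope <- (log(g$od[mid + 1]) - log(g$od[mid - 1])) /
    (g$t[mid + 1] - g$t[mid - 1])
  expect_lt(stats::median(abs(slope - g$mu[mid])), 1e-3)
  # nominal rates bound the realized Monod maxima
  expect_lt(sim$truth$mu1_real, 0.9)
  expect_gt(sim$truth$mu1_real, 0.8)
  expect_lt(sim$truth$mu2_real, 0.35)
  expect_gt(sim$truth$mu2_real, 0.3)
})

test_that("simulators are deterministic given their seed", {
  a <- simulate_diauxic_growth(seed = 42)
  b <- simulate_diauxic_growth(seed = 42)
  expect_identical(a$series$od, b$series$od)
  c1 <- simulate_budget_tables(seed = 7)
  c2 <- simulate_budget_tables(seed = 7)
  expect_identical(c1$table, c2$table)
  expect_false(identical(simulate_diauxic_growth(seed = 1)$series$od,
                         simulate_diauxic_growth(seed = 2)$series$od))
})

test_that("degenerate substrate inputs give flat or monophasic curves", {
  sim <- simulate_diauxic_growth(glucose0 = 0, noise_sd = 0, seed = 1)
  expect_lt(diff(range(sim$series$od)), 1e-6)
  expect_error(simulate_diauxic_growth(dt = 0), "positive")
  expect_error(simulate_diauxic_growth(mu1 = 0.3, mu2 = 0.5), "mu1 > mu2")
})

test_that("triangular PA integrates to the closed-form GFP when noiseless", {
  rise <- 2; fall <- -5; t_on <- 0; t_pk <- 3.75
  sim <- simulate_promoter_reporter(rise_rate = rise, fall_rate = fall,
                                    t_on = t_on, t_peak = t_pk,
                                    noise_frac = 0, seed = 5)
  w <- get_well(sim$series, colnames(sim$series$od)[1])
  # independent quadrature of PA* x OD on the truth grid
  g <- sim$truth$growth$grid
  pa_true <- ifelse(g$t < t_on, 0,
                    ifelse(g$t <= t_pk, rise * (g$t - t_on),
                           pmax(rise * (t_pk - t_on) + fall * (g$t - t_pk), 0)))
  integrand <- pa_true * g$od
  gfp_oracle <- sim$truth$gfp0 +
    approx(g$t, c(0, cumsum((integrand[-1] + integrand[-length(integrand)]) / 2 *
                              diff(g$t))), w$times)$y
  expect_equal(w$GFP, gfp_oracle, tolerance = 1e-6)
  # zero activity means constant GFP
  flat <- simulate_promoter_reporter(rise_rate = 1e-9, fall_rate = -1e-9,
                                     noise_frac = 0, seed = 5)
  wf <- get_well(flat$series, colnames(flat$series$od)[1])
  expect_lt(diff(range(wf$GFP)), 1e-6)
})

test_that("allocation simulator plants recoverable lines", {
  strains <- data.frame(strain = c("WT", "m1"), intercept = c(2, 2),
                        slope = c(3, 3))
  sim <- simulate_reporter_allocation(strains, noise_frac = 0, seed = 1)
  # zero noise: downstream regression on the truth recovers (a, b) exactly
  tr <- sim$truth[sim$truth$strain == "WT", ]
  fit <- suppressWarnings(fit_allocation_regression(
    data.frame(mu = tr$mu, f_norm = tr$f_norm_true), "WT",
    require_media = FALSE))
  expect_equal(fit$slope, 3, tolerance = 1e-9)
  expect_equal(fit$intercept, 2, tolerance = 1e-9)
})

test_that("isocost simulator puts noiseless points exactly on the line", {
  sim <- simulate_isocost(budget = 900, slope = -1.5, noise_frac = 0,
                          seed = 3)
  fit <- suppressWarnings(
    fit_isocost_line(setNames(sim$truth[, c("rfp_true", "gfp_true")],
                              c("rfp", "gfp"))))
  expect_equal(fit$slope, -1.5, tolerance = 1e-9)
  expect_equal(fit$budget, 900, tolerance = 1e-9)
  expect_error(simulate_isocost(levels = c(0, 5)), "3 inducer levels")
})

test_that("budget simulator scales planted totals without breaking truth", {
  sim <- simulate_budget_tables(n_genes = 300, up_total_fg = 4,
                                down_total_fg = 1, seed = 6)
  # independent loop over the truth record
  up <- 0; down <- 0
  for (i in seq_len(nrow(sim$truth))) {
    if (sim$truth$direction[i] == "up") up <- up + abs(sim$truth$delta_fg[i])
    if (sim$truth$direction[i] == "down") down <- down + abs(sim$truth$delta_fg[i])
  }
  expect_equal(up, 4, tolerance = 1e-9)
  expect_equal(down, 1, tolerance = 1e-9)
  # all-zero fold changes mean all-zero deltas
  null <- simulate_budget_tables(n_genes = 100, frac_up = 0, frac_down = 0,
                                 seed = 2)
  expect_true(all(null$truth$delta_fg == 0))
})
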