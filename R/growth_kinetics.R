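#' Estimate the time-resolved growth rate of one well by GP regression
#'
#' Fits a squared-exponential Gaussian process to log OD and takes the
#' analytic derivative of the posterior mean as the growth-rate curve
#' mu(t) = d log OD / dt (per hour), with pointwise uncertainty from the
#' derivative-process posterior. OD is clipped at the detection floor before
#' the log transform so early near-zero readings cannot dominate the fit.
#'
#' @param times numeric vector of times in hours (or a `PlateTimeSeries`,
#'   in which case `od` names the well to fit).
#' @param od numeric vector of OD600 readings, or the well id when `times`
#'   is a `PlateTimeSeries`.
#' @param od_floor detection floor (OD units); values below are clipped.
#' @param lengthscale_bounds,noise_bounds GP hyperparameter bounds passed to
#'   [gp_fit()]; defaults are `[2*median(dt), span]` hours for the
#'   length-scale and `[1e-4, 1]` log-OD units for the noise sd.
#' @param n_restarts,seed multi-start control for the marginal-likelihood
#'   optimization.
#' @param refine evaluation refinement factor: mu(t) is also evaluated on a
#'   grid `refine` times finer than the observations for phase detection,
#'   since the posterior derivative is an analytic function of time.
#' @return object of class `GrowthFit`: `times`, `od`, `mu_t`, `mu_sd_t`
#'   (both on the observation grid), `mu_max`, `t_mu_max`, `od_max`,
#'   `t_od_max`, `fine` (data.frame `t`, `mu` on the refined grid),
#'   `hyperparams`, `log_marginal_likelihood`.
#' @export
fit_growth_curve <- function(times, od, od_floor = 0.005,
                             lengthscale_bounds = NULL,
                             noise_bounds = c(1e-4, 1),
                             n_restarts = 5, seed = 17, refine = 4L) {
  if (inherits(times, "PlateTimeSeries")) {
    w <- get_well(times, od)
    times <- w$times; od <- w$od
  }
  stopifnot(length(times) == length(od))
  if (length(times) < 10) stop("need at least 10 time points")
  od_clip <- pmax(od, od_floor)
  y <- log(od_clip)
  # additive plate-reader noise of fixed sd has variance ~ 1/OD^2 on the
  # log scale; weight the GP noise accordingly so early low-OD scatter
  # cannot dominate the derivative
  gp <- gp_fit(times, y, lengthscale_bounds = lengthscale_bounds,
               noise_bounds = noise_bounds, n_restarts = n_restarts,
               seed = seed, noise_weights = 1 / od_clip^2)
  pr <- predict(gp, times)
  t_fine <- seq(min(times), max(times), length.out = refine * length(times))
  pf <- predict(gp, t_fine)
  if (max(abs(pf$deriv)) <= 0.02)
    warning("growth rate is ~0 everywhere (constant or non-growing OD)")
  i_max <- which.max(pr$deriv)
  i_od <- which.max(od)
  structure(list(
    times = times, od = od, log_od = y,
    mu_t = pr$deriv, mu_sd_t = pr$deriv_sd,
    mu_max = pr$deriv[i_max], t_mu_max = times[i_max],
    od_max = od[i_od], t_od_max = times[i_od],
    fine = data.frame(t = t_fine, mu = pf$deriv, mu_sd = pf$deriv_sd,
                      log_od = pf$mean),
    hyperparams = gp$hyperparams,
    log_marginal_likelihood = gp$log_marginal_likelihood,
    gp = gp), class = "GrowthFit")
}

#' @export
print.GrowthFit <- function(x, ...) {
  cat(sprintf("GrowthFit: mu_max = %.4g 1/h at t = %.3g h (OD max %.3g at %.3g h)\n",
              x$mu_max, x$t_mu_max, x$od_max, x$t_od_max))
  cat(sprintf("  GP: length-scale %.3g h, noise sd %.3g, logML %.4g\n",
              x$hyperparams[["lengthscale"]], x$hyperparams[["noise_sd"]],
              x$log_marginal_likelihood))
  invisible(x)
}

#' Characterize a diauxic shift from a fitted growth-rate curve
#'
#' A diauxic shift is a growth pause between two growth phases, so
#' detection is gated on an interior valley of mu(t) dropping below
#' `valley_frac * mu_max`: the pre- and post-shift growth rates mu1 and
#' mu2 are the largest local maxima on either side of the deepest
#' qualifying valley. Both flanking maxima must have prominence at least
#' `prominence_frac * mu_max` above the valley floor and be separated by
#' at least `min_separation` hours, otherwise the curve is called
#' monophasic. Gating on the pause (rather than ranking all local maxima
#' by height) keeps small posterior wiggles on a growth plateau from
#' being mistaken for a second phase. The shift time is the mu minimum
#' between the two maxima; the lag is the contiguous interval around it
#' where mu stays below `resumption_frac * mu2`.
#'
#' @param fit a `GrowthFit`.
#' @param prominence_frac minimum height of each phase maximum above the
#'   valley floor, as a fraction of mu_max.
#' @param min_separation minimum separation between the two phase maxima
#'   (hours).
#' @param valley_frac the pause must bring mu below this fraction of
#'   mu_max for the curve to count as diauxic.
#' @param resumption_frac growth counts as resumed once mu exceeds this
#'   fraction of mu2 (defines the lag interval).
#' @return a `DiauxicMetrics` list (`mu1`, `t_mu1`, `mu2`, `t_mu2`,
#'   `shift_time`, `lag`, `ratio`, `low_prominence` flag) or the
#'   character scalar `"monophasic"`.
#' @export
detect_growth_phases <- function(fit, prominence_frac = 0.10,
                                 min_separation = 1,
                                 valley_frac = 0.3,
                                 resumption_frac = 0.5) {
  stopifnot(inherits(fit, "GrowthFit"))
  tt <- fit$fine$t; mu <- fit$fine$mu
  n <- length(mu)
  if (n < 10) stop("growth-rate curve too short")
  mu_max <- max(mu)
  if (mu_max <= 0) return("monophasic")
  valleys <- which(diff(sign(diff(mu))) > 0) + 1L
  valleys <- valleys[mu[valleys] < valley_frac * mu_max]
  if (!length(valleys)) return("monophasic")
  best <- NULL
  for (v in valleys) {
    iL <- which.max(mu[seq_len(v)])
    iR <- v - 1L + which.max(mu[seq(v, n)])
    prom <- min(mu[iL], mu[iR]) - mu[v]
    if (prom < prominence_frac * mu_max) next
    if (tt[iR] - tt[iL] < min_separation) next
    score <- min(mu[iL], mu[iR])
    if (is.null(best) || score > best$score)
      best <- list(i1 = iL, i2 = iR, v = v, score = score, prom = prom)
  }
  if (is.null(best)) return("monophasic")
  i1 <- best$i1; i2 <- best$i2
  v <- best$v
  # Selection-bias correction for the phase maxima: the reported maximum of
  # a posterior-mean curve overshoots the true maximum by about
  # E[max of m N(0,1)] * sd, where m counts the competing local maxima in
  # the phase window (a broad wiggly plateau has several; a single sharp,
  # well-measured peak has one and gets no correction).
  sdv <- fit$fine$mu_sd
  e_max_norm <- function(m) {
    tab <- c(0, 0.5642, 0.8463, 1.0294, 1.1630, 1.2672, 1.3522)
    if (m <= 7) tab[m] else sqrt(2 * log(m))
  }
  phase_value <- function(window, i_peak) {
    loc <- window[which(diff(sign(diff(mu[window]))) < 0) + 1L]
    # only maxima within ~2 posterior sd of the peak compete for the max
    m <- max(sum(mu[loc] >= mu[i_peak] - 2 * sdv[i_peak]), 1L)
    mu[i_peak] - e_max_norm(m) * sdv[i_peak]
  }
  mu1_est <- phase_value(seq_len(v), i1)
  mu2_est <- phase_value(seq(v, n), i2)
  between <- seq(i1, i2)
  i_min <- between[which.min(mu[between])]
  shift_time <- tt[i_min]
  below <- mu < resumption_frac * mu2_est
  lo <- i_min; while (lo > 1 && below[lo - 1]) lo <- lo - 1
  hi <- i_min; while (hi < n && below[hi + 1]) hi <- hi + 1
  lag <- if (below[i_min]) tt[hi] - tt[lo] else 0
  structure(list(
    mu1 = mu1_est, t_mu1 = tt[i1],
    mu2 = mu2_est, t_mu2 = tt[i2],
    shift_time = shift_time, lag = lag,
    ratio = mu2_est / mu1_est,
    low_prominence = best$prom < 2 * prominence_frac * mu_max),
    class = "DiauxicMetrics")
}

#' @export
print.DiauxicMetrics <- function(x, ...) {
  cat(sprintf("Diauxic shift: mu1 = %.3g at %.3g h, mu2 = %.3g at %.3g h\n",
              x$mu1, x$t_mu1, x$mu2, x$t_mu2))
  cat(sprintf("  shift at %.3g h, lag %.3g h, mu2/mu1 = %.3g\n",
              x$shift_time, x$lag, x$ratio))
  if (x$low_prominence) cat("  (low-prominence call; inspect the curve)\n")
  invisible(x)
}

#' Summarize growth metrics over replicates, by strain and medium
#'
#' @param metrics data.frame with one row per well: columns `strain`,
#'   `medium`, plus numeric metric columns (at least `mu_max`).
#' @param reference strain name to compare each group's `mu_max` against
#'   (Welch two-sample t test at 95% confidence, within each medium).
#' @return data.frame with one row per strain x medium x metric: `mean`,
#'   `sd` (NA when n = 1), `n`, and for `mu_max` rows `p_vs_ref` and
#'   `significant` against the reference strain in the same medium.
#' @export
summarize_replicates <- function(metrics, reference = NULL) {
  stopifnot(all(c("strain", "medium") %in% names(metrics)))
  num_cols <- names(metrics)[vapply(metrics, is.numeric, logical(1))]
  if (!length(num_cols)) stop("no numeric metric columns")
  groups <- unique(metrics[, c("strain", "medium")])
  rows <- list()
  for (g in seq_len(nrow(groups))) {
    sub <- metrics[metrics$strain == groups$strain[g] &
                     metrics$medium == groups$medium[g], , drop = FALSE]
    for (m in num_cols) {
      v <- sub[[m]][!is.na(sub[[m]])]
      n <- length(v)
      p <- NA_real_
      if (!is.null(reference) && m == "mu_max" &&
          groups$strain[g] != reference) {
        ref <- metrics[metrics$strain == reference &
                         metrics$medium == groups$medium[g], "mu_max"]
        ref <- ref[!is.na(ref)]
        if (n >= 2 && length(ref) >= 2 &&
            (stats::sd(v) > 0 || stats::sd(ref) > 0)) {
          p <- stats::t.test(v, ref)$p.value
        } else if (n >= 2 && length(ref) >= 2) {
          p <- if (isTRUE(all.equal(mean(v), mean(ref)))) 1 else 0
        }
      }
      if (!is.null(reference) && m == "mu_max" &&
          groups$strain[g] == reference) p <- 1
      rows[[length(rows) + 1L]] <- data.frame(
        strain = groups$strain[g], medium = groups$medium[g], metric = m,
        mean = mean(v), sd = if (n > 1) stats::sd(v) else NA_real_, n = n,
        p_vs_ref = p, significant = !is.na(p) & p < 0.05)
    }
  }
  do.call(rbind, rows)
}

#' Fit every (non-blank) well of a plate and tabulate growth metrics
#'
#' @param series a `PlateTimeSeries`.
#' @param ... passed to [fit_growth_curve()] and [detect_growth_phases()].
#' @return list with `fits` (named list of `GrowthFit`) and `table`
#'   (data.frame: well, strain, medium, replicate, mu_max, t_mu_max, od_max,
#'   mu1, mu2, shift_time, lag, diauxic flag).
#' @export
fit_growth_plate <- function(series, prominence_frac = 0.10,
                             min_separation = 1, ...) {
  wells <- setdiff(colnames(series$od), series$flags$blank_wells)
  fits <- list(); rows <- list()
  for (w in wells) {
    f <- fit_growth_curve(series, w, od_floor = series$od_floor, ...)
    ph <- detect_growth_phases(f, prominence_frac = prominence_frac,
                               min_separation = min_separation)
    diaux <- inherits(ph, "DiauxicMetrics")
    meta <- series$wells[series$wells$well == w, ]
    rows[[w]] <- data.frame(
      well = w, strain = meta$strain, medium = meta$medium,
      replicate = meta$replicate,
      mu_max = f$mu_max, t_mu_max = f$t_mu_max,
      od_max = f$od_max, t_od_max = f$t_od_max,
      diauxic = diaux,
      mu1 = if (diaux) ph$mu1 else NA_real_,
      mu2 = if (diaux) ph$mu2 else NA_real_,
      shift_time = if (diaux) ph$shift_time else NA_real_,
      lag = if (diaux) ph$lag else NA_real_)
    fits[[w]] <- f
  }
  list(fits = fits, table = do.call(rbind, rows))
}
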