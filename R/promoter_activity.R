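#' Promoter activity from a reporter time course: PA(t) = (dGFP/dt)/OD
#'
#' Differentiates the GFP signal with the same GP engine used for growth
#' rates (analytic derivative of the posterior mean) or, optionally, a
#' Savitzky-Golay filter (window 7, order 2), then divides by OD. PA is the
#' per-cell transcription rate proxy of the reporter's promoter.
#'
#' @param times numeric times (hours), or a `PlateTimeSeries` (then `gfp`
#'   names the well).
#' @param gfp numeric GFP vector, or the well id.
#' @param od numeric OD vector (ignored when a plate is given).
#' @param channel channel name when extracting from a plate.
#' @param method `"gp"` (default) or `"sgolay"`.
#' @param od_floor OD detection floor; OD is clipped here before division.
#' @param normalize divide PA by its own maximum (used for cross-plate
#'   comparison since fluorescence units are arbitrary).
#' @param seed passed to the GP multi-start.
#' @return a `PAProfile`: `times`, `pa_t`, `pa_raw` (un-normalized),
#'   `t_peak`, `pa_peak`, `normalized`, `method`; slopes unset until
#'   [segment_pa()].
#' @export
compute_pa <- function(times, gfp, od = NULL, channel = "GFP",
                       method = c("gp", "sgolay"), od_floor = 0.005,
                       normalize = FALSE, seed = 17) {
  method <- match.arg(method)
  if (inherits(times, "PlateTimeSeries")) {
    w <- get_well(times, gfp)
    if (is.null(w[[channel]])) stop("channel '", channel, "' not present")
    gfp <- w[[channel]]; od <- w$od; times <- w$times
  }
  stopifnot(length(times) == length(gfp), length(times) == length(od))
  od_clip <- pmax(od, od_floor)
  if (mean(od <= od_floor) > 0.5)
    warning("OD at or below the floor for >50% of points; PA is unreliable")
  t_fine <- seq(min(times), max(times), length.out = 4L * length(times))
  if (method == "gp") {
    # fluorescence noise grows with signal (multiplicative component); the
    # weights use the signal's rise above its minimum so PA stays exactly
    # invariant to a constant offset on GFP
    rng <- diff(range(gfp))
    w <- if (rng > 0) (gfp - min(gfp) + 0.1 * rng)^2 else rep(1, length(gfp))
    gp <- gp_fit(times, gfp, seed = seed, noise_weights = w)
    dgfp <- predict(gp, times)$deriv
    dgfp_fine <- predict(gp, t_fine)$deriv
    od_fine <- exp(stats::approx(times, log(od_clip), t_fine)$y)
  } else {
    dt <- stats::median(diff(times))
    dgfp <- signal::sgolayfilt(gfp, p = 2, n = 7, m = 1, ts = dt)
    dgfp_fine <- stats::approx(times, dgfp, t_fine)$y
    od_fine <- exp(stats::approx(times, log(od_clip), t_fine)$y)
  }
  pa_raw <- dgfp / od_clip
  pa_fine <- dgfp_fine / od_fine
  pa <- pa_raw
  if (normalize) {
    m <- max(pa_raw)
    if (m > 0) { pa <- pa_raw / m; pa_fine <- pa_fine / m }
  }
  i_peak <- which.max(pa)
  structure(list(times = times, pa_t = pa, pa_raw = pa_raw,
                 fine = data.frame(t = t_fine, pa = pa_fine),
                 t_peak = times[i_peak], pa_peak = pa[i_peak],
                 normalized = normalize, method = method,
                 slope_pre = NULL, slope_post = NULL), class = "PAProfile")
}

#' Two-phase slope segmentation of a promoter-activity profile
#'
#' The rise slope is fitted where PA climbs from `onset_frac * pa_peak` to
#' `(1 - onset_frac) * pa_peak` before the peak, the fall slope where it
#' descends through the same band after the peak — the usual linear-region
#' (20-80%) convention, which keeps the smoother-rounded cap around the
#' peak out of the fit. Each slope is an OLS fit of PA on time with a 95%
#' confidence interval, computed on the refined evaluation grid.
#'
#' @param profile a `PAProfile` with an interior maximum.
#' @param onset_frac fraction of the peak bounding the linear band
#'   (default 0.2: slopes fitted between 20% and 80% of the peak).
#' @param end_time optional explicit end of the fall window (hours), e.g.
#'   the diauxic `shift_time + lag` from [detect_growth_phases()].
#' @return the `PAProfile` with `slope_pre`, `slope_post` set, each a list
#'   `estimate`, `ci`, `se`, `n`, `window` (start/end times).
#' @export
segment_pa <- function(profile, onset_frac = 0.2, end_time = NULL) {
  stopifnot(inherits(profile, "PAProfile"))
  i_obs_peak <- which.max(profile$pa_t)
  if (i_obs_peak == 1 || i_obs_peak == length(profile$pa_t))
    stop("no interior PA peak; cannot segment")
  tt <- profile$fine$t; pa <- profile$fine$pa
  i_peak <- which.max(pa)
  peak <- pa[i_peak]
  lo <- onset_frac * peak; hi <- (1 - onset_frac) * peak
  pre <- seq_len(i_peak)
  idx_pre <- pre[pa[pre] >= lo & pa[pre] <= hi]
  # restrict to the contiguous climb just before the peak
  if (length(idx_pre)) {
    brk <- which(diff(idx_pre) > 1)
    if (length(brk)) idx_pre <- idx_pre[seq(max(brk) + 1, length(idx_pre))]
  }
  post <- seq(i_peak, length(pa))
  if (!is.null(end_time)) post <- post[tt[post] <= end_time]
  idx_post <- post[pa[post] >= lo & pa[post] <= hi]
  if (length(idx_post)) {
    brk <- which(diff(idx_post) > 1)
    if (length(brk)) idx_post <- idx_post[seq_len(brk[1])]
  }
  ols_slope <- function(idx) {
    if (length(idx) < 2)
      stop("slope band with <2 points; adjust onset_frac")
    fit <- stats::lm(pa[idx] ~ tt[idx])
    ci <- if (length(idx) > 2) stats::confint(fit)[2, ] else c(NA_real_, NA_real_)
    list(estimate = unname(stats::coef(fit)[2]), ci = unname(ci),
         se = summary(fit)$coefficients[2, "Std. Error"],
         n = length(idx), window = range(tt[idx]))
  }
  profile$slope_pre <- ols_slope(idx_pre)
  profile$slope_post <- ols_slope(idx_post)
  profile$onset_frac <- onset_frac
  profile
}

#' @export
print.PAProfile <- function(x, ...) {
  cat(sprintf("PAProfile (%s%s): peak %.4g at t = %.3g h\n", x$method,
              if (x$normalized) ", normalized" else "", x$pa_peak, x$t_peak))
  if (!is.null(x$slope_pre))
    cat(sprintf("  rise slope %+.4g [%.4g, %.4g], fall slope %+.4g [%.4g, %.4g]\n",
                x$slope_pre$estimate, x$slope_pre$ci[1], x$slope_pre$ci[2],
                x$slope_post$estimate, x$slope_post$ci[1], x$slope_post$ci[2]))
  invisible(x)
}

#' Compare promoter-activity slope dynamics between a mutant and the WT
#'
#' Reports the mutant's rise slope as a percentage of the WT rise slope and
#' the fold change of the fall-slope magnitudes. When lists of replicate
#' (segmented) profiles are supplied, per-replicate slopes feed a Welch t
#' test at 95% confidence for each phase.
#'
#' @param mutant,wt segmented `PAProfile`s, or lists of replicate segmented
#'   profiles.
#' @return list: `pct_pre` (mutant rise slope / WT rise slope x 100, NA when
#'   the WT slope is 0), `fold_post` (|mutant fall| / |WT fall|), and when
#'   replicates are given `p_pre`, `p_post`, `significant_pre`,
#'   `significant_post`.
#' @export
compare_pa <- function(mutant, wt) {
  as_list <- function(x) if (inherits(x, "PAProfile")) list(x) else x
  m <- as_list(mutant); w <- as_list(wt)
  get_slopes <- function(lst, which) vapply(lst, function(p) {
    if (is.null(p[[which]])) stop("profiles must be segmented first")
    p[[which]]$estimate
  }, numeric(1))
  pre_m <- get_slopes(m, "slope_pre"); pre_w <- get_slopes(w, "slope_pre")
  post_m <- get_slopes(m, "slope_post"); post_w <- get_slopes(w, "slope_post")
  pct_pre <- if (mean(pre_w) == 0) NA_real_ else 100 * mean(pre_m) / mean(pre_w)
  fold_post <- if (mean(abs(post_w)) == 0) NA_real_ else
    mean(abs(post_m)) / mean(abs(post_w))
  out <- list(pct_pre = pct_pre, fold_post = fold_post,
              n_mutant = length(m), n_wt = length(w))
  if (length(m) >= 2 && length(w) >= 2) {
    welch <- function(x, y) {
      if (stats::sd(x) == 0 && stats::sd(y) == 0)
        return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
      stats::t.test(x, y)$p.value
    }
    out$p_pre <- welch(pre_m, pre_w)
    out$p_post <- welch(abs(post_m), abs(post_w))
    out$significant_pre <- out$p_pre < 0.05
    out$significant_post <- out$p_post < 0.05
  }
  out
}
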