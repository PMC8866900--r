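#' Normalized reporter fluorescence during exponential growth
#'
#' Computes the allocation proxy F/OD over the exponential window, defined
#' as the times where the fitted growth rate is at least
#' `window_frac * mu_max`. For a ribosomal-protein fusion such as
#' rplI:msfGFP this per-OD fluorescence tracks ribosome content.
#'
#' @param series a `PlateTimeSeries` (or a [get_well()] list).
#' @param well well id when `series` is a plate.
#' @param fit the `GrowthFit` for that well.
#' @param channel fluorescence channel name (default `"GFP"`).
#' @param window_frac exponential-window threshold as a fraction of mu_max.
#' @param blank scalar blank fluorescence to subtract (0 if the plate was
#'   already blank-corrected).
#' @return an `AllocationPoint` list: `strain`, `medium`, `mu` (mean mu over
#'   the window), `f_norm`, `f_norm_sd`, `n_window`.
#' @export
compute_normalized_fluorescence <- function(series, well = NULL, fit,
                                            channel = "GFP",
                                            window_frac = 0.8, blank = 0) {
  if (inherits(series, "PlateTimeSeries")) {
    stopifnot(!is.null(well))
    w <- get_well(series, well)
    meta <- series$wells[series$wells$well == well, ]
    strain <- meta$strain; medium <- meta$medium
  } else {
    w <- series; strain <- NA_character_; medium <- NA_character_
  }
  if (is.null(w[[channel]])) stop("channel '", channel, "' not present")
  stopifnot(inherits(fit, "GrowthFit"))
  in_window <- fit$mu_t >= window_frac * fit$mu_max
  if (!any(in_window))
    stop("empty exponential window; lower window_frac (currently ",
         window_frac, ")")
  ratio <- (w[[channel]][in_window] - blank) / w$od[in_window]
  structure(list(strain = strain, medium = medium,
                 mu = mean(fit$mu_t[in_window]),
                 f_norm = mean(ratio),
                 f_norm_sd = if (sum(in_window) > 1) stats::sd(ratio) else 0,
                 n_window = sum(in_window)), class = "AllocationPoint")
}

#' Linear regression of normalized reporter fluorescence on growth rate
#'
#' Ordinary least squares of f_norm on mu across media (and, for the pooled
#' variant, across strains), with 95% confidence intervals on slope and
#' intercept. The slope measures how strongly reporter allocation scales
#' with growth rate.
#'
#' @param points data.frame with numeric columns `mu` and `f_norm` and
#'   optionally `strain`, `medium`.
#' @param strain label recorded in the result (`"pooled"` for combined fits).
#' @param require_media require at least two distinct media when a `medium`
#'   column is present.
#' @return an `AllocationRegression` list: `strain`, `slope`, `slope_ci`,
#'   `slope_se`, `intercept`, `intercept_ci`, `n`, `df`, `r_squared`.
#' @export
fit_allocation_regression <- function(points, strain = "pooled",
                                      require_media = TRUE) {
  points <- as.data.frame(points)
  stopifnot(all(c("mu", "f_norm") %in% names(points)))
  points <- points[is.finite(points$mu) & is.finite(points$f_norm), ]
  if (nrow(points) < 3) stop("need at least 3 points for the regression")
  if (require_media && "medium" %in% names(points) &&
      length(unique(points$medium)) < 2)
    stop("points must span at least 2 distinct media")
  if (stats::sd(points$mu) == 0)
    stop("all growth rates identical; slope is not identifiable")
  fit <- stats::lm(f_norm ~ mu, data = points)
  ci <- stats::confint(fit, level = 0.95)
  sm <- summary(fit)
  structure(list(
    strain = strain,
    slope = unname(stats::coef(fit)["mu"]),
    slope_ci = unname(ci["mu", ]),
    slope_se = sm$coefficients["mu", "Std. Error"],
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    intercept_ci = unname(ci["(Intercept)", ]),
    n = nrow(points), df = fit$df.residual,
    r_squared = sm$r.squared), class = "AllocationRegression")
}

#' @export
print.AllocationRegression <- function(x, ...) {
  cat(sprintf("Allocation regression [%s]: f_norm = %.4g + %.4g * mu\n",
              x$strain, x$intercept, x$slope))
  cat(sprintf("  slope 95%% CI [%.4g, %.4g], n = %d, r^2 = %.3f\n",
              x$slope_ci[1], x$slope_ci[2], x$n, x$r_squared))
  invisible(x)
}

#' Compare two allocation-regression slopes
#'
#' Two-sample t test on the slope difference using the OLS slope standard
#' errors with Welch-Satterthwaite degrees of freedom; significance at 95%
#' confidence. No multiple-testing correction is applied: comparisons are
#' reported per strain pair.
#'
#' @param a,b `AllocationRegression` objects.
#' @return list: `estimate` (slope_a - slope_b), `se`, `ci` (95%), `t`,
#'   `df`, `p`, `significant`.
#' @export
compare_slopes <- function(a, b) {
  stopifnot(inherits(a, "AllocationRegression"),
            inherits(b, "AllocationRegression"))
  est <- a$slope - b$slope
  se <- sqrt(a$slope_se^2 + b$slope_se^2)
  if (se == 0) {
    return(list(estimate = est, se = 0, ci = c(est, est),
                t = if (est == 0) 0 else Inf, df = NA_real_,
                p = if (est == 0) 1 else 0, significant = est != 0))
  }
  v1 <- a$slope_se^2; v2 <- b$slope_se^2
  df <- (v1 + v2)^2 / (v1^2 / a$df + v2^2 / b$df)
  tstat <- est / se
  p <- 2 * stats::pt(-abs(tstat), df)
  ci <- est + c(-1, 1) * stats::qt(0.975, df) * se
  list(estimate = est, se = se, ci = ci, t = tstat, df = df, p = p,
       significant = p < 0.05)
}
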