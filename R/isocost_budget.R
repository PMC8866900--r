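#' Dual-reporter expression matched at a target OD
#'
#' For each inducer level (one well per level), finds the first time OD
#' crosses `od_target` — linearly interpolating between samples — and
#' returns (RFP/OD, GFP/OD) at that time. Matching at a common OD in early
#' exponential growth makes the reporter pair comparable across strains and
#' levels.
#'
#' @param series a `PlateTimeSeries` whose wells are the inducer levels.
#' @param levels named mapping well id -> inducer concentration, or `NULL`
#'   to use all non-blank wells (level taken from the `replicate` field).
#' @param od_target OD at which expression is read (default 0.2).
#' @param tolerance the well must reach `od_target - tolerance` to count;
#'   wells that never do are dropped with a warning.
#' @param gfp_channel,rfp_channel channel names.
#' @return data.frame: `well`, `level`, `t_cross` (h), `gfp` (GFP/OD),
#'   `rfp` (RFP/OD).
#' @export
match_expression <- function(series, levels = NULL, od_target = 0.2,
                             tolerance = 0.02,
                             gfp_channel = "GFP", rfp_channel = "RFP") {
  stopifnot(inherits(series, "PlateTimeSeries"))
  wells <- if (!is.null(levels)) names(levels) else
    setdiff(colnames(series$od), series$flags$blank_wells)
  rows <- list()
  for (wl in wells) {
    w <- get_well(series, wl)
    if (is.null(w[[gfp_channel]]) || is.null(w[[rfp_channel]]))
      stop("GFP/RFP channels required")
    od <- w$od
    if (max(od) < od_target - tolerance) {
      warning("well ", wl, " never reaches OD ", od_target, "; dropped")
      next
    }
    i <- which(od >= od_target)[1]
    if (is.na(i)) i <- which.max(od)   # within tolerance of target
    interp_at <- function(v) {
      if (i == 1 || od[i] <= od_target) return(list(t = w$times[i], v = v[i]))
      f <- (od_target - od[i - 1]) / (od[i] - od[i - 1])
      list(t = w$times[i - 1] + f * diff(w$times[c(i - 1, i)]),
           v = v[i - 1] + f * (v[i] - v[i - 1]))
    }
    g <- interp_at(w[[gfp_channel]]); r <- interp_at(w[[rfp_channel]])
    od_at <- min(od_target, od[i])
    rows[[wl]] <- data.frame(
      well = wl,
      level = if (!is.null(levels)) levels[[wl]] else
        series$wells$replicate[series$wells$well == wl],
      t_cross = g$t, gfp = g$v / od_at, rfp = r$v / od_at)
  }
  if (!length(rows)) stop("no well reached the target OD")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit an isocost line to dual-reporter points across inducer levels
#'
#' OLS of GFP/OD on RFP/OD over the inducer levels. Under a fixed cellular
#' expression budget the points fall on a negatively sloped line; the
#' GFP-axis intercept is taken as the budget metric (the constitutive
#' reporter's output when the induced one takes nothing), and the RFP-axis
#' intercept is reported alongside.
#'
#' @param points data.frame with columns `rfp`, `gfp` (one row per level),
#'   e.g. from [match_expression()].
#' @param strain label stored in the fit.
#' @return an `IsocostFit`: `strain`, `points`, `slope`, `slope_ci`,
#'   `gfp_intercept`, `gfp_intercept_ci`, `gfp_intercept_se`,
#'   `rfp_intercept`, `budget`, `n_levels`, `r_squared`, `df`.
#' @export
fit_isocost_line <- function(points, strain = NA_character_) {
  points <- as.data.frame(points)
  stopifnot(all(c("rfp", "gfp") %in% names(points)))
  if (nrow(points) < 3) stop("need at least 3 inducer levels")
  if (stats::sd(points$rfp) == 0)
    stop("all RFP values identical; isocost slope is not identifiable")
  fit <- stats::lm(gfp ~ rfp, data = points)
  co <- stats::coef(fit)
  ci <- stats::confint(fit)
  sm <- summary(fit)
  if (co["rfp"] >= 0)
    warning("isocost slope is non-negative; no budget trade-off visible")
  structure(list(
    strain = strain, points = points[, c("rfp", "gfp")],
    slope = unname(co["rfp"]), slope_ci = unname(ci["rfp", ]),
    gfp_intercept = unname(co["(Intercept)"]),
    gfp_intercept_ci = unname(ci["(Intercept)", ]),
    gfp_intercept_se = sm$coefficients["(Intercept)", "Std. Error"],
    rfp_intercept = if (co["rfp"] != 0) unname(-co["(Intercept)"] / co["rfp"])
                    else NA_real_,
    budget = unname(co["(Intercept)"]),
    n_levels = nrow(points), df = fit$df.residual,
    r_squared = sm$r.squared), class = "IsocostFit")
}

#' @export
print.IsocostFit <- function(x, ...) {
  cat(sprintf("Isocost line [%s]: gfp = %.4g %+.4g * rfp (n = %d, r^2 = %.3f)\n",
              x$strain, x$gfp_intercept, x$slope, x$n_levels, x$r_squared))
  cat(sprintf("  budget (GFP intercept) = %.4g [%.4g, %.4g]\n",
              x$budget, x$gfp_intercept_ci[1], x$gfp_intercept_ci[2]))
  invisible(x)
}

#' Compare expression budgets across strains against a reference
#'
#' Budget ratio (strain / reference) with a 95% CI by first-order error
#' propagation on the two intercept standard errors; flagged significant
#' when the CI excludes 1. A reference whose own budget CI spans 0 makes
#' the ratio numerically unstable, and the row is flagged accordingly.
#'
#' @param fits list of `IsocostFit` objects.
#' @param reference strain name of the reference fit.
#' @return data.frame: `strain`, `budget`, `ratio`, `ratio_ci_lo`,
#'   `ratio_ci_hi`, `significant`, `unstable`.
#' @export
compare_budgets <- function(fits, reference) {
  stopifnot(length(fits) >= 2)
  strains <- vapply(fits, function(f) f$strain, character(1))
  if (!reference %in% strains) stop("reference strain not among the fits")
  ref <- fits[[which(strains == reference)[1]]]
  ref_unstable <- ref$gfp_intercept_ci[1] <= 0 && ref$gfp_intercept_ci[2] >= 0
  rows <- lapply(fits, function(f) {
    ratio <- f$budget / ref$budget
    rel_var <- (f$gfp_intercept_se / f$budget)^2 +
      (ref$gfp_intercept_se / ref$budget)^2
    se <- abs(ratio) * sqrt(rel_var)
    ci <- ratio + c(-1, 1) * 1.96 * se
    data.frame(strain = f$strain, budget = f$budget, ratio = ratio,
               ratio_ci_lo = ci[1], ratio_ci_hi = ci[2],
               significant = (ci[1] > 1 || ci[2] < 1) &&
                 f$strain != reference,
               unstable = ref_unstable)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
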