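#' Simulate diauxic (glucose then acetate) growth as a plate-reader series
#'
#' Sequential two-substrate Monod model integrated with deSolve: biomass
#' grows on glucose at Monod rate `mu1 * G/(G + ks_g)` while excreting
#' acetate in proportion to the biomass formed (overflow yield
#' `acetate_yield` substrate units per OD formed); once glucose falls below
#' `glucose_threshold` growth pauses for `lag_duration` hours, then resumes
#' on the accumulated acetate at Monod rate `mu2 * A/(A + ks_a)`.
#' Substrates are expressed in OD-equivalents (yield 1 OD per unit), so
#' `glucose0` directly sets the glucose-phase biomass gain. i.i.d. Gaussian
#' noise (OD units) is added to the sampled OD.
#'
#' The returned truth record carries the analytic growth-rate curve of the
#' noiseless model on a fine grid, the per-phase maxima of that curve
#' (`mu1_real`, `mu2_real` — slightly below the nominal `mu1`, `mu2`
#' because of Monod saturation), the glucose-exhaustion time and the shift
#' time (midpoint of the growth pause).
#'
#' @param mu1 nominal maximum growth rate on glucose (1/h).
#' @param mu2 nominal maximum growth rate on acetate (1/h); must be < mu1.
#' @param od0 initial OD.
#' @param glucose0 initial glucose (OD-equivalents).
#' @param acetate0 acetate present at inoculation (OD-equivalents).
#' @param acetate_yield acetate excreted per OD formed on glucose.
#' @param ks_g,ks_a Monod half-saturation constants (substrate units).
#' @param lag_duration pause between glucose exhaustion and acetate growth (h).
#' @param glucose_threshold glucose level that triggers the pause.
#' @param noise_sd additive Gaussian noise on OD.
#' @param dt sampling interval (h); default 1/3 h (20-minute plate reads).
#' @param t_end end of the record (h).
#' @param n_wells replicate wells (independent noise draws).
#' @param strain,medium metadata labels.
#' @param seed RNG seed for the noise.
#' @return list with `series` (a `PlateTimeSeries`) and `truth` (list:
#'   `mu1_nominal`, `mu2_nominal`, `mu1_real`, `mu2_real`, `t_exhaust`,
#'   `shift_time`, `lag`, `dt`, `grid` data.frame `t`, `od`, `mu`).
#' @export
simulate_diauxic_growth <- function(mu1 = 0.9, mu2 = 0.35, od0 = 0.05,
                                    glucose0 = 1.8, acetate0 = 0,
                                    acetate_yield = 0.3,
                                    ks_g = 0.05, ks_a = 0.01,
                                    lag_duration = 1,
                                    glucose_threshold = 1e-3,
                                    noise_sd = 0.01, dt = 1/3, t_end = 10,
                                    n_wells = 1, strain = "WT",
                                    medium = "glucose", seed = 17) {
  if (dt <= 0) stop("sampling interval must be positive")
  if (!(mu1 > mu2 && mu2 > 0)) stop("need mu1 > mu2 > 0")
  fine_dt <- min(dt, 0.02)
  # stage 1: glucose growth + acetate overflow, stop at glucose threshold
  glu <- function(t, y, p) {
    G <- max(y["G"], 0)
    mu <- mu1 * G / (G + ks_g)
    list(c(X = mu * y["X"], G = -mu * y["X"], A = acetate_yield * mu * y["X"]))
  }
  root_g <- function(t, y, p) y["G"] - glucose_threshold
  if (glucose0 > glucose_threshold) {
    s1 <- deSolve::lsodar(c(X = od0, G = glucose0, A = acetate0),
                          seq(0, t_end, by = fine_dt), glu, parms = NULL,
                          rootfunc = root_g, rtol = 1e-8, atol = 1e-10)
    t_exhaust <- unname(s1[nrow(s1), "time"])
    x_shift <- unname(s1[nrow(s1), "X"])
    a_shift <- unname(s1[nrow(s1), "A"])
  } else {
    s1 <- NULL
    t_exhaust <- 0; x_shift <- od0; a_shift <- acetate0
  }
  # stage 2: pause of lag_duration, then stage 3: acetate growth
  t_resume <- t_exhaust + lag_duration
  ace <- function(t, y, p) {
    A <- max(y["A"], 0)
    mu <- mu2 * A / (A + ks_a)
    list(c(X = mu * y["X"], A = -mu * y["X"]))
  }
  s3 <- if (t_resume < t_end) {
    grid3 <- unique(c(seq(t_resume, t_end, by = fine_dt), t_end))
    deSolve::ode(c(X = x_shift, A = a_shift), grid3, ace, parms = NULL,
                 rtol = 1e-7, atol = 1e-9)
  } else NULL

  od_at <- function(tq) {
    vapply(tq, function(t) {
      if (t <= t_exhaust && !is.null(s1))
        stats::approx(s1[, "time"], s1[, "X"], t)$y
      else if (t <= t_resume || is.null(s3)) x_shift
      else stats::approx(s3[, "time"], s3[, "X"], t)$y
    }, numeric(1))
  }
  mu_at <- function(tq) {
    vapply(tq, function(t) {
      if (t <= t_exhaust && !is.null(s1)) {
        G <- stats::approx(s1[, "time"], s1[, "G"], t)$y
        mu1 * G / (G + ks_g)
      } else if (t <= t_resume || is.null(s3)) 0
      else {
        A <- stats::approx(s3[, "time"], s3[, "A"], t)$y
        mu2 * A / (A + ks_a)
      }
    }, numeric(1))
  }
  times <- seq(0, t_end, by = dt)
  od_true <- od_at(times)
  fine_t <- seq(0, t_end, by = fine_dt)
  truth <- list(
    mu1_nominal = mu1, mu2_nominal = mu2,
    mu1_real = if (!is.null(s1)) max(mu_at(fine_t[fine_t <= t_exhaust]))
               else NA_real_,
    mu2_real = if (t_resume < t_end) max(mu_at(fine_t[fine_t > t_resume])) else NA_real_,
    t_exhaust = t_exhaust, shift_time = t_exhaust + lag_duration / 2,
    lag = lag_duration, dt = dt,
    grid = data.frame(t = fine_t, od = od_at(fine_t), mu = mu_at(fine_t)))
  noise <- with_local_seed(seed,
    matrix(stats::rnorm(length(times) * n_wells, 0, noise_sd),
           ncol = n_wells))
  od <- matrix(od_true, nrow = length(times), ncol = n_wells) + noise
  colnames(od) <- paste0("W", seq_len(n_wells))
  wells <- data.frame(well = colnames(od), strain = strain, medium = medium,
                      replicate = seq_len(n_wells))
  list(series = plate_time_series(times, od, wells), truth = truth)
}

# simple saturating growth curve used by the reporter simulators:
# exponential at rate mu from od0 up to a carrying capacity K (logistic)
logistic_od <- function(times, mu, od0 = 0.05, K = 1.5) {
  K * od0 * exp(mu * times) / (K + od0 * (exp(mu * times) - 1))
}

#' Simulate ribosome-reporter wells on a per-strain allocation line
#'
#' Each condition grows logistically at its medium's growth rate mu and
#' carries a fluorescence channel F(t) = (a + b mu) * OD(t) * (1 + eps),
#' i.e. the normalized signal F/OD sits on the strain's allocation line
#' a + b mu with multiplicative noise. Ground truth (a, b) per strain is
#' returned for test oracles.
#'
#' @param strains data.frame with columns `strain`, `intercept` (a),
#'   `slope` (b).
#' @param mu_values growth rates of the media (1/h); the medium label is
#'   `M<i>`.
#' @param noise_frac multiplicative noise sd on fluorescence (default 0.03).
#' @param dt,t_end sampling grid (h).
#' @param od0,K logistic growth-curve parameters.
#' @param seed RNG seed.
#' @return list with `series` (`PlateTimeSeries` with a GFP channel; one
#'   well per strain x medium) and `truth` (data.frame: well, strain,
#'   medium, mu, a, b, f_norm_true = a + b mu).
#' @export
simulate_reporter_allocation <- function(strains,
                                         mu_values = seq(0.25, 1.67,
                                                         length.out = 11),
                                         noise_frac = 0.03, dt = 1/3,
                                         t_end = 8, od0 = 0.05, K = 1.5,
                                         seed = 17) {
  stopifnot(all(c("strain", "intercept", "slope") %in% names(strains)))
  times <- seq(0, t_end, by = dt)
  combos <- expand.grid(si = seq_len(nrow(strains)),
                        mi = seq_along(mu_values))
  n <- nrow(combos)
  eps <- with_local_seed(seed,
    matrix(stats::rnorm(length(times) * n, 0, noise_frac), ncol = n))
  od <- matrix(NA_real_, length(times), n)
  gfp <- matrix(NA_real_, length(times), n)
  truth <- vector("list", n)
  for (k in seq_len(n)) {
    s <- strains[combos$si[k], ]; mu <- mu_values[combos$mi[k]]
    od[, k] <- logistic_od(times, mu, od0, K)
    f_true <- s$intercept + s$slope * mu
    gfp[, k] <- f_true * od[, k] * (1 + eps[, k])
    truth[[k]] <- data.frame(well = paste0("W", k), strain = s$strain,
                             medium = paste0("M", combos$mi[k]), mu = mu,
                             a = s$intercept, b = s$slope,
                             f_norm_true = f_true)
  }
  colnames(od) <- colnames(gfp) <- paste0("W", seq_len(n))
  truth <- do.call(rbind, truth)
  wells <- data.frame(well = truth$well, strain = truth$strain,
                      medium = truth$medium, replicate = 1)
  list(series = plate_time_series(times, od, wells,
                                  channels = list(GFP = gfp)),
       truth = truth)
}

#' Simulate allocation points directly on a strain's allocation line
#'
#' Lightweight companion to [simulate_reporter_allocation()] for
#' statistical calibration studies: emits (mu, f_norm) pairs with
#' multiplicative noise on f_norm and the growth rates taken as exact
#' design values, bypassing the plate/GP stack.
#'
#' @param intercept,slope the allocation line f_norm = intercept +
#'   slope * mu.
#' @param mu_values design growth rates (1/h).
#' @param noise_frac multiplicative noise sd on f_norm (default 0.05).
#' @param seed RNG seed.
#' @return data.frame with columns `mu`, `f_norm`, `medium`.
#' @export
simulate_allocation_points <- function(intercept = 2, slope = 3,
                                       mu_values = seq(0.25, 1.67,
                                                       length.out = 11),
                                       noise_frac = 0.05, seed = 17) {
  f_true <- intercept + slope * mu_values
  eps <- with_local_seed(seed,
    stats::rnorm(length(mu_values), 0, noise_frac))
  data.frame(mu = mu_values, f_norm = f_true * (1 + eps),
             medium = paste0("M", seq_along(mu_values)))
}

# piecewise-linear (triangular) promoter-activity pulse: 0 before t_on,
# rising at rise_rate to the peak, falling at fall_rate (negative) to 0
triangular_pa <- function(t, t_on, rise_rate, t_peak, fall_rate) {
  peak <- rise_rate * (t_peak - t_on)
  ifelse(t < t_on, 0,
         ifelse(t <= t_peak, rise_rate * (t - t_on),
                pmax(peak + fall_rate * (t - t_peak), 0)))
}

#' Simulate an aceB-like promoter-reporter well with known PA*(t)
#'
#' Builds GFP by integrating a prescribed promoter-activity pulse against
#' the OD curve: GFP(t) = GFP(0) + integral of PA*(tau) OD(tau) dtau (+
#' multiplicative noise). The default pulse rises linearly from `t_on` to a
#' peak hours before the growth shift and decays linearly after it, the
#' shape seen for the aceB promoter ahead of the glucose-acetate
#' transition.
#'
#' @param rise_rate PA rise slope (a.u./OD/h per h).
#' @param fall_rate PA fall slope (negative).
#' @param t_on PA onset time (h).
#' @param t_peak PA peak time (h).
#' @param growth list of arguments for [simulate_diauxic_growth()] (noise
#'   is applied to GFP only; the OD channel keeps its own noise setting).
#' @param gfp0 initial GFP (a.u.); kept small relative to the integrated
#'   reporter signal, as for an induced promoter rising well above
#'   autofluorescence background.
#' @param noise_frac multiplicative GFP noise sd (default 0.01, a typical
#'   plate-reader fluorescence CV).
#' @param seed RNG seed.
#' @return list with `series` (`PlateTimeSeries`, channels GFP), `truth`
#'   (list: `pa_fun`, `rise_rate`, `fall_rate`, `t_on`, `t_peak`,
#'   `pa_peak`, plus the growth truth record).
#' @export
simulate_promoter_reporter <- function(rise_rate = 2, fall_rate = -5,
                                       t_on = 0, t_peak = 3.75,
                                       growth = list(noise_sd = 0),
                                       gfp0 = 0.5, noise_frac = 0.01,
                                       seed = 17) {
  stopifnot(rise_rate > 0, fall_rate < 0)
  sim <- do.call(simulate_diauxic_growth,
                 utils::modifyList(list(seed = seed), growth))
  if (t_peak >= sim$truth$shift_time)
    warning("PA peak at or after the growth shift; aceB-like pulses peak before it")
  pa_fun <- function(t) triangular_pa(t, t_on, rise_rate, t_peak, fall_rate)
  g <- sim$truth$grid                     # fine noiseless grid
  integrand <- pa_fun(g$t) * g$od
  cum <- c(0, cumsum((integrand[-1] + integrand[-nrow(g)]) / 2 * diff(g$t)))
  times <- sim$series$times
  gfp_true <- gfp0 + stats::approx(g$t, cum, times)$y
  eps <- with_local_seed(seed + 1,
    stats::rnorm(length(times), 0, noise_frac))
  gfp <- matrix(gfp_true * (1 + eps), ncol = 1,
                dimnames = list(NULL, colnames(sim$series$od)[1]))
  series <- plate_time_series(times, sim$series$od[, 1, drop = FALSE],
                              sim$series$wells[1, , drop = FALSE],
                              channels = list(GFP = gfp))
  list(series = series,
       truth = list(pa_fun = pa_fun, rise_rate = rise_rate,
                    fall_rate = fall_rate, t_on = t_on, t_peak = t_peak,
                    pa_peak = rise_rate * (t_peak - t_on),
                    gfp0 = gfp0, growth = sim$truth))
}

#' Simulate a gene budget table with planted mass-contribution totals
#'
#' Draws per-gene protein copies, molecular weights and WT transcript
#' abundances, assigns up/down labels to the stated fractions, applies
#' log2 fold changes to get mutant transcripts, and computes the true mass
#' deltas with the same translation-efficiency model the pipeline uses.
#' When `up_total_fg` / `down_total_fg` are given, the fold changes are
#' rescaled (in transcript space, which is exact because delta is linear in
#' r_mut - r_wt) so the direction totals hit the planted targets exactly.
#'
#' @param n_genes number of genes.
#' @param frac_up,frac_down fractions of genes up-/down-regulated.
#' @param lfc_sd sd of the log2 fold changes (mean +/-1 for up/down).
#' @param up_total_fg,down_total_fg planted direction totals (sum of
#'   |delta| in fg), or `NULL` to leave the draws unscaled.
#' @param copies_meanlog,copies_sdlog lognormal parameters for protein
#'   copies per cell.
#' @param mw_meanlog,mw_sdlog lognormal parameters for molecular weight
#'   (g/mol).
#' @param seed RNG seed.
#' @return list with `table` (a `GeneBudgetTable`-shaped data.frame) and
#'   `truth` (data.frame: id, s_i, delta_fg, direction, category).
#' @export
simulate_budget_tables <- function(n_genes = 1000, frac_up = 0.1,
                                   frac_down = 0.1, lfc_sd = 0.5,
                                   up_total_fg = NULL, down_total_fg = NULL,
                                   copies_meanlog = log(500),
                                   copies_sdlog = 1.2,
                                   mw_meanlog = log(35000), mw_sdlog = 0.45,
                                   seed = 17) {
  stopifnot(frac_up >= 0, frac_down >= 0, frac_up + frac_down <= 1)
  d <- with_local_seed(seed, {
    copies <- stats::rlnorm(n_genes, copies_meanlog, copies_sdlog)
    mw <- stats::rlnorm(n_genes, mw_meanlog, mw_sdlog)
    r_wt <- stats::rlnorm(n_genes, log(50), 1)
    n_up <- round(frac_up * n_genes); n_down <- round(frac_down * n_genes)
    dir <- sample(rep(c("up", "down", "unchanged"),
                      c(n_up, n_down, n_genes - n_up - n_down)))
    lfc <- ifelse(dir == "up", stats::rnorm(n_genes, 1, lfc_sd),
                  ifelse(dir == "down", stats::rnorm(n_genes, -1, lfc_sd), 0))
    lfc[dir == "up"] <- pmax(lfc[dir == "up"], 0.1)
    lfc[dir == "down"] <- pmin(lfc[dir == "down"], -0.1)
    cat_pool <- c("growth", "hedging", "other")
    category <- sample(cat_pool, n_genes, replace = TRUE,
                       prob = c(0.35, 0.35, 0.3))
    list(copies = copies, mw = mw, r_wt = r_wt, dir = dir, lfc = lfc,
         category = category)
  })
  s_i <- d$copies / d$r_wt
  r_mut <- d$r_wt * 2^d$lfc
  delta <- (r_mut - d$r_wt) * s_i * d$mw / AVOGADRO * FG_PER_G
  # rescale transcript differences so planted direction totals are exact
  rescale <- function(which_dir, target) {
    idx <- d$dir == which_dir
    tot <- sum(abs(delta[idx]))
    if (tot > 0 && !is.null(target)) {
      f <- target / tot
      r_mut[idx] <<- d$r_wt[idx] + (r_mut[idx] - d$r_wt[idx]) * f
      delta[idx] <<- delta[idx] * f
    }
  }
  rescale("up", up_total_fg)
  rescale("down", down_total_fg)
  ids <- sprintf("g%04d", seq_len(n_genes))
  table <- data.frame(id = ids, r_wt = d$r_wt, r_mut = r_mut,
                      copies_wt = d$copies, mw = d$mw,
                      direction = d$dir, category = d$category,
                      stringsAsFactors = FALSE)
  truth <- data.frame(id = ids, s_i = s_i, delta_fg = delta,
                      direction = d$dir, category = d$category,
                      stringsAsFactors = FALSE)
  list(table = table, truth = truth)
}

#' Simulate a dual-reporter isocost experiment
#'
#' One well per inducer level: growth is exponential through the matching
#' OD, the induced reporter's per-OD output rises with the level, and the
#' constitutive reporter sits on the isocost line
#' gfp = budget + slope * rfp with multiplicative noise. Channels are
#' stored as F(t) = (F/OD) * OD(t) so [match_expression()] is exercised
#' end-to-end.
#'
#' @param budget GFP-axis intercept (a.u.), the planted budget.
#' @param slope isocost slope (negative).
#' @param levels inducer concentrations; default the four AHL levels
#'   0, 2.5, 5 and 20 nM.
#' @param rfp_max per-OD RFP output at the highest level (saturating
#'   Michaelis-type response, half-max at `k_ind`).
#' @param k_ind inducer half-saturation.
#' @param mu growth rate of the wells (1/h).
#' @param noise_frac multiplicative noise sd on both reporters.
#' @param dt,t_end,od0 sampling grid and inoculum.
#' @param strain metadata label.
#' @param seed RNG seed.
#' @return list with `series` (`PlateTimeSeries`, channels GFP and RFP,
#'   one well per level), `levels` (well -> level mapping) and `truth`
#'   (data.frame: level, rfp_true, gfp_true; plus `budget`, `slope`).
#' @export
simulate_isocost <- function(budget = 1000, slope = -2,
                             levels = c(0, 2.5, 5, 20), rfp_max = 300,
                             k_ind = 4, mu = 0.6, noise_frac = 0.03,
                             dt = 1/3, t_end = 6, od0 = 0.02,
                             strain = "WT", seed = 17) {
  if (length(levels) < 3) stop("need at least 3 inducer levels")
  times <- seq(0, t_end, by = dt)
  od_curve <- od0 * exp(mu * times)
  n <- length(levels)
  eps <- with_local_seed(seed,
    matrix(stats::rnorm(2 * n, 0, noise_frac), ncol = 2))
  rfp_true <- rfp_max * levels / (levels + k_ind)
  gfp_true <- budget + slope * rfp_true
  od <- matrix(od_curve, length(times), n)
  gfp <- sweep(od, 2, gfp_true * (1 + eps[, 1]), "*")
  rfp <- sweep(od, 2, rfp_true * (1 + eps[, 2]), "*")
  wells <- paste0("L", seq_len(n))
  colnames(od) <- colnames(gfp) <- colnames(rfp) <- wells
  meta <- data.frame(well = wells, strain = strain, medium = "glucose",
                     replicate = seq_len(n))
  list(series = plate_time_series(times, od, meta,
                                  channels = list(GFP = gfp, RFP = rfp)),
       levels = stats::setNames(as.list(levels), wells),
       truth = data.frame(level = levels,
                          rfp_true = rfp_true * (1 + eps[, 2]),
                          gfp_true = gfp_true * (1 + eps[, 1]),
                          budget = budget, slope = slope))
}
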