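#' Gaussian-process regression with analytic derivative of the posterior mean
#'
#' Fits a zero-mean GP (after centring) with a squared-exponential kernel
#' \deqn{k(t, t') = a^2 \exp\{-(t - t')^2 / (2\ell^2)\} + \sigma_n^2 \delta_{tt'}}
#' to scalar observations `y` at times `t`, choosing the hyperparameters
#' (amplitude `a`, length-scale `ell`, noise sd `sigma_n`) by maximizing the
#' log marginal likelihood with L-BFGS-B from several seeded starting points.
#' The posterior mean and its analytic first derivative (with the pointwise
#' sd of the derivative process) can then be evaluated anywhere.
#'
#' A linear mean function (OLS trend in `t`) is fitted first and the GP
#' models the residuals; the trend slope is added back to the derivative.
#' For growth curves this keeps the residual process near-stationary and
#' prevents the posterior mean from bowing at the record edges, where a
#' constant-mean GP would otherwise inflate the derivative.
#'
#' This is the derivative-estimation engine behind [fit_growth_curve()] and
#' [compute_pa()]; it is deliberately small (dense Cholesky, one-dimensional
#' inputs) because plate-reader series have at most a few hundred points.
#'
#' @param t numeric vector of observation times (hours), strictly increasing.
#' @param y numeric vector of observations, same length as `t`.
#' @param lengthscale_bounds length-2 numeric, bounds for `ell` in hours.
#'   Default `c(2 * median(diff(t)), diff(range(t)))`.
#' @param noise_bounds length-2 numeric, bounds for `sigma_n` (units of `y`).
#' @param amplitude_bounds length-2 numeric, bounds for `a` (units of `y`).
#' @param n_restarts number of optimizer starting points (the first is a
#'   data-driven heuristic, the rest are drawn uniformly in log-space).
#' @param seed integer seed controlling the random restarts.
#' @param noise_weights optional positive vector of relative noise
#'   variances (length of `y`): the noise variance at point i is
#'   `sigma_n^2 * noise_weights[i]`, with the weights normalized to
#'   minimum 1 so `sigma_n` is the noise sd at the best-measured point.
#'   Used for log-transformed OD, where additive instrument noise has
#'   variance proportional to 1/OD^2 on the log scale.
#' @return an object of class `gp_fit`: list with elements `t`, `y`,
#'   `hyperparams` (named: amplitude, lengthscale, noise_sd),
#'   `log_marginal_likelihood`, `mean_y`, `alpha`, `L` (Cholesky factor),
#'   and `converged`.
#' @export
gp_fit <- function(t, y,
                   lengthscale_bounds = NULL,
                   noise_bounds = c(1e-4, 1),
                   amplitude_bounds = NULL,
                   n_restarts = 5,
                   seed = 17,
                   noise_weights = NULL) {
  stopifnot(is.numeric(t), is.numeric(y), length(t) == length(y))
  if (length(t) < 3) stop("gp_fit needs at least 3 points")
  if (any(diff(t) <= 0)) stop("times must be strictly increasing")
  n <- length(t)
  # precision-weighted linear trend (GLS under the declared noise model)
  wt <- if (is.null(noise_weights)) rep(1, n) else 1 / noise_weights
  trend <- stats::lm.wfit(cbind(1, t), y, w = wt)
  beta <- unname(trend$coefficients)
  yc <- unname(trend$residuals)
  span <- diff(range(t))
  dt_med <- stats::median(diff(t))
  if (is.null(lengthscale_bounds)) lengthscale_bounds <- c(2 * dt_med, span)
  sd_y <- stats::sd(yc)
  if (!is.finite(sd_y) || sd_y < 1e-9 * max(1, abs(beta[1]))) {
    # (near-)exactly linear signal: the trend is the whole fit
    hp <- c(amplitude = noise_bounds[1], lengthscale = lengthscale_bounds[2],
            noise_sd = noise_bounds[1])
    return(structure(list(t = t, y = y, hyperparams = hp,
                          log_marginal_likelihood = NA_real_,
                          beta = beta,
                          alpha = rep(0, n), L = NULL, converged = TRUE,
                          constant = TRUE),
                     class = "gp_fit"))
  }
  if (is.null(amplitude_bounds)) amplitude_bounds <- c(1e-3 * sd_y, 10 * sd_y)

  D2 <- outer(t, t, "-")^2
  if (is.null(noise_weights)) {
    w <- rep(1, n)
  } else {
    stopifnot(length(noise_weights) == n, all(noise_weights > 0))
    w <- noise_weights / min(noise_weights)
  }
  lower <- log(c(amplitude_bounds[1], lengthscale_bounds[1], noise_bounds[1]))
  upper <- log(c(amplitude_bounds[2], lengthscale_bounds[2], noise_bounds[2]))

  # Maximum-likelihood noise estimates from a few dozen points are unstable
  # (the optimizer can absorb noise into a short length-scale). Anchor the
  # noise sd with a weakly-informative lognormal prior centred on a robust
  # second-difference estimate, which is nearly signal-free for smooth
  # growth-scale trends.
  if (n >= 6) {
    d2 <- diff(yc, differences = 2)
    denom <- sqrt(w[seq_len(n - 2)] + 4 * w[seq(2, n - 1)] + w[seq(3, n)])
    s_hat <- stats::mad(d2 / denom)
  } else s_hat <- sd_y / 2
  s_hat <- min(max(s_hat, noise_bounds[1]), noise_bounds[2])
  prior_sd <- 0.5

  nll <- function(theta) {
    a2 <- exp(2 * theta[1]); l2 <- exp(2 * theta[2]); s2 <- exp(2 * theta[3])
    K <- a2 * exp(-0.5 * D2 / l2)
    diag(K) <- diag(K) + s2 * w + 1e-10 * a2
    L <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(L)) return(1e10)
    alpha <- backsolve(L, forwardsolve(t(L), yc))
    as.numeric(0.5 * sum(yc * alpha) + sum(log(diag(L))) +
                 0.5 * n * log(2 * pi) +
                 0.5 * ((theta[3] - log(s_hat)) / prior_sd)^2)
  }
  nll_grad <- function(theta) {
    a2 <- exp(2 * theta[1]); l2 <- exp(2 * theta[2]); s2 <- exp(2 * theta[3])
    Kse <- a2 * exp(-0.5 * D2 / l2)
    K <- Kse
    diag(K) <- diag(K) + s2 * w + 1e-10 * a2
    L <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(L)) return(c(0, 0, 0))
    alpha <- backsolve(L, forwardsolve(t(L), yc))
    Kinv <- chol2inv(L)
    W <- Kinv - tcrossprod(alpha)     # -(alpha alpha' - K^-1)
    g <- function(dK) 0.5 * sum(W * dK)
    dK_da <- 2 * Kse
    dK_dl <- Kse * (D2 / l2)
    dK_ds <- diag(2 * s2 * w, n)
    c(g(dK_da), g(dK_dl),
      g(dK_ds) + (theta[3] - log(s_hat)) / prior_sd^2)
  }

  # starting points: one heuristic + seeded uniform draws in log-space
  starts <- matrix(NA_real_, nrow = n_restarts, ncol = 3)
  starts[1, ] <- pmin(pmax(log(c(sd_y, span / 4, 0.1 * sd_y)), lower), upper)
  if (n_restarts > 1) {
    u <- with_local_seed(seed, stats::runif(3 * (n_restarts - 1)))
    u <- matrix(u, ncol = 3)
    for (j in 1:3) starts[-1, j] <- lower[j] + u[, j] * (upper[j] - lower[j])
  }

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[i, ], nll, nll_grad, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    stop("GP hyperparameter optimization failed from every start; last starts: ",
         paste(signif(exp(starts[nrow(starts), ]), 3), collapse = ", "))
  }

  theta <- best$par
  a2 <- exp(2 * theta[1]); l2 <- exp(2 * theta[2]); s2 <- exp(2 * theta[3])
  K <- a2 * exp(-0.5 * D2 / l2)
  diag(K) <- diag(K) + s2 * w + 1e-10 * a2
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), yc))
  structure(list(
    t = t, y = y,
    hyperparams = c(amplitude = sqrt(a2), lengthscale = sqrt(l2),
                    noise_sd = sqrt(s2)),
    log_marginal_likelihood = -best$value,
    beta = beta, alpha = alpha, L = L,
    converged = best$convergence == 0,
    constant = FALSE), class = "gp_fit")
}

#' Evaluate a fitted GP posterior mean, derivative and their uncertainties
#'
#' @param object a [gp_fit()] object.
#' @param t_new times at which to evaluate (defaults to the training times).
#' @param ... unused.
#' @return data.frame with columns `t`, `mean`, `sd` (posterior sd of the
#'   latent function), `deriv` (analytic derivative of the posterior mean)
#'   and `deriv_sd` (posterior sd of the derivative process).
#' @export
predict.gp_fit <- function(object, t_new = object$t, ...) {
  b <- object$beta
  if (isTRUE(object$constant)) {
    return(data.frame(t = t_new, mean = b[1] + b[2] * t_new,
                      sd = 0, deriv = rep(b[2], length(t_new)),
                      deriv_sd = 0))
  }
  hp <- object$hyperparams
  a2 <- hp[["amplitude"]]^2; l2 <- hp[["lengthscale"]]^2
  Dn <- outer(t_new, object$t, "-")
  Ks <- a2 * exp(-0.5 * Dn^2 / l2)
  dKs <- -Ks * Dn / l2
  mu <- as.numeric(Ks %*% object$alpha) + b[1] + b[2] * t_new
  dmu <- as.numeric(dKs %*% object$alpha) + b[2]
  # pointwise variances via the Cholesky factor
  V <- forwardsolve(t(object$L), t(Ks))
  var_f <- pmax(a2 - colSums(V^2), 0)
  Vd <- forwardsolve(t(object$L), t(dKs))
  var_d <- pmax(a2 / l2 - colSums(Vd^2), 0)
  data.frame(t = t_new, mean = mu, sd = sqrt(var_f),
             deriv = dmu, deriv_sd = sqrt(var_d))
}

#' @export
print.gp_fit <- function(x, ...) {
  cat("Gaussian-process fit (squared-exponential kernel)\n")
  cat(sprintf("  n = %d points over [%.3g, %.3g]\n",
              length(x$t), min(x$t), max(x$t)))
  hp <- x$hyperparams
  cat(sprintf("  amplitude = %.4g, length-scale = %.4g, noise sd = %.4g\n",
              hp[["amplitude"]], hp[["lengthscale"]], hp[["noise_sd"]]))
  cat(sprintf("  log marginal likelihood = %.4g\n", x$log_marginal_likelihood))
  invisible(x)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library code never perturbs user simulations.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
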