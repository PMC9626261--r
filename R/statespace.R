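# Kalman machinery for the latent-trend model
#
#   y(t)     = x(t) + eps(t),        eps ~ N(0, sigma2)
#   x(t+1)   = x(t) + v(t)
#   v(t+1)   = v(t) + eta(t),        eta ~ N(0, sigma2_eta)
#
# i.e. the observed log-parameter equals a latent level plus noise, the
# level advances by a velocity (the log relative fitness), and the velocity
# itself drifts as a random walk. `order` >= 2 adds higher time-derivative
# states, with the innovation on the highest derivative only.

ssm_matrices <- function(order) {
  m <- order + 1L
  Tm <- diag(m)
  Tm[cbind(seq_len(m - 1L), seq_len(m - 1L) + 1L)] <- 1
  list(m = m, Tm = Tm)
}

# forward filter; returns filtered/predicted moments and the log-likelihood
ssm_filter <- function(y, order, sigma2, sigma2_eta, kappa = NULL) {
  n <- length(y)
  mats <- ssm_matrices(order)
  m <- mats$m; Tm <- mats$Tm
  if (is.null(kappa)) kappa <- 1e7 * max(var(y), 1e-8)
  Q <- matrix(0, m, m); Q[m, m] <- sigma2_eta
  a <- c(y[1], rep(0, m - 1L))
  P <- diag(kappa, m)
  a_pred <- matrix(NA_real_, m, n); P_pred <- array(NA_real_, c(m, m, n))
  a_filt <- matrix(NA_real_, m, n); P_filt <- array(NA_real_, c(m, m, n))
  ll <- 0
  n_skip <- m  # drop diffuse-dominated terms
  for (t in seq_len(n)) {
    a_pred[, t] <- a; P_pred[, , t] <- P
    v <- y[t] - a[1]
    Fv <- P[1, 1] + sigma2
    if (t > n_skip) ll <- ll - 0.5 * (log(2 * pi * Fv) + v * v / Fv)
    Kg <- P[, 1] / Fv
    a <- a + Kg * v
    P <- P - tcrossprod(Kg, P[1, ])
    P <- (P + t(P)) / 2
    a_filt[, t] <- a; P_filt[, , t] <- P
    # time update
    a <- drop(Tm %*% a)
    P <- Tm %*% P %*% t(Tm) + Q
  }
  list(loglik = ll, a_pred = a_pred, P_pred = P_pred,
       a_filt = a_filt, P_filt = P_filt, Tm = Tm, m = m)
}

ssm_smooth <- function(flt) {
  n <- ncol(flt$a_filt); m <- flt$m; Tm <- flt$Tm
  a_s <- flt$a_filt; P_s <- flt$P_filt
  for (t in seq(n - 1L, 1L)) {
    Pp <- flt$P_pred[, , t + 1L]
    ridge <- 1e-10 * (1 + max(abs(diag(Pp))))
    J <- flt$P_filt[, , t] %*% t(Tm) %*% solve(Pp + diag(ridge, m))
    a_s[, t] <- flt$a_filt[, t] + drop(J %*% (a_s[, t + 1L] - flt$a_pred[, t + 1L]))
    P_s[, , t] <- flt$P_filt[, , t] +
      J %*% (P_s[, , t + 1L] - Pp) %*% t(J)
  }
  list(a = a_s, P = P_s)
}

#' Fit a latent-trend state-space model to a parameter series
#'
#' Fits the model `y(t) = x(t) + eps(t)`, `x(t+1) = x(t) + v(t)`,
#' `v(t+1) = v(t) + eta(t)` to a real-valued series (typically a
#' log-transformed mixture parameter), where the latent velocity `v(t)` is
#' the log relative fitness driving the replicator dynamics of the series.
#' The two noise variances are estimated by maximizing the marginal
#' likelihood computed by a forward Kalman filter with diffuse
#' initialization; smoothed level and velocity paths are obtained by the
#' Rauch-Tung-Striebel smoother. `order >= 2` adds states for higher time
#' derivatives (the Gaussian innovation then enters the highest derivative
#' only).
#'
#' @param y Numeric series of at least 4 finite observations, in time order.
#' @param order Number of latent derivative states (default 1: level +
#'   velocity).
#' @param sigma2,sigma2_eta Optional fixed values for the observation-noise
#'   and velocity-innovation variances; when supplied the corresponding
#'   parameter is not estimated (use `sigma2_eta = 0` for a constant-velocity
#'   trend, which reproduces the least-squares line on noiseless input).
#' @return An object of class `trend_ssm`: list with `y`, `order`,
#'   `sigma2`, `sigma2_eta`, smoothed `level` and `velocity` vectors,
#'   filtered counterparts, one-step-ahead predictions `pred`, and
#'   `loglik`. `tidy()` returns the per-time smoothed states; `glance()` the
#'   scalar summaries.
#' @examples
#' fit <- fit_trend_ssm(3 + 0.5 * (1:20))
#' tail(fit$velocity, 1) # ~0.5
#' @export
fit_trend_ssm <- function(y, order = 1, sigma2 = NULL, sigma2_eta = NULL) {
  y <- as.numeric(y)
  if (length(y) < 4) abort("series must have at least 4 observations")
  if (any(!is.finite(y))) abort("series must be finite")
  n <- length(y)
  s2y <- var(y)

  if (s2y == 0) {
    # perfectly constant series: zero-noise, zero-velocity fit
    out <- list(y = y, order = as.integer(order), sigma2 = 0, sigma2_eta = 0,
                level = y, velocity = rep(0, n),
                level_filt = y, velocity_filt = rep(0, n),
                pred = y, loglik = Inf)
    class(out) <- "trend_ssm"
    return(out)
  }

  lo <- log(s2y) + log(1e-10)
  hi <- log(s2y) + log(1e4)
  fixed_s2 <- !is.null(sigma2)
  fixed_se <- !is.null(sigma2_eta)
  nll <- function(par) {
    i <- 1L
    if (!fixed_s2) { s2 <- exp(par[i]); i <- i + 1L } else s2 <- sigma2
    se <- if (fixed_se) sigma2_eta else exp(par[i])
    -ssm_filter(y, order, s2, se)$loglik
  }
  n_free <- 2L - fixed_s2 - fixed_se
  if (n_free > 0) {
    starts <- list(c(log(0.5 * s2y), log(0.05 * s2y)),
                   c(log(0.05 * s2y), log(0.5 * s2y)),
                   c(log(0.9 * s2y), log(1e-4 * s2y)))
    best <- NULL
    for (st in starts) {
      p0 <- c(if (!fixed_s2) st[1], if (!fixed_se) st[2])
      opt <- tryCatch(
        optim(p0, nll, method = "L-BFGS-B",
              lower = rep(lo, n_free), upper = rep(hi, n_free)),
        error = function(e) NULL)
      if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
    }
    if (is.null(best)) abort("state-space likelihood maximization failed")
    par <- best$par
    i <- 1L
    if (!fixed_s2) { sigma2 <- exp(par[i]); i <- i + 1L }
    if (!fixed_se) sigma2_eta <- exp(par[i])
    loglik <- -best$value
  } else {
    loglik <- -nll(numeric(0))
  }

  flt <- ssm_filter(y, order, sigma2, sigma2_eta)
  sm <- ssm_smooth(flt)
  out <- list(y = y, order = as.integer(order),
              sigma2 = sigma2, sigma2_eta = sigma2_eta,
              level = sm$a[1, ], velocity = sm$a[2, ],
              level_filt = flt$a_filt[1, ], velocity_filt = flt$a_filt[2, ],
              pred = flt$a_pred[1, ], loglik = loglik)
  class(out) <- "trend_ssm"
  out
}

#' @export
print.trend_ssm <- function(x, ...) {
  cat(sprintf("Latent-trend state-space fit (order %d, n = %d)\n", x$order, length(x$y)))
  cat(sprintf("  sigma2 = %.4g, sigma2_eta = %.4g, terminal velocity = %.4g\n",
              x$sigma2, x$sigma2_eta, tail(x$velocity, 1)))
  invisible(x)
}

#' @export
tidy.trend_ssm <- function(x, ...) {
  tibble(time = seq_along(x$y), y = x$y, level = x$level, velocity = x$velocity)
}

#' @export
glance.trend_ssm <- function(x, ...) {
  tibble(order = x$order, n = length(x$y), sigma2 = x$sigma2,
         sigma2_eta = x$sigma2_eta, logLik = x$loglik,
         terminal_velocity = tail(x$velocity, 1))
}

#' Forecast a fitted trend with a fitness reduction factor
#'
#' Extrapolates the terminal smoothed level linearly with the terminal
#' smoothed velocity damped by the reduction factor `rho`:
#' `x(T + h) = x(T) + h * rho * v(T)`. `rho = 1` trusts the inferred trend
#' fully; small `rho` yields conservative, near-static forecasts.
#'
#' @param fit A [fit_trend_ssm()] object.
#' @param horizon Number of steps ahead (`>= 1`).
#' @param rho Fitness reduction factor in `[0.01, 1]`.
#' @return Numeric vector of length `horizon` with the forecast values.
#' @export
forecast_trend <- function(fit, horizon, rho = 1) {
  if (horizon < 1) abort("`horizon` must be at least 1")
  if (rho < 0.01 || rho > 1) abort("`rho` must lie in [0.01, 1]")
  xT <- tail(fit$level, 1)
  vT <- tail(fit$velocity, 1)
  xT + seq_len(horizon) * rho * vT
}
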