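#' Dirichlet log-density
#'
#' Evaluates the log of the Dirichlet density
#' `Dir(theta; alpha, mu) = Gamma(alpha) / prod_i Gamma(alpha mu_i) *
#' prod_i theta_i^(alpha mu_i - 1)` at one or more probability vectors,
#' using log-gamma throughout. Under this mean/concentration
#' parameterization the component-wise moments are `E(theta_i) = mu_i` and
#' `V(theta_i) = mu_i (1 - mu_i) / (alpha + 1)`, so `mu` is the cluster
#' centre and `alpha` controls its size.
#'
#' @param theta A probability vector, or a matrix with one probability
#'   vector per row. All components must be strictly positive (apply
#'   [floor_renormalize()] first if zeros may occur).
#' @param alpha Positive concentration parameter.
#' @param mu Mean distribution, same length as `theta` (columns).
#' @return Numeric vector of log-densities (nats), one per row of `theta`.
#' @examples
#' dirichlet_log_density(c(0.3, 0.7), alpha = 2, mu = c(0.5, 0.5)) # 0: uniform
#' @export
dirichlet_log_density <- function(theta, alpha, mu) {
  if (!is.matrix(theta)) theta <- matrix(theta, nrow = 1)
  if (ncol(theta) != length(mu)) abort("`theta` and `mu` dimensions differ")
  if (alpha <= 0) abort("`alpha` must be positive")
  if (any(theta <= 0))
    abort("`theta` has non-positive components; floor and renormalize first")
  a_mu <- alpha * mu
  const <- lgamma(alpha) - sum(lgamma(a_mu))
  drop(log(theta) %*% (a_mu - 1)) + const
}

# weighted profile log-likelihood of alpha with mu fixed
dirichlet_alpha_loglik <- function(alpha, mu, log_theta_wsum, w_total) {
  a_mu <- alpha * mu
  w_total * (lgamma(alpha) - sum(lgamma(a_mu))) + sum(a_mu * log_theta_wsum) -
    sum(log_theta_wsum)
}

# maximize over ln alpha on [ln alpha_min, ln alpha_max]
estimate_dirichlet_alpha <- function(theta, weights, mu,
                                     alpha_min = 1e-2, alpha_max = 1e6) {
  lt <- log(theta)
  s <- drop(crossprod(lt, weights)) # sum_j w_j log theta_ji
  w_total <- sum(weights)
  f <- function(la) dirichlet_alpha_loglik(exp(la), mu, s, w_total)
  opt <- optimize(f, interval = c(log(alpha_min), log(alpha_max)), maximum = TRUE,
                  tol = 1e-8)
  alpha <- exp(opt$maximum)
  boundary <- NULL
  if (opt$maximum >= log(alpha_max) - 1e-4) {
    alpha <- alpha_max
    boundary <- "upper"
  } else if (opt$maximum <= log(alpha_min) + 1e-4) {
    alpha <- alpha_min
    boundary <- "lower"
  }
  list(alpha = alpha, boundary = boundary, loglik = f(log(alpha)))
}

#' Fit a Dirichlet distribution to probability vectors
#'
#' Estimates the mean distribution `mu` as the (weighted) arithmetic mean of
#' the input vectors and the concentration `alpha` by maximizing the
#' (weighted) Dirichlet log-likelihood with `mu` held fixed, via 1-D
#' maximization over `ln alpha` on `[ln alpha_min, ln alpha_max]`. When the
#' input vectors are (nearly) identical the likelihood is unbounded in
#' `alpha` (the variance identity forces `alpha` to infinity), in which case
#' `alpha` is capped at `alpha_max` and a warning is emitted.
#'
#' @param theta Matrix of probability vectors (rows), or a style table (see
#'   [style_tbl]), in which case its probability columns are used.
#' @param weights Optional non-negative per-row weights (default equal).
#' @param floor Probability floor applied before taking logs (default 1e-6).
#' @param alpha_min,alpha_max Search bounds for the concentration.
#' @return An object of class `dirichlet_fit`: a list with `alpha`, `mu`,
#'   `boundary` (`NULL`, "lower" or "upper"), `loglik` and `n`. `tidy()`
#'   returns the per-component means; `glance()` the scalar summaries.
#' @examples
#' th <- rdirichlet(500, alpha = 30, mu = c(0.5, 0.3, 0.2))
#' fit <- estimate_dirichlet(th)
#' glance(fit)
#' @export
estimate_dirichlet <- function(theta, weights = NULL, floor = 1e-6,
                               alpha_min = 1e-2, alpha_max = 1e6) {
  if (is.data.frame(theta)) theta <- style_theta(theta)
  if (!is.matrix(theta)) abort("`theta` must be a matrix or style table")
  n <- nrow(theta)
  if (n < 2) abort("need at least 2 probability vectors")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) abort("`weights` length must match rows of `theta`")
  if (any(weights < 0)) abort("`weights` must be non-negative")
  if (sum(weights) <= 0) abort("total weight must be positive")

  theta_f <- floor_renormalize(theta, floor = floor)
  w <- weights / sum(weights)
  mu <- drop(crossprod(theta_f, w))
  mu <- mu / sum(mu)
  est <- estimate_dirichlet_alpha(theta_f, weights, mu,
                                  alpha_min = alpha_min, alpha_max = alpha_max)
  if (identical(est$boundary, "upper"))
    warn("alpha hit the upper search bound (vectors nearly identical); value capped")
  structure(
    list(alpha = est$alpha, mu = mu, boundary = est$boundary,
         loglik = est$loglik, n = n, floor = floor),
    class = "dirichlet_fit"
  )
}

#' @export
print.dirichlet_fit <- function(x, ...) {
  cat(sprintf("Dirichlet fit: D = %d, alpha = %.4g%s, n = %d\n",
              length(x$mu), x$alpha,
              if (!is.null(x$boundary)) paste0(" (", x$boundary, " bound)") else "",
              x$n))
  invisible(x)
}

#' @export
tidy.dirichlet_fit <- function(x, ...) {
  tibble(component = names(x$mu) %||% as.character(seq_along(x$mu)),
         mu = unname(x$mu),
         variance = unname(x$mu * (1 - x$mu) / (x$alpha + 1)))
}

#' @export
glance.dirichlet_fit <- function(x, ...) {
  tibble(alpha = x$alpha, D = length(x$mu), n = x$n,
         logLik = x$loglik, boundary = x$boundary %||% "none")
}
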