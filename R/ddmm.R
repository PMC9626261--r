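#' Dirichlet mixture parameters at one time point
#'
#' A `dmm_params` object holds one year's Dirichlet mixture: mixture
#' probabilities `pi` (length K, summing to one), concentrations `alpha`
#' (positive, length K) and mean distributions `mu` (K x D matrix with unit
#' row sums). A `dmm_trajectory` is a year-indexed list of `dmm_params`
#' sharing K and D; `tidy()` turns either into a long tibble.
#'
#' @param t Integer year.
#' @param pi Mixture probabilities, length K.
#' @param alpha Concentrations, length K.
#' @param mu K x D matrix of mean distributions.
#' @return `dmm_params()` returns a validated `dmm_params` object.
#' @export
dmm_params <- function(t, pi, alpha, mu) {
  if (!is.matrix(mu)) mu <- matrix(mu, nrow = 1)
  K <- length(pi)
  stopifnot(length(alpha) == K, nrow(mu) == K)
  check_prob_vector(pi, "pi")
  if (any(alpha <= 0)) abort("all concentrations must be positive")
  for (k in seq_len(K)) check_prob_vector(mu[k, ], sprintf("mu[%d,]", k))
  structure(list(t = as.integer(t), K = K, pi = pi, alpha = alpha, mu = mu),
            class = "dmm_params")
}

#' @export
print.dmm_params <- function(x, ...) {
  cat(sprintf("DMM parameters at t = %d: K = %d, D = %d\n", x$t, x$K, ncol(x$mu)))
  cat("pi:   ", paste(sprintf("%.3f", x$pi), collapse = " "), "\n")
  cat("alpha:", paste(sprintf("%.3g", x$alpha), collapse = " "), "\n")
  invisible(x)
}

#' @export
tidy.dmm_params <- function(x, ...) {
  tibble(t = x$t, cluster = seq_len(x$K), pi = x$pi, alpha = x$alpha,
         mu = lapply(seq_len(x$K), function(k) x$mu[k, ]))
}

new_dmm_trajectory <- function(params_list) {
  yrs <- vapply(params_list, function(p) p$t, integer(1))
  params_list <- params_list[order(yrs)]
  names(params_list) <- sort(yrs)
  structure(params_list, class = "dmm_trajectory")
}

#' @export
print.dmm_trajectory <- function(x, ...) {
  yrs <- as.integer(names(x))
  cat(sprintf("DMM trajectory: %d years (%d..%d), K = %d, D = %d\n",
              length(x), min(yrs), max(yrs), x[[1]]$K, ncol(x[[1]]$mu)))
  invisible(x)
}

#' @export
tidy.dmm_trajectory <- function(x, ...) {
  dplyr::bind_rows(lapply(unclass(x), tidy))
}

# extract the params for one year, error if absent
trajectory_at <- function(traj, year) {
  p <- traj[[as.character(year)]]
  if (is.null(p)) abort(sprintf("trajectory has no parameters for year %d", year))
  p
}

#' Mixture log-density of style vectors under DMM parameters
#'
#' Scores probability vectors under the Dirichlet mixture
#' `sum_k pi_k Dir(theta; alpha_k, mu_k)`, with optional concentration
#' inflation used when smoothed parameters are compared against single-year
#' data (a single year is more concentrated than the smoothed distribution).
#'
#' @param theta Probability vectors (matrix rows) or a style table.
#' @param params A [dmm_params()] object.
#' @param conc_factor Multiplier applied to every `alpha_k` before scoring
#'   (default 1).
#' @param floor Probability floor applied to `theta` and `mu` before logs.
#' @return Numeric vector of per-vector mixture log-densities (nats).
#' @export
dmm_log_density <- function(theta, params, conc_factor = 1, floor = 1e-6) {
  if (is.data.frame(theta)) theta <- style_theta(theta)
  if (!is.matrix(theta)) theta <- matrix(theta, nrow = 1)
  theta <- floor_renormalize(theta, floor = floor)
  K <- params$K
  comp <- matrix(0, nrow(theta), K)
  for (k in seq_len(K)) {
    mu_k <- floor_renormalize(params$mu[k, ], floor = floor)
    comp[, k] <- log(params$pi[k] + 1e-300) +
      dirichlet_log_density(theta, params$alpha[k] * conc_factor, mu_k)
  }
  row_logsumexp(comp)
}

#' Per-year slice statistics of labelled style vectors
#'
#' Splits cluster-assigned style vectors into yearly slices and computes the
#' simple (single-slice) estimates: relative cluster frequencies
#' `pi_S(k, s)`, unweighted mean distributions `mu_S(k, s)`, and the member
#' vectors of every populated (cluster, year) cell, retained so concentration
#' likelihoods can be evaluated later. Empty cells are flagged missing, not
#' zero.
#'
#' @param styles A style table (see [style_tbl]).
#' @param labels Integer cluster labels in `1..K`, one per row of `styles`.
#' @param K Number of clusters (default `max(labels)`).
#' @return An object of class `slice_estimates` with elements `years`,
#'   `K`, `D`, `n` (years x K membership counts), `pi_S` (years x K),
#'   `mu_S` (list over clusters of years x D matrices, `NA` rows when
#'   missing) and `members` (per cluster, per year, the member theta matrix).
#'   `tidy()` returns a long tibble of `pi_S` with sample sizes.
#' @export
slice_statistics <- function(styles, labels, K = max(labels)) {
  n <- nrow(styles)
  if (length(labels) != n) abort("`labels` length must match `styles` rows")
  if (any(labels < 1 | labels > K | labels != round(labels)))
    abort("`labels` must be integers in 1..K")
  years <- sort(unique(styles$year))
  theta <- style_theta(styles)
  D <- ncol(theta)
  Y <- length(years)
  n_ks <- matrix(0L, Y, K, dimnames = list(years, NULL))
  pi_S <- matrix(NA_real_, Y, K, dimnames = list(years, NULL))
  mu_S <- lapply(seq_len(K), function(k) matrix(NA_real_, Y, D, dimnames = list(years, colnames(theta))))
  members <- lapply(seq_len(K), function(k) setNames(vector("list", Y), years))
  for (si in seq_len(Y)) {
    in_year <- styles$year == years[si]
    tot <- sum(in_year)
    for (k in seq_len(K)) {
      sel <- in_year & labels == k
      n_ks[si, k] <- sum(sel)
      pi_S[si, k] <- sum(sel) / tot
      if (any(sel)) {
        th_k <- theta[sel, , drop = FALSE]
        mu_S[[k]][si, ] <- colMeans(th_k)
        members[[k]][[si]] <- th_k
      }
    }
  }
  structure(list(years = years, K = K, D = D, n = n_ks, pi_S = pi_S,
                 mu_S = mu_S, members = members,
                 feature_names = colnames(theta)),
            class = "slice_estimates")
}

#' @export
print.slice_estimates <- function(x, ...) {
  cat(sprintf("Slice estimates: %d years (%d..%d), K = %d, D = %d, %d songs\n",
              length(x$years), min(x$years), max(x$years), x$K, x$D, sum(x$n)))
  invisible(x)
}

#' @export
tidy.slice_estimates <- function(x, ...) {
  tidyr::expand_grid(year = x$years, cluster = seq_len(x$K)) %>%
    mutate(n = as.vector(t(x$n)), pi_S = as.vector(t(x$pi_S)))
}

#' Exponential-decay weighted-average DMM estimate at one year
#'
#' Estimates the Dirichlet mixture parameters at year `t` by pooling all
#' yearly slice estimates up to `t` with exponential decay weights
#' `e^{(s - t)/tau}`: the mixture probabilities and mean distributions are
#' decay-weighted averages of the per-slice values (normalized by
#' `C(t) = sum of weights`), and each concentration maximizes the
#' decay-weighted sum of its member songs' Dirichlet log-densities with the
#' mean held at its weighted-average value. Missing (cluster, year) cells
#' contribute no weight. The sum over past years is truncated at the first
#' data year.
#'
#' @param slices A [slice_statistics()] object.
#' @param t Target year (must have at least one populated slice at or
#'   before it).
#' @param tau Positive time constant of the exponential decay, in years.
#' @param first_year Truncation year for the backward sum (default: first
#'   year present in `slices`).
#' @param floor Probability floor applied to member vectors before logs.
#' @param alpha_min,alpha_max Concentration search bounds.
#' @return A [dmm_params()] object for year `t`.
#' @export
weighted_average_estimate <- function(slices, t, tau,
                                      first_year = min(slices$years),
                                      floor = 1e-6,
                                      alpha_min = 1e-2, alpha_max = 1e6) {
  if (tau <= 0) abort("`tau` must be positive")
  use <- slices$years >= first_year & slices$years <= t
  if (!any(use)) abort(sprintf("no populated slices at or before year %d", t))
  yrs <- slices$years[use]
  w <- exp((yrs - t) / tau)
  K <- slices$K

  pi_rows <- slices$pi_S[use, , drop = FALSE]
  pi_hat <- drop(crossprod(pi_rows, w)) / sum(w)
  pi_hat <- pmax(pi_hat, 0)
  pi_hat <- pi_hat / sum(pi_hat)

  mu_hat <- matrix(0, K, slices$D, dimnames = list(NULL, slices$feature_names))
  alpha_hat <- numeric(K)
  for (k in seq_len(K)) {
    mk <- slices$mu_S[[k]][use, , drop = FALSE]
    have <- !is.na(mk[, 1])
    if (!any(have)) {
      # cluster never observed up to t: uninformative placeholder
      mu_hat[k, ] <- rep(1 / slices$D, slices$D)
      alpha_hat[k] <- 1
      warn(sprintf("cluster %d has no members up to year %d; placeholder parameters used", k, t))
      next
    }
    wk <- w[have]
    mu_k <- drop(crossprod(mk[have, , drop = FALSE], wk)) / sum(wk)
    mu_k <- mu_k / sum(mu_k)
    mu_hat[k, ] <- mu_k
    # decay-weighted member-song likelihood for alpha (slice weight applied per song)
    mem <- slices$members[[k]][use][have]
    th <- do.call(rbind, mem)
    w_song <- rep(wk, vapply(mem, nrow, integer(1)))
    th <- floor_renormalize(th, floor = floor)
    mu_f <- floor_renormalize(mu_k, floor = floor)
    if (nrow(th) < 2) {
      alpha_hat[k] <- alpha_max
      warn(sprintf("cluster %d has a single member up to year %d; alpha capped", k, t))
    } else {
      est <- estimate_dirichlet_alpha(th, w_song, mu_f,
                                      alpha_min = alpha_min, alpha_max = alpha_max)
      if (!is.null(est$boundary))
        warn(sprintf("alpha for cluster %d hit the %s search bound at year %d",
                     k, est$boundary, t))
      alpha_hat[k] <- est$alpha
    }
  }
  dmm_params(t, pi_hat, alpha_hat, mu_hat)
}

#' Time-window DMM estimate at one year
#'
#' Pools the songs of years `(t - width + 1) .. t` with equal weight and
#' computes the same statistics as the simple per-slice method on the pooled
#' sample. Width 1 reproduces the single-year estimate; a width spanning all
#' years gives the global pooled estimate. Used as the comparison method for
#' the exponential-decay estimator.
#'
#' @inheritParams weighted_average_estimate
#' @param width Window width in years (`>= 1`).
#' @return A [dmm_params()] object for year `t`.
#' @export
window_estimate <- function(slices, t, width, floor = 1e-6,
                            alpha_min = 1e-2, alpha_max = 1e6) {
  if (width < 1) abort("`width` must be at least 1")
  use <- slices$years > t - width & slices$years <= t
  if (!any(use)) abort(sprintf("no populated slices in window ending at %d", t))
  K <- slices$K
  n_k <- colSums(slices$n[use, , drop = FALSE])
  if (sum(n_k) == 0) abort("empty window")
  pi_hat <- n_k / sum(n_k)
  mu_hat <- matrix(0, K, slices$D, dimnames = list(NULL, slices$feature_names))
  alpha_hat <- numeric(K)
  for (k in seq_len(K)) {
    mem <- slices$members[[k]][use]
    mem <- mem[!vapply(mem, is.null, logical(1))]
    if (length(mem) == 0) {
      mu_hat[k, ] <- rep(1 / slices$D, slices$D)
      alpha_hat[k] <- 1
      warn(sprintf("cluster %d empty in window ending at %d; placeholder parameters used", k, t))
      next
    }
    th <- do.call(rbind, mem)
    mu_k <- colMeans(th)
    mu_hat[k, ] <- mu_k / sum(mu_k)
    th_f <- floor_renormalize(th, floor = floor)
    if (nrow(th_f) < 2) {
      alpha_hat[k] <- alpha_max
    } else {
      est <- estimate_dirichlet_alpha(th_f, rep(1, nrow(th_f)),
                                      floor_renormalize(mu_hat[k, ], floor = floor),
                                      alpha_min = alpha_min, alpha_max = alpha_max)
      alpha_hat[k] <- est$alpha
    }
  }
  dmm_params(t, pi_hat, alpha_hat, mu_hat)
}

#' Estimate a DMM parameter trajectory over a range of years
#'
#' Applies [weighted_average_estimate()] (or [window_estimate()]) at each
#' requested year, producing the year-indexed parameter trajectory of the
#' dynamic Dirichlet mixture.
#'
#' @param styles A style table.
#' @param labels Cluster labels for every row of `styles`.
#' @param years Integer years at which to estimate (default: all data years).
#' @param tau Time constant for the weighted-average method.
#' @param method `"weighted"` (exponential decay; default) or `"window"`.
#' @param width Window width when `method = "window"`.
#' @param K Number of clusters (default `max(labels)`).
#' @param ... Passed on to the per-year estimator.
#' @return A `dmm_trajectory` object.
#' @examples
#' sim <- sample_ddmm_dataset(example_trajectory_spec(years = 1990:1999))
#' traj <- estimate_ddmm(sim$styles, sim$labels, tau = 5)
#' tidy(traj)
#' @export
estimate_ddmm <- function(styles, labels, years = NULL, tau = 10,
                          method = c("weighted", "window"), width = 1,
                          K = max(labels), ...) {
  method <- match.arg(method)
  slices <- slice_statistics(styles, labels, K = K)
  if (is.null(years)) years <- slices$years
  est <- lapply(years, function(t) {
    if (method == "weighted") weighted_average_estimate(slices, t, tau = tau, ...)
    else window_estimate(slices, t, width = width, ...)
  })
  new_dmm_trajectory(est)
}

#' Select the decay time constant by next-year likelihood
#'
#' For each candidate time constant `tau` and each referential year `t0`,
#' estimates the mixture at `t0` from data up to `t0` and evaluates the mean
#' per-song mixture log-density of the styles created in year `t0 + 1`
#' (assuming the style distribution changes little in one year). The curve is
#' averaged over referential years; the selected `tau` maximizes it.
#'
#' @param styles A style table covering the referential years and their
#'   following years.
#' @param labels Cluster labels for every row of `styles`.
#' @param tau_grid Candidate time constants (default `1:30`).
#' @param t0_range Referential years to average over (default: all years
#'   with data in the following year, except the last).
#' @param K Number of clusters.
#' @param floor Probability floor for density evaluation.
#' @return A tibble with columns `tau` and `mean_loglik`, with attribute
#'   `best` (the maximizing tau). The attribute is also returned by
#'   `attr(x, "best")`.
#' @export
select_time_constant <- function(styles, labels, tau_grid = 1:30,
                                 t0_range = NULL, K = max(labels),
                                 floor = 1e-6) {
  if (length(tau_grid) == 0) abort("`tau_grid` must be non-empty")
  slices <- slice_statistics(styles, labels, K = K)
  yrs <- slices$years
  if (is.null(t0_range)) t0_range <- yrs[yrs < max(yrs)]
  t0_range <- t0_range[(t0_range + 1) %in% yrs]
  if (length(t0_range) == 0) abort("no referential year has data in the following year")
  theta_by_year <- split(seq_len(nrow(styles)), styles$year)
  theta <- style_theta(styles)
  scores <- matrix(NA_real_, length(tau_grid), length(t0_range))
  for (ti in seq_along(tau_grid)) {
    for (j in seq_along(t0_range)) {
      t0 <- t0_range[j]
      params <- suppressWarnings(
        weighted_average_estimate(slices, t0, tau = tau_grid[ti], floor = floor))
      test <- theta[theta_by_year[[as.character(t0 + 1)]], , drop = FALSE]
      scores[ti, j] <- mean(dmm_log_density(test, params, floor = floor))
    }
  }
  out <- tibble(tau = tau_grid, mean_loglik = rowMeans(scores))
  attr(out, "best") <- tau_grid[which.max(out$mean_loglik)]
  out
}
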