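#' Static forecast of DMM parameters
#'
#' Baseline that freezes the referential year's parameters: the forecast for
#' every future year equals the input.
#'
#' @param params A [dmm_params()] object for the referential year.
#' @param horizon Number of future years.
#' @return A `dmm_trajectory` covering `params$t + 1 .. params$t + horizon`.
#' @export
static_forecast <- function(params, horizon) {
  if (horizon < 1) abort("`horizon` must be at least 1")
  new_dmm_trajectory(lapply(seq_len(horizon), function(h)
    dmm_params(params$t + h, params$pi, params$alpha, params$mu)))
}

# fit per-series state-space models for every parameter family of a trajectory
fit_trajectory_ssm <- function(trajectory, order = 1, rare_threshold = 0.01,
                               floor = 1e-6) {
  yrs <- as.integer(names(trajectory))
  K <- trajectory[[1]]$K
  D <- ncol(trajectory[[1]]$mu)
  pi_mat <- t(vapply(trajectory, function(p) p$pi, numeric(K)))
  al_mat <- t(vapply(trajectory, function(p) p$alpha, numeric(K)))
  if (K == 1) { pi_mat <- matrix(pi_mat, ncol = 1); al_mat <- matrix(al_mat, ncol = 1) }
  mu_arr <- array(NA_real_, c(length(yrs), K, D))
  for (i in seq_along(yrs)) mu_arr[i, , ] <- trajectory[[i]]$mu

  pi_fits <- lapply(seq_len(K), function(k)
    fit_trend_ssm(log(pmax(pi_mat[, k], floor)), order = order))
  alpha_fits <- lapply(seq_len(K), function(k)
    fit_trend_ssm(log(al_mat[, k]), order = order))
  mu_fits <- vector("list", K)
  mu_dynamic <- matrix(FALSE, K, D)
  for (k in seq_len(K)) {
    past_mean <- colMeans(matrix(mu_arr[, k, ], ncol = D))
    dyn <- past_mean > rare_threshold
    mu_dynamic[k, ] <- dyn
    mu_fits[[k]] <- lapply(which(dyn), function(i)
      fit_trend_ssm(log(pmax(mu_arr[, k, i], floor)), order = order))
    names(mu_fits[[k]]) <- as.character(which(dyn))
  }
  list(years = yrs, K = K, D = D, pi_fits = pi_fits, alpha_fits = alpha_fits,
       mu_fits = mu_fits, mu_dynamic = mu_dynamic,
       last = trajectory[[length(trajectory)]])
}

#' Forecast DDMM parameters with the state-space evolutionary model
#'
#' Fits a latent-trend state-space model ([fit_trend_ssm()]) to each
#' log-transformed parameter series of an estimated trajectory -- `ln pi_k`,
#' `ln alpha_k`, and `ln mu_ki` for the non-rare components -- and
#' extrapolates each with its family's fitness reduction factor. Forecast
#' mixture probabilities are renormalized across clusters, and mean
#' distributions are renormalized across components; components whose past
#' average probability is at or below `rare_threshold` are carried forward
#' statically (rare components are dominated by sampling noise). This
#' decoupled treatment is the slow-evolution approximation of the coupled
#' replicator dynamics: with velocities `v_k = ln(w_k / wbar)` the
#' normalized decoupled update reproduces the replicator update.
#'
#' @param trajectory A `dmm_trajectory` of estimates up to the referential
#'   year (at least 4 years).
#' @param horizon Number of years to forecast.
#' @param rho Named list or vector with reduction factors `pi`, `alpha`,
#'   `mu`, each in `[0.01, 1]` (default all 1).
#' @param order State-space order (default 1).
#' @param rare_threshold Past-average probability below which a mean
#'   component stays static (default 0.01).
#' @param floor Probability floor before logs (default 1e-6).
#' @return An object of class `ddmm_forecast`: a `dmm_trajectory` of
#'   forecast parameters with the fitted state-space models attached as
#'   attributes (`fits`).
#' @examples
#' sim <- sample_ddmm_dataset(example_trajectory_spec(years = 1990:2009))
#' traj <- estimate_ddmm(sim$styles, sim$labels, tau = 5)
#' fc <- forecast_ddmm(traj, horizon = 5)
#' tidy(fc)
#' @export
forecast_ddmm <- function(trajectory, horizon,
                          rho = c(pi = 1, alpha = 1, mu = 1),
                          order = 1, rare_threshold = 0.01, floor = 1e-6) {
  if (length(trajectory) < 4) abort("trajectory must cover at least 4 years")
  if (horizon < 1) abort("`horizon` must be at least 1")
  rho <- unlist(rho)
  for (fam in c("pi", "alpha", "mu")) {
    if (is.na(rho[fam])) abort(sprintf("`rho` must name a '%s' entry", fam))
    if (rho[fam] < 0.01 || rho[fam] > 1)
      abort(sprintf("rho['%s'] must lie in [0.01, 1]", fam))
  }
  fits <- fit_trajectory_ssm(trajectory, order = order,
                             rare_threshold = rare_threshold, floor = floor)
  K <- fits$K; D <- fits$D
  t0 <- fits$last$t

  ln_pi <- vapply(fits$pi_fits, forecast_trend, numeric(horizon),
                  horizon = horizon, rho = rho[["pi"]])
  ln_al <- vapply(fits$alpha_fits, forecast_trend, numeric(horizon),
                  horizon = horizon, rho = rho[["alpha"]])
  if (horizon == 1) { ln_pi <- matrix(ln_pi, 1); ln_al <- matrix(ln_al, 1) }

  mu_fc <- array(rep(fits$last$mu, each = horizon), c(horizon, K, D))
  for (k in seq_len(K)) {
    for (i in names(fits$mu_fits[[k]])) {
      mu_fc[, k, as.integer(i)] <-
        exp(forecast_trend(fits$mu_fits[[k]][[i]], horizon = horizon,
                           rho = rho[["mu"]]))
    }
  }

  out <- lapply(seq_len(horizon), function(h) {
    pi_h <- exp(ln_pi[h, ] - logsumexp(ln_pi[h, ]))
    mu_h <- mu_fc[h, , , drop = FALSE][1, , ]
    if (K == 1) mu_h <- matrix(mu_h, nrow = 1)
    mu_h <- mu_h / rowSums(mu_h)
    colnames(mu_h) <- colnames(fits$last$mu)
    dmm_params(t0 + h, pi_h, exp(ln_al[h, ]), mu_h)
  })
  res <- new_dmm_trajectory(out)
  attr(res, "fits") <- fits
  attr(res, "rho") <- rho
  class(res) <- c("ddmm_forecast", class(res))
  res
}

#' @export
print.ddmm_forecast <- function(x, ...) {
  yrs <- as.integer(names(x))
  cat(sprintf("SSEM forecast: %d..%d, K = %d, rho = (pi %.2g, alpha %.2g, mu %.2g)\n",
              min(yrs), max(yrs), x[[1]]$K,
              attr(x, "rho")[["pi"]], attr(x, "rho")[["alpha"]], attr(x, "rho")[["mu"]]))
  invisible(x)
}

#' Backtest-optimized fitness reduction factors
#'
#' Selects, independently for each parameter family, the reduction factor on
#' a fixed grid within `[0.01, 1]` that minimizes the backtest error on
#' held-out terminal years of the trajectory: SKL divergence for mixture
#' probabilities and mean distributions, log-squared error for
#' concentrations. The trajectory is truncated `holdout` years before its
#' end, forecast over the held-out span at every candidate, and scored
#' against the estimates for those years.
#'
#' @param trajectory A `dmm_trajectory` (at least `4 + holdout` years).
#' @param rho_grid Candidate reduction factors (all in `[0.01, 1]`).
#' @param holdout Number of terminal years held out (`>= 3`).
#' @param order,rare_threshold,floor Passed to [forecast_ddmm()].
#' @return A tibble with columns `family`, `rho` (selected value) plus the
#'   full error grid as attribute `curve` (tibble `family`, `rho`, `error`).
#' @export
optimize_reduction_factor <- function(trajectory,
                                      rho_grid = c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1),
                                      holdout = 3, order = 1,
                                      rare_threshold = 0.01, floor = 1e-6) {
  if (any(rho_grid < 0.01 | rho_grid > 1)) abort("`rho_grid` must lie in [0.01, 1]")
  if (holdout < 3) abort("`holdout` must be at least 3")
  n <- length(trajectory)
  if (n < 4 + holdout) abort("trajectory too short for the requested holdout")
  train <- new_dmm_trajectory(unclass(trajectory)[seq_len(n - holdout)])
  test <- new_dmm_trajectory(unclass(trajectory)[seq(n - holdout + 1, n)])
  rows <- list()
  for (r in rho_grid) {
    fc <- forecast_ddmm(train, horizon = holdout,
                        rho = c(pi = r, alpha = r, mu = r),
                        order = order, rare_threshold = rare_threshold,
                        floor = floor)
    err <- prediction_errors(fc, test, floor = floor) %>%
      group_by(.data$family) %>%
      summarise(error = mean(.data$error), .groups = "drop") %>%
      mutate(rho = r)
    rows[[length(rows) + 1L]] <- err
  }
  curve <- dplyr::bind_rows(rows)
  best <- curve %>%
    group_by(.data$family) %>%
    filter(.data$error == min(.data$error)) %>%
    dplyr::slice(1) %>%
    ungroup() %>%
    select("family", "rho")
  attr(best, "curve") <- curve
  best
}
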