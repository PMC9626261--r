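#' Floor and renormalize probability vectors
#'
#' Replaces each component by `max(theta_i, floor)` and renormalizes to unit
#' sum, so that logarithms and Dirichlet densities are always defined. The
#' operation is idempotent for any floor below `1/D` and leaves strictly
#' interior vectors essentially unchanged.
#'
#' @param theta A probability vector or a matrix of probability vectors
#'   (rows).
#' @param floor Positive floor (default 1e-6).
#' @return Object of the same shape with strictly positive entries and unit
#'   (row) sums.
#' @examples
#' floor_renormalize(c(1, 0))
#' @export
floor_renormalize <- function(theta, floor = 1e-6) {
  if (!is.matrix(theta)) {
    return(drop(floor_renormalize(matrix(theta, nrow = 1), floor = floor)))
  }
  if (any(rowSums(theta) <= 0)) abort("all-zero probability vector")
  if (floor <= 0) return(theta / rowSums(theta))
  low <- theta < floor
  # raise deficient components to the floor and absorb the mass from the
  # others proportionally, so re-applying the operation is a no-op
  th <- theta
  th[low] <- floor
  n_low <- rowSums(low)
  high_mass <- rowSums(theta * !low)
  scale <- (1 - floor * n_low) / high_mass
  th[!low] <- (theta * scale)[!low]
  th / rowSums(th)
}

kl_terms <- function(p, q) {
  # 0 * log(0/q) treated as 0; p > 0 with q = 0 gives +Inf (callers floor first)
  ifelse(p > 0, p * (log(p) - log(q)), 0)
}

#' Jensen-Shannon divergence
#'
#' `JS(p, q) = KL(p || m)/2 + KL(q || m)/2` with `m = (p + q)/2`, in nats.
#' Symmetric, bounded by `ln 2`, and defined for vectors with zeros
#' (`0 log 0 = 0`).
#'
#' @param p,q Probability vectors of equal length.
#' @return Non-negative scalar (nats).
#' @examples
#' js_divergence(c(1, 0), c(0, 1)) # ln 2
#' @export
js_divergence <- function(p, q) {
  if (length(p) != length(q)) abort("`p` and `q` must have equal length")
  check_prob_vector(p, "p"); check_prob_vector(q, "q")
  m <- (p + q) / 2
  sum(kl_terms(p, m)) / 2 + sum(kl_terms(q, m)) / 2
}

#' Symmetric Kullback-Leibler divergence
#'
#' `SKL(p, q) = KL(p || q) + KL(q || p)` (sum convention), in nats, computed
#' after flooring both arguments so the logs are finite.
#'
#' @param p,q Probability vectors of equal length.
#' @param floor Probability floor applied to both arguments first.
#' @return Non-negative scalar (nats).
#' @examples
#' skl_divergence(c(0.8, 0.2), c(0.2, 0.8)) # 1.2 * log(4)
#' @export
skl_divergence <- function(p, q, floor = 1e-6) {
  if (length(p) != length(q)) abort("`p` and `q` must have equal length")
  check_prob_vector(p, "p"); check_prob_vector(q, "q")
  p <- floor_renormalize(p, floor)
  q <- floor_renormalize(q, floor)
  sum(p * (log(p) - log(q))) + sum(q * (log(q) - log(p)))
}

#' Log-squared error for concentration parameters
#'
#' `(ln a - ln b)^2`; scale-invariant, used to compare predicted and actual
#' Dirichlet concentrations.
#'
#' @param alpha_pred,alpha_true Positive scalars (vectorized).
#' @return Non-negative value(s).
#' @export
log_squared_error <- function(alpha_pred, alpha_true) {
  if (any(alpha_pred <= 0) || any(alpha_true <= 0))
    abort("concentrations must be positive")
  (log(alpha_pred) - log(alpha_true))^2
}

#' Per-family DMM parameter prediction errors
#'
#' Compares predicted against actual mixture parameters year by year:
#' the mixture-probability error is the SKL divergence between the two
#' K-vectors, the mean-distribution error the unweighted mean over clusters
#' of per-cluster SKL divergences, and the concentration error the
#' unweighted mean over clusters of log-squared errors. If a second
#' (baseline) prediction is supplied, each error is also reported normalized
#' by the baseline's error for the same year and family (the baseline's own
#' ratio is 1 by construction).
#'
#' @param predicted,actual `dmm_trajectory` objects with matched cluster
#'   indexing; errors are computed on the years present in both.
#' @param normalize_by Optional third trajectory (typically the static
#'   forecast) whose errors against `actual` define the normalization.
#' @param floor Probability floor for the SKL computations.
#' @return A tibble with columns `t`, `family` (`"pi"`, `"alpha"`, `"mu"`),
#'   `error`, and `ratio` when `normalize_by` is given.
#' @export
prediction_errors <- function(predicted, actual, normalize_by = NULL,
                              floor = 1e-6) {
  yrs <- intersect(names(predicted), names(actual))
  if (length(yrs) == 0) abort("`predicted` and `actual` share no years")
  one <- function(pred, act) {
    if (pred$K != act$K) abort("cluster count mismatch between predictions and actuals")
    tibble(
      t = act$t,
      family = c("pi", "alpha", "mu"),
      error = c(
        skl_divergence(pred$pi, act$pi, floor = floor),
        mean(log_squared_error(pred$alpha, act$alpha)),
        mean(vapply(seq_len(act$K), function(k)
          skl_divergence(pred$mu[k, ], act$mu[k, ], floor = floor), numeric(1)))
      )
    )
  }
  out <- dplyr::bind_rows(lapply(yrs, function(y) one(predicted[[y]], actual[[y]])))
  if (!is.null(normalize_by)) {
    base <- dplyr::bind_rows(lapply(yrs, function(y) one(normalize_by[[y]], actual[[y]]))) %>%
      dplyr::rename(base_error = "error")
    out <- out %>%
      left_join(base, by = c("t", "family")) %>%
      mutate(ratio = .data$error / .data$base_error) %>%
      select(-"base_error")
  }
  out
}

#' Predictive log-likelihood gain over a baseline model
#'
#' Backtests forecast mixtures against held-out style vectors: each test
#' song of year `t_p` is scored under the mixture predicted for year
#' `t_p + dp` (the look-ahead `dp` compensates for the lag introduced by
#' exponential-decay smoothing) with every concentration multiplied by
#' `conc_factor` (a single year is more concentrated than the smoothed
#' distribution). The gain is the mean per-song log-density minus that of a
#' baseline scored the same way, typically the static single-cluster (K = 1)
#' model.
#'
#' @param predicted A `dmm_trajectory` of forecast parameters (must cover
#'   `t_p + dp` for every test year `t_p`).
#' @param test_styles Style table of held-out songs.
#' @param baseline A `dmm_trajectory` for the baseline model, same coverage.
#' @param dp Integer look-ahead offset (default 0).
#' @param conc_factor Concentration multiplier (default 1).
#' @param floor Probability floor for density evaluation.
#' @return A tibble with one row per test year: `t`, `n`, `model_ll`,
#'   `baseline_ll` (mean per-song log-densities) and `gain`.
#' @export
loglik_gain <- function(predicted, test_styles, baseline, dp = 0,
                        conc_factor = 1, floor = 1e-6) {
  yrs <- sort(unique(test_styles$year))
  theta <- style_theta(test_styles)
  rows <- lapply(yrs, function(tp) {
    pars <- trajectory_at(predicted, tp + dp)
    base <- trajectory_at(baseline, tp + dp)
    th <- theta[test_styles$year == tp, , drop = FALSE]
    ll_m <- mean(dmm_log_density(th, pars, conc_factor = conc_factor, floor = floor))
    ll_b <- mean(dmm_log_density(th, base, conc_factor = conc_factor, floor = floor))
    tibble(t = tp, n = nrow(th), model_ll = ll_m, baseline_ll = ll_b,
           gain = ll_m - ll_b)
  })
  dplyr::bind_rows(rows)
}
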