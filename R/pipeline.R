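#' Run an end-to-end style-evolution experiment
#'
#' Orchestrates the full pipeline on a style table: cluster the styles,
#' estimate the yearly Dirichlet-mixture parameter trajectory up to a
#' referential year `t0` with exponential-decay smoothing, forecast the
#' parameters over a horizon with the state-space evolutionary model,
#' compare against the static baseline on the actually realized parameter
#' estimates, and backtest mixture log-likelihood gains against the
#' single-cluster (K = 1) static baseline on the held-out songs.
#'
#' Clustering scope `"past_only"` (the default) fits the mixture only on
#' songs up to `t0`, so no future information leaks into the forecasts;
#' `"global"` mimics a single all-data clustering. Every random stage
#' derives its own seed deterministically from `seed`.
#'
#' @param styles A style table covering years beyond `t0`.
#' @param K Number of clusters.
#' @param t0 Referential year: estimation uses data up to `t0`, evaluation
#'   the years after it.
#' @param horizon Forecast horizon in years.
#' @param tau Decay time constant for the weighted-average estimator.
#' @param rho Reduction factors as in [forecast_ddmm()], or `"optimize"` to
#'   select them per family by backtesting within the training span.
#' @param dp Look-ahead offset for the likelihood backtest.
#' @param conc_factor Concentration multiplier for the likelihood backtest.
#' @param clustering_scope `"past_only"` or `"global"`.
#' @param n_restarts EM restarts.
#' @param seed Global seed.
#' @param out_dir Optional directory; when given, all artifacts (style
#'   table, mixture model, trajectories, forecasts, error and gain tables,
#'   manifest) are written there as plain text.
#' @return An object of class `style_experiment`: list with `mixture`,
#'   `labels`, `trajectory`, `forecast`, `static`, `actual`, `errors`
#'   (normalized by the static model), `gains` (vs the K = 1 static
#'   baseline), `rho`, and `manifest`.
#' @examples
#' sim <- sample_ddmm_dataset(example_trajectory_spec(years = 1985:2009))
#' ex <- run_style_experiment(sim$styles, K = 3, t0 = 1999, horizon = 5,
#'                            tau = 5, n_restarts = 2, seed = 1)
#' ex$errors
#' @export
run_style_experiment <- function(styles, K, t0, horizon, tau = 10,
                                 rho = c(pi = 1, alpha = 1, mu = 1),
                                 dp = 0, conc_factor = 1,
                                 clustering_scope = c("past_only", "global"),
                                 n_restarts = 5, seed = 1, out_dir = NULL) {
  clustering_scope <- match.arg(clustering_scope)
  if (!any(styles$year <= t0)) abort("no styles at or before `t0`")
  if (!any(styles$year > t0)) abort("no styles after `t0` to evaluate against")

  fit_data <- if (clustering_scope == "past_only")
    styles[styles$year <= t0, ] else styles
  mixture <- fit_style_clusters(fit_data, K = K, n_restarts = n_restarts,
                                seed = derive_seed(seed, "cluster"))
  labels <- assign_clusters(mixture, styles)

  first_year <- min(styles$year)
  past <- styles$year <= t0
  traj <- estimate_ddmm(styles[past, ], labels[past],
                        years = first_year:t0, tau = tau, K = K)

  if (identical(rho, "optimize")) {
    sel <- optimize_reduction_factor(traj)
    rho <- setNames(sel$rho, sel$family)[c("pi", "alpha", "mu")]
  }
  fc <- forecast_ddmm(traj, horizon = horizon + dp, rho = rho)
  static <- static_forecast(traj[[as.character(t0)]], horizon + dp)

  eval_years <- (t0 + 1):min(t0 + horizon, max(styles$year))
  actual <- estimate_ddmm(styles, labels, years = eval_years, tau = tau, K = K)
  errors <- prediction_errors(fc, actual, normalize_by = static)

  # K = 1 static baseline for the likelihood backtest
  traj1 <- estimate_ddmm(styles[past, ], rep(1L, sum(past)),
                         years = t0, tau = tau, K = 1)
  base1 <- static_forecast(traj1[[as.character(t0)]], horizon + dp)
  test <- styles[styles$year %in% eval_years, ]
  gains <- loglik_gain(fc, test, base1, dp = dp, conc_factor = conc_factor)

  manifest <- list(K = K, t0 = t0, horizon = horizon, tau = tau,
                   rho = as.list(rho), dp = dp, conc_factor = conc_factor,
                   clustering_scope = clustering_scope,
                   n_restarts = n_restarts, seed = seed,
                   seeds = list(cluster = derive_seed(seed, "cluster")),
                   n_songs = nrow(styles),
                   feature_kind = style_feature_kind(styles))

  out <- structure(
    list(mixture = mixture, labels = labels, trajectory = traj,
         forecast = fc, static = static, actual = actual,
         errors = errors, gains = gains, rho = rho, manifest = manifest),
    class = "style_experiment")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_style_table(styles, file.path(out_dir, "styles.csv"))
    write_style_mixture(mixture, file.path(out_dir, "mixture.json"))
    write_dmm_trajectory(traj, file.path(out_dir, "trajectory.json"))
    write_dmm_trajectory(fc, file.path(out_dir, "forecast.json"))
    write_dmm_trajectory(actual, file.path(out_dir, "actual.json"))
    readr::write_csv(errors, file.path(out_dir, "errors.csv"))
    readr::write_csv(gains, file.path(out_dir, "gains.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = I(17))
  }
  out
}

#' @export
print.style_experiment <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("Style-evolution experiment: K = %d, t0 = %d, horizon = %d, tau = %g\n",
              m$K, m$t0, m$horizon, m$tau))
  mean_ratio <- x$errors %>%
    group_by(.data$family) %>%
    summarise(ratio = mean(.data$ratio), .groups = "drop")
  cat("mean error ratios vs static:\n")
  for (i in seq_len(nrow(mean_ratio)))
    cat(sprintf("  %-5s %.3f\n", mean_ratio$family[i], mean_ratio$ratio[i]))
  cat(sprintf("mean log-likelihood gain vs K = 1 static: %.3f\n", mean(x$gains$gain)))
  invisible(x)
}

#' @export
glance.style_experiment <- function(x, ...) {
  r <- x$errors %>%
    group_by(.data$family) %>%
    summarise(ratio = mean(.data$ratio), .groups = "drop")
  tibble(K = x$manifest$K, t0 = x$manifest$t0,
         horizon = x$manifest$horizon,
         pi_ratio = r$ratio[r$family == "pi"],
         alpha_ratio = r$ratio[r$family == "alpha"],
         mu_ratio = r$ratio[r$family == "mu"],
         mean_gain = mean(x$gains$gain))
}
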