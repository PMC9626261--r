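# shared synthetic study conditions

# three well-separated mean distributions on an 8-cell simplex
sep_mu3 <- function() {
  rbind(c(0.45, 0.20, 0.10, 0.10, 0.05, 0.04, 0.03, 0.03),
        c(0.04, 0.05, 0.45, 0.20, 0.10, 0.08, 0.05, 0.03),
        c(0.03, 0.04, 0.05, 0.08, 0.10, 0.20, 0.45, 0.05))
}

# constant-parameter scenario for estimator recovery
recovery_spec <- function(n_songs = 200) {
  trajectory_spec(1980:2009, pi0 = c(0.25, 0.35, 0.40),
                  alpha = c(20, 30, 40), mu = sep_mu3(),
                  n_songs = n_songs, n_events = 300)
}

# persistent-fitness-trend scenario: cluster 3 rises, cluster 1 declines,
# cluster 3 also contracts (alpha doubles)
trend_spec <- function(n_songs = 50) {
  trajectory_spec(1970:2009, pi0 = c(0.55, 0.30, 0.15),
                  fitness = c(0.94, 1.0, 1.07),
                  alpha = c(25, 30, 35), alpha_end = c(25, 30, 70),
                  mu = sep_mu3(), n_songs = n_songs, n_events = 300)
}

# a constant DMM trajectory built directly from parameters
constant_trajectory <- function(years, pi, alpha, mu) {
  new_dmm_trajectory <- getFromNamespace("new_dmm_trajectory", "styledyn")
  new_dmm_trajectory(lapply(years, function(t) dmm_params(t, pi, alpha, mu)))
}

# trajectory from explicit per-year parameter values
new_dmm_trajectory_for_test <- function(years, pi_mat, alpha, mu = NULL,
                                        mu_series = NULL) {
  ctor <- getFromNamespace("new_dmm_trajectory", "styledyn")
  pi_mat <- as.matrix(pi_mat)
  ctor(lapply(seq_along(years), function(i) {
    m <- if (!is.null(mu_series)) mu_series[[i]] else mu
    a <- if (is.matrix(alpha)) alpha[i, ] else alpha
    dmm_params(years[i], pi_mat[i, ], a, m)
  }))
}

# brute-force alpha grid-search oracle for the Dirichlet fit
grid_search_alpha <- function(theta, mu, grid = exp(seq(log(1e-2), log(1e6),
                                                        length.out = 400))) {
  ll <- vapply(grid, function(a)
    sum(dirichlet_log_density(theta, a, mu)), numeric(1))
  grid[which.max(ll)]
}
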