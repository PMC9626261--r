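make_styles <- function(theta, years, n_events = 100) {
  new_style_tbl <- getFromNamespace("new_style_tbl", "styledyn")
  new_style_tbl(theta, sprintf("s%03d", seq_len(nrow(theta))), years,
                rep(n_events, nrow(theta)), "synthetic",
                sprintf("f%d", seq_len(ncol(theta))))
}

test_that("per-slice statistics compute frequencies and means, flag empties", {
  theta <- rbind(c(0.6, 0.4), c(0.7, 0.3), c(0.2, 0.8), c(0.3, 0.7),
                 c(0.6, 0.4), c(0.4, 0.6))
  styles <- make_styles(theta, c(2000, 2000, 2000, 2000, 2001, 2001))
  labels <- c(1L, 1L, 2L, 2L, 1L, 1L)
  sl <- slice_statistics(styles, labels, K = 2)
  expect_equal(sl$pi_S["2000", ], c(0.5, 0.5))
  expect_equal(unname(sl$mu_S[[2]]["2000", ]), c(0.25, 0.75))
  # cluster 2 has no members in 2001: missing, not zero
  expect_true(all(is.na(sl$mu_S[[2]]["2001", ])))
  expect_equal(sl$pi_S["2001", ], c(1, 0))
  expect_equal(unname(rowSums(sl$pi_S)), c(1, 1))
  expect_error(slice_statistics(styles, c(labels[-6], 5L), K = 2), "1..K")
})

test_that("decay weights concentrate on the target year as tau -> 0", {
  set.seed(6)
  theta <- floor_renormalize(matrix(runif(20 * 3), 20), 1e-3)
  styles <- make_styles(theta, rep(2000:2003, each = 5))
  labels <- rep(1L, 20)
  sl <- slice_statistics(styles, labels, K = 1)
  est <- weighted_average_estimate(sl, 2003, tau = 1e-3)
  expect_equal(drop(est$mu), colMeans(theta[16:20, ]), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(est$pi, 1)
})

test_that("time-constant data give the same estimate for any tau", {
  theta_year <- rbind(c(0.5, 0.3, 0.2), c(0.3, 0.5, 0.2), c(0.2, 0.3, 0.5))
  theta <- do.call(rbind, rep(list(theta_year), 4))
  styles <- make_styles(theta, rep(2000:2003, each = 3))
  labels <- rep(c(1L, 1L, 2L), 4)
  sl <- slice_statistics(styles, labels, K = 2)
  e1 <- suppressWarnings(weighted_average_estimate(sl, 2003, tau = 0.5))
  e2 <- suppressWarnings(weighted_average_estimate(sl, 2003, tau = 20))
  expect_equal(e1$pi, e2$pi, tolerance = 1e-12)
  expect_equal(e1$mu, e2$mu, tolerance = 1e-12)
  expect_equal(e1$pi, c(2 / 3, 1 / 3), tolerance = 1e-12)
})

test_that("two populated slices combine with the exponential decay weights", {
  m1 <- c(0.7, 0.2, 0.1)
  m2 <- c(0.2, 0.2, 0.6)
  theta <- rbind(m1, m1, m2, m2) # two songs per year so means are exact
  styles <- make_styles(theta, c(2000, 2000, 2001, 2001))
  sl <- slice_statistics(styles, rep(1L, 4), K = 1)
  tau <- 3
  est <- suppressWarnings(weighted_average_estimate(sl, 2001, tau = tau))
  w <- exp(-1 / tau)
  expect_equal(drop(est$mu), (w * m1 + m2) / (w + 1), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("weighted averages are convex combinations and converge to the pooled mean", {
  set.seed(7)
  theta <- floor_renormalize(matrix(runif(40 * 3), 40), 1e-3)
  styles <- make_styles(theta, rep(1991:1998, each = 5))
  labels <- rep(1:2, 20)[order(rep(1:2, 20))][1:40]
  labels <- rep(c(1L, 1L, 1L, 2L, 2L), 8)
  sl <- slice_statistics(styles, labels, K = 2)
  est <- weighted_average_estimate(sl, 1998, tau = 4)
  expect_equal(sum(est$pi), 1, tolerance = 1e-12)
  expect_equal(unname(rowSums(est$mu)), c(1, 1), tolerance = 1e-12)
  for (k in 1:2) {
    rng <- range(sl$pi_S[, k])
    expect_gte(est$pi[k], rng[1] - 1e-12)
    expect_lte(est$pi[k], rng[2] + 1e-12)
  }
  # tau -> infinity: equal-weight average of the slice estimates
  big <- weighted_average_estimate(sl, 1998, tau = 1e6)
  expect_equal(big$pi, colMeans(sl$pi_S), tolerance = 1e-5)
  expect_equal(big$mu[1, ], colMeans(sl$mu_S[[1]]), tolerance = 1e-5)
})

test_that("window estimates pool years uniformly", {
  set.seed(8)
  theta <- floor_renormalize(matrix(runif(30 * 3), 30), 1e-3)
  styles <- make_styles(theta, rep(2001:2003, each = 10))
  labels <- rep(rep(c(1L, 2L), 5), 3)
  sl <- slice_statistics(styles, labels, K = 2)

  w1 <- window_estimate(sl, 2003, width = 1)
  expect_equal(w1$pi, sl$pi_S["2003", ], tolerance = 1e-12)
  expect_equal(w1$mu[1, ], sl$mu_S[[1]]["2003", ], tolerance = 1e-12)

  wall <- window_estimate(sl, 2003, width = 3)
  expect_equal(wall$mu[2, ], colMeans(theta[labels == 2L, ]), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(wall$pi, c(0.5, 0.5), tolerance = 1e-12)

  # width 2 with equal slice sizes averages the two slice means
  w2 <- window_estimate(sl, 2003, width = 2)
  expect_equal(w2$mu[1, ],
               colMeans(sl$mu_S[[1]][c("2002", "2003"), ]), tolerance = 1e-12)
  expect_error(window_estimate(sl, 1990, width = 1), "no populated")
})

test_that("estimate_ddmm produces a coherent year-indexed trajectory", {
  sim <- sample_ddmm_dataset(example_trajectory_spec(years = 1995:2004), seed = 9)
  traj <- estimate_ddmm(sim$styles, sim$labels, tau = 5)
  expect_s3_class(traj, "dmm_trajectory")
  expect_equal(as.integer(names(traj)), 1995:2004)
  td <- tidy(traj)
  expect_equal(nrow(td), 10 * 3)
  expect_true(all(td$alpha > 0))
})

test_that("time-constant selection favours smoothing for slowly drifting data", {
  mu <- rbind(c(0.5, 0.2, 0.1, 0.1, 0.05, 0.05),
              c(0.05, 0.1, 0.5, 0.2, 0.1, 0.05))
  spec <- trajectory_spec(1980:2009, pi0 = c(0.5, 0.5),
                          fitness = c(0.99, 1.01), alpha = c(30, 30),
                          mu = mu, n_songs = 20, n_events = 200)
  sim <- sample_ddmm_dataset(spec, seed = 10)
  curve <- suppressWarnings(
    select_time_constant(sim$styles, sim$labels, tau_grid = c(1, 8),
                         t0_range = 1990:2008))
  ll <- setNames(curve$mean_loglik, curve$tau)
  expect_gt(ll[["8"]], ll[["1"]])

  # stationary data: pooling more years cannot hurt, beyond noise
  spec0 <- trajectory_spec(1980:2009, pi0 = c(0.5, 0.5), alpha = c(30, 30),
                           mu = mu, n_songs = 20, n_events = 200)
  sim0 <- sample_ddmm_dataset(spec0, seed = 11)
  curve0 <- suppressWarnings(
    select_time_constant(sim0$styles, sim0$labels, tau_grid = c(1, 30),
                         t0_range = 1990:2008))
  ll0 <- setNames(curve0$mean_loglik, curve0$tau)
  expect_gt(ll0[["30"]], ll0[["1"]] - 0.02)
  expect_error(select_time_constant(sim0$styles, sim0$labels,
                                    tau_grid = numeric(0)), "non-empty")
})
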