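test_that("noiseless trends and constant series give exact terminal velocities", {
  lin <- fit_trend_ssm(3 + 0.5 * (1:20))
  expect_equal(tail(lin$velocity, 1), 0.5, tolerance = 1e-6)
  flat <- fit_trend_ssm(rep(2.5, 10))
  expect_equal(tail(flat$velocity, 1), 0, tolerance = 1e-6)
  expect_error(fit_trend_ssm(c(1, 2, 3)), "at least 4")
  expect_error(fit_trend_ssm(c(1, 2, NA, 4, 5)), "finite")
})

test_that("zero velocity innovation reduces to constant-velocity regression", {
  set.seed(12)
  y <- 1 + 0.8 * (1:15) + rnorm(15, 0, 0.3)
  fit <- fit_trend_ssm(y, sigma2_eta = 0)
  slope <- unname(coef(lm(y ~ seq_along(y)))[2])
  expect_equal(tail(fit$velocity, 1), slope, tolerance = 1e-5)
  # smoothed velocity is constant past the diffuse burn-in of the filter
  expect_lt(diff(range(fit$velocity[5:15])), 1e-6 * abs(slope))
})

test_that("noise variances are recovered within a factor of 2 and filtering beats the naive walk", {
  set.seed(13)
  reps <- 40
  s2 <- se <- rmse_f <- rmse_naive <- numeric(reps)
  for (r in seq_len(reps)) {
    v <- cumsum(c(0.02, rnorm(49, 0, 0.02)))
    x <- cumsum(c(0, v))[1:50]
    y <- x + rnorm(50, 0, 0.1)
    fit <- fit_trend_ssm(y)
    s2[r] <- fit$sigma2
    se[r] <- fit$sigma2_eta
    err_f <- y[11:50] - fit$pred[11:50]
    err_n <- y[11:50] - y[10:49]
    rmse_f[r] <- sqrt(mean(err_f^2))
    rmse_naive[r] <- sqrt(mean(err_n^2))
  }
  expect_lt(abs(log(median(s2) / 0.01)), log(2))
  expect_lt(abs(log(median(se) / 4e-4)), log(2))
  expect_lt(median(rmse_f), median(rmse_naive))
})

test_that("forecasts scale linearly with the reduction factor", {
  fit <- fit_trend_ssm(3 + 0.5 * (1:20))
  expect_equal(forecast_trend(fit, 5, rho = 1), 3 + 0.5 * (21:25),
               tolerance = 1e-6)
  xT <- tail(fit$level, 1)
  full <- forecast_trend(fit, 8, rho = 1) - xT
  half <- forecast_trend(fit, 8, rho = 0.5) - xT
  expect_equal(half, full / 2, tolerance = 1e-9)
  tiny <- forecast_trend(fit, 8, rho = 0.01)
  expect_equal(tiny, rep(xT, 8) + 0.01 * full, tolerance = 1e-9)
  expect_error(forecast_trend(fit, 5, rho = 0), "0.01")
  expect_error(forecast_trend(fit, 5, rho = 1.5), "0.01")
})

test_that("static forecast freezes parameters at every horizon", {
  p <- dmm_params(2000, c(0.6, 0.4), c(10, 20),
                  rbind(c(0.7, 0.3), c(0.2, 0.8)))
  st <- static_forecast(p, 20)
  expect_equal(st[["2001"]]$pi, p$pi)
  expect_equal(st[["2020"]]$alpha, p$alpha)
  expect_equal(st[["2020"]]$mu, p$mu)
  expect_equal(sum(st[["2010"]]$pi), 1)
})

test_that("constant parameter series forecast to the static model", {
  traj <- constant_trajectory(2000:2006, c(0.5, 0.3, 0.2), c(10, 20, 30),
                              sep_mu3())
  fc <- forecast_ddmm(traj, horizon = 6)
  st <- static_forecast(traj[["2006"]], 6)
  for (y in names(fc)) {
    expect_equal(fc[[y]]$pi, st[[y]]$pi, tolerance = 1e-6)
    expect_equal(fc[[y]]$alpha, st[[y]]$alpha, tolerance = 1e-6)
    expect_equal(fc[[y]]$mu, st[[y]]$mu, tolerance = 1e-6)
  }
})

test_that("replicator trajectories with constant fitness are extrapolated correctly", {
  w <- c(1.05, 1.0, 0.95)
  pis <- simulate_replicator(c(0.2, 0.5, 0.3), w, 30)
  mu <- sep_mu3()
  hist_years <- 1980:2000
  traj <- new_dmm_trajectory_for_test(hist_years, pis[1:21, ], c(20, 20, 20), mu)
  fc <- forecast_ddmm(traj, horizon = 10, rho = c(pi = 1, alpha = 1, mu = 1))
  for (h in 1:10) {
    expect_equal(fc[[as.character(2000 + h)]]$pi, pis[21 + h, ],
                 tolerance = 0.02, ignore_attr = TRUE)
  }
})

test_that("rare mean components are carried forward statically", {
  D <- 5
  mu_start <- c(0.495, 0.3, 0.1, 0.1, 0.005)
  mu_end <- c(0.295, 0.5, 0.1, 0.1, 0.005)
  yrs <- 1990:2000
  frac <- (seq_along(yrs) - 1) / (length(yrs) - 1)
  traj <- new_dmm_trajectory_for_test(
    yrs, matrix(1, length(yrs), 1), rep(20, 1) ,
    NULL, mu_series = lapply(frac, function(f)
      rbind((1 - f) * mu_start + f * mu_end)))
  fc <- forecast_ddmm(traj, horizon = 5, rho = c(pi = 1, alpha = 1, mu = 1))
  for (h in 1:5) {
    mu_h <- fc[[as.character(2000 + h)]]$mu[1, ]
    # the 0.005 component stays at its last value up to renormalization
    expect_equal(unname(mu_h[5] / mu_h[5]), 1)
    expect_lt(abs(mu_h[5] - 0.005), 5e-4)
    # the trending components keep moving
    expect_lt(mu_h[1], 0.30)
    expect_gt(mu_h[2], 0.50)
  }
})

test_that("decoupled log-forecasts with normalization match the replicator update", {
  set.seed(14)
  for (i in 1:10) {
    pi0 <- floor_renormalize(runif(4), 1e-3)
    v <- runif(4, -0.05, 0.05)
    w <- exp(v)
    coupled <- simulate_replicator(pi0, w, 1)[2, ]
    vrel <- log(w / sum(w * pi0))
    dec <- exp(log(pi0) + vrel)
    dec <- dec / sum(dec)
    expect_lt(max(abs(dec - coupled)), 1e-3)
  }
})

test_that("reduction factors are selected by backtest error", {
  # a single-candidate grid is returned unconditionally
  traj <- constant_trajectory(2000:2009, c(0.5, 0.5), c(10, 10),
                              rbind(c(0.6, 0.4), c(0.3, 0.7)))
  sel1 <- optimize_reduction_factor(traj, rho_grid = 1, holdout = 3)
  expect_true(all(sel1$rho == 1))
  expect_error(optimize_reduction_factor(traj, rho_grid = c(0.001, 1)),
               "0.01")

  # persistent trend: trend-following (large rho) wins
  w <- c(1.06, 0.97)
  pis <- simulate_replicator(c(0.3, 0.7), w, 19)
  tr_trend <- new_dmm_trajectory_for_test(1990:2009, pis, c(15, 25),
                                          rbind(c(0.6, 0.4), c(0.3, 0.7)))
  sel <- optimize_reduction_factor(tr_trend, rho_grid = c(0.01, 0.1, 0.5, 1),
                                   holdout = 5)
  expect_gte(sel$rho[sel$family == "pi"], 0.5)

  # white-noise fluctuation around a constant: damping wins
  set.seed(15)
  pi_noise <- floor_renormalize(
    matrix(rep(c(0.5, 0.5), each = 20), 20) * exp(matrix(rnorm(40, 0, 0.15), 20)))
  tr_noise <- new_dmm_trajectory_for_test(1990:2009, pi_noise, c(15, 25),
                                          rbind(c(0.6, 0.4), c(0.3, 0.7)))
  seln <- optimize_reduction_factor(tr_noise, rho_grid = c(0.01, 0.1, 0.5, 1),
                                    holdout = 5)
  expect_lte(seln$rho[seln$family == "pi"], 0.1)
})
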