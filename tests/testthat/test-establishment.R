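# The FFBS sampler is checked against the independent closed-form Kalman
# recursions in helper-oracles.R, in known-variance mode where its retained
# level paths are i.i.d. draws from the exact smoothing distribution.

test_that("constant series: sampler matches the closed-form Kalman limit", {
  y <- rep(3, 15)
  cfg <- mcmc_config(iterations = 4000, burn_in = 500,
                     fixed_obs_var = 0.5, fixed_level_var = 1e-8,
                     seed = 1)
  fit <- fit_local_level(y, cfg)
  init <- llm_init(fit$z)
  sm <- kalman_smoother_oracle(fit$z, 0.5, 1e-8, init$m0, init$C0)
  est <- colMeans(fit$draws$level)
  mcse <- apply(fit$draws$level, 2, sd) / sqrt(nrow(fit$draws$level))
  expect_true(all(abs(est - sm$mean) < 3 * mcse + 1e-6))
})

test_that("FFBS level posterior matches the exact Kalman smoother", {
  set.seed(42)
  n_bad <- 0; n_tot <- 0
  for (rep in 1:5) {
    sim <- simulate_local_level(30, s2e = 1, s2h = 0.1, mu0 = 2)
    cfg <- mcmc_config(iterations = 4500, burn_in = 500,
                       transform = "identity",
                       fixed_obs_var = 1, fixed_level_var = 0.1)
    fit <- fit_local_level(sim$z, cfg)
    init <- llm_init(sim$z)
    sm <- kalman_smoother_oracle(sim$z, 1, 0.1, init$m0, init$C0)
    est <- colMeans(fit$draws$level)
    mcse <- apply(fit$draws$level, 2, sd) / sqrt(nrow(fit$draws$level))
    n_bad <- n_bad + sum(abs(est - sm$mean) > 3 * mcse)
    n_tot <- n_tot + 30
    # posterior sd should match the smoother sd too (i.i.d. draws)
    expect_equal(apply(fit$draws$level, 2, sd), sqrt(sm$var),
                 tolerance = 0.1)
  }
  # ~0.3% of pointwise 3-SE checks fail by chance for a correct sampler
  expect_lt(n_bad / n_tot, 0.02)
})

test_that("missing observations diffuse the level between updates", {
  set.seed(9)
  z <- c(rnorm(10, 5, 0.3), NA, NA, rnorm(5, 5, 0.3))
  cfg <- mcmc_config(iterations = 3000, burn_in = 500,
                     transform = "identity",
                     fixed_obs_var = 0.25, fixed_level_var = 0.2, seed = 2)
  fit <- fit_local_level(z, cfg)
  init <- llm_init(z)
  sm <- kalman_smoother_oracle(z, 0.25, 0.2, init$m0, init$C0)
  est <- colMeans(fit$draws$level)
  mcse <- apply(fit$draws$level, 2, sd) / sqrt(nrow(fit$draws$level))
  expect_true(mean(abs(est - sm$mean) < 3 * mcse) > 0.9)
})

test_that("input validation: short or non-finite series are rejected", {
  expect_error(fit_local_level(rep(1, 9)), "insufficient calibration")
  expect_error(fit_local_level(c(rep(1, 12), Inf)), "non-finite")
  yna <- c(rep(NA, 10), rep(1, 9))
  expect_error(fit_local_level(yna), "insufficient calibration")
})

test_that("one-step forecast matches the closed-form Kalman forecast", {
  set.seed(17)
  sim <- simulate_local_level(25, s2e = 1, s2h = 0.2, mu0 = 3)
  cfg <- mcmc_config(iterations = 6000, burn_in = 500,
                     transform = "identity",
                     fixed_obs_var = 1, fixed_level_var = 0.2, seed = 3)
  fit <- fit_local_level(sim$z, cfg)
  draws <- forecast_one_step(fit)
  zf <- attr(draws, "z_draws")
  init <- llm_init(sim$z)
  kf <- kalman_filter_oracle(sim$z, 1, 0.2, init$m0, init$C0)
  mcse <- sd(zf) / sqrt(length(zf))
  expect_lt(abs(mean(zf) - kf$forecast_mean), 3 * mcse)
  expect_equal(var(zf), kf$forecast_var, tolerance = 0.1)
})

test_that("predictive spread always exceeds the filtered level spread", {
  set.seed(23)
  for (s2h in c(0.01, 0.5)) {
    sim <- simulate_local_level(20, s2e = 0.5, s2h = s2h)
    fit <- fit_local_level(exp(pmax(sim$z, 0)),
                           mcmc_config(seed = 4))
    draws <- forecast_one_step(fit)
    expect_gte(var(attr(draws, "z_draws")),
               var(attr(draws, "level_draws")))
  }
})

test_that("an all-zero history forecasts zero moths", {
  fit <- fit_local_level(rep(0, 15), mcmc_config(seed = 5))
  draws <- forecast_one_step(fit)
  expect_gt(prob_zero(draws), 0.95)
  expect_lt(mean(draws), 0.5)
})

test_that("prob_zero counts draws below the threshold", {
  expect_equal(prob_zero(c(0, 0.1, 0.2, 0.4), 0.5), 1.0)
  expect_equal(prob_zero(c(1, 2, 3, 4), 0.5), 0.0)
  expect_equal(prob_zero(c(rep(0, 2), rep(5, 998)), 0.5), 0.002)
  expect_error(prob_zero(numeric(0)), "empty")
})

test_that("establishment year is the first sub-alpha year at or after detection", {
  years <- 1995:1998
  expect_equal(establishment_year(c(0.9, 0.4, 0.009, 0.001), years, 1995),
               1997L)
  expect_true(is.na(establishment_year(rep(0.5, 4), years, 1995)))
  # sub-alpha years before detection are ignored
  expect_equal(establishment_year(c(0.005, 0.5, 0.002, 0.5), years, 1996),
               1997L)
  expect_error(establishment_year(c(0.5), 1995, NA), "never detected")
  # threshold is a strict inequality
  expect_true(is.na(establishment_year(0.01, 1995, 1995)))
})

test_that("waiting time is the year difference, guarded against inversion", {
  expect_equal(waiting_time(2000L, 2007L), 7L)
  expect_equal(waiting_time(2000L, 2000L), 0L)
  expect_error(waiting_time(2005L, 2000L), "precedes")
})

test_that("variance posteriors concentrate near simulated truth", {
  set.seed(31)
  sim <- simulate_local_level(60, s2e = 1, s2h = 0.1, mu0 = 3)
  fit <- fit_local_level(sim$z,
                         mcmc_config(transform = "identity", seed = 6))
  e_lo <- quantile(fit$draws$sig2_obs, 0.025)
  e_hi <- quantile(fit$draws$sig2_obs, 0.975)
  expect_true(e_lo < 1 && 1 < e_hi)
  expect_lt(quantile(fit$draws$sig2_level, 0.5), 1)  # well below s2e
})

test_that("tenfold counts never raise the probability of zero", {
  set.seed(45)
  y <- rpois(15, 2)
  p1 <- prob_zero(forecast_one_step(fit_local_level(y, mcmc_config(seed = 7))))
  p10 <- prob_zero(forecast_one_step(fit_local_level(y * 10,
                                                     mcmc_config(seed = 7))))
  expect_lte(p10, p1)
})

test_that("fits are fully deterministic given the seed", {
  y <- c(0, 0, 0, 1, 0, 2, 1, 3, 2, 5, 8, 12)
  f1 <- fit_local_level(y, mcmc_config(seed = 99))
  f2 <- fit_local_level(y, mcmc_config(seed = 99))
  expect_identical(f1$draws, f2$draws)
})

test_that("establish_quadrats resolves statuses and respects the window", {
  sim <- simulate_dataset(sim_config(n_rows = 5, n_cols = 5, seed = 77))
  ser <- median_series(assign_quadrats(sim$traps,
                                       grid_spec(n_rows = 5, n_cols = 5)))
  est <- establish_quadrats(ser, config = mcmc_config(seed = 8))
  expect_s3_class(est, "wt_establishment")
  inc <- est[est$status == "INCLUDED", ]
  expect_gt(nrow(inc), 0)
  # first target year leaves 10 calibration years
  pz <- tidyr::unnest(est[, c("row", "col", "prob_zero")], "prob_zero")
  expect_gte(min(pz$year), 1995)
  expect_true(all(inc$establishment_year >= inc$detection_year))
  expect_true(all(inc$waiting_time ==
                    inc$establishment_year - inc$detection_year))
  expect_true(all(pz$p >= 0 & pz$p <= 1))
})

test_that("the establishment stage is deterministic given config and seed", {
  sim <- simulate_dataset(sim_config(n_rows = 4, n_cols = 4, seed = 3))
  ser <- median_series(assign_quadrats(sim$traps,
                                       grid_spec(n_rows = 4, n_cols = 4)))
  e1 <- establish_quadrats(ser, config = mcmc_config(seed = 11))
  e2 <- establish_quadrats(ser, config = mcmc_config(seed = 11))
  expect_identical(e1, e2)
})

test_that("forecast validation behaves at its reference points", {
  rec <- tibble::tibble(
    forecasts = list(tibble::tibble(year = 1995:2004,
                                    forecast = 1:10 + 0.0,
                                    observed = 1:10 + 0.0)))
  expect_equal(validate_forecasts(rec), 1.0)
  set.seed(5)
  n <- 300
  obs <- rpois(n, 5)
  rec2 <- tibble::tibble(
    forecasts = list(tibble::tibble(year = seq_len(n),
                                    forecast = sample(obs),
                                    observed = obs + 0.0)))
  expect_lt(abs(validate_forecasts(rec2)), 3 / sqrt(n))
  expect_error(validate_forecasts(tibble::tibble(forecasts = list(
    tibble::tibble(year = 1:2, forecast = c(1, 2), observed = c(1, 2))))),
    "at least 3")
  expect_error(validate_forecasts(tibble::tibble(forecasts = list(
    tibble::tibble(year = 1:5, forecast = rep(1, 5), observed = 1:5 + 0.0)))),
    "zero-variance")
})

test_that("forecasts on simulated data beat their own permutation null", {
  sim <- simulate_dataset(sim_config(n_rows = 5, n_cols = 5, seed = 21))
  ser <- median_series(assign_quadrats(sim$traps,
                                       grid_spec(n_rows = 5, n_cols = 5)))
  est <- establish_quadrats(ser, config = mcmc_config(seed = 9),
                            stop_at_establishment = FALSE)
  r_obs <- validate_forecasts(est)
  pairs <- tidyr::unnest(est[, "forecasts"], "forecasts")
  pairs <- pairs[!is.na(pairs$observed), ]
  set.seed(1)
  r_perm <- replicate(200, cor(sample(pairs$forecast), pairs$observed))
  expect_gt(r_obs, quantile(r_perm, 0.99))
})
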