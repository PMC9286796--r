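# Simulated mixed-model data with known coefficients, for recovery and
# selection checks. Predictors are standard normal, so the standardized
# fit scale coincides with the generative scale up to sampling noise.
make_lmm_data <- function(n, beta, sd_group = 1, sd_resid = 1,
                          n_groups = 12, n_noise = 0) {
  k <- length(beta)
  X <- matrix(rnorm(n * (k + n_noise)), n)
  colnames(X) <- c(names(beta),
                   if (n_noise > 0) paste0("noise", seq_len(n_noise)))
  g <- sample(paste0("g", seq_len(n_groups)), n, replace = TRUE)
  b <- setNames(rnorm(n_groups, 0, sd_group), paste0("g", seq_len(n_groups)))
  y <- drop(X[, seq_len(k), drop = FALSE] %*% beta) + b[g] +
    rnorm(n, 0, sd_resid)
  out <- tibble::tibble(waiting_time = y, level4 = g,
                        detection_year = rnorm(n),
                        neighborhood_wait = rnorm(n))
  dplyr::bind_cols(out, tibble::as_tibble(X))
}

test_that("with no group variance the fit matches an OLS oracle", {
  set.seed(2)
  dat <- make_lmm_data(500, c(a = 1, b = -0.5), sd_group = 0)
  fit <- suppressMessages(fit_lmm(dat, c("a", "b"), standardize = FALSE))
  expect_equal(fit$sigma2_group, 0)  # ML lands on the boundary
  ols <- lm(waiting_time ~ a + b + detection_year + neighborhood_wait,
            data = dat)
  est <- tidy(fit)
  expect_lt(max(abs(est$estimate[match(names(coef(ols)), est$term)] -
                      coef(ols))), 1e-6)
})

test_that("coefficients recover simulated truth within reported error", {
  set.seed(2)
  hits <- 0
  for (r in 1:20) {
    dat <- make_lmm_data(1000, c(a = 1, b = -0.7), 1, 1)
    est <- tidy(fit_lmm(dat, c("a", "b"), standardize = FALSE))
    ok_a <- abs(est$estimate[est$term == "a"] - 1) <
      2 * est$std.error[est$term == "a"]
    ok_b <- abs(est$estimate[est$term == "b"] + 0.7) <
      2 * est$std.error[est$term == "b"]
    hits <- hits + (ok_a && ok_b)
  }
  expect_gte(hits, 16)  # ~0.95^2 joint coverage per replicate
})

test_that("adding a pure-noise predictor never lowers the log-likelihood", {
  set.seed(3)
  dat <- make_lmm_data(400, c(a = 1), n_noise = 1)
  f0 <- fit_lmm(dat, "a")
  f1 <- fit_lmm(dat, c("a", "noise1"))
  expect_gte(as.numeric(logLik(f1$model)), as.numeric(logLik(f0$model)))
})

test_that("AIC counts fixed plus variance parameters", {
  set.seed(4)
  dat <- make_lmm_data(300, c(a = 1))
  fit <- fit_lmm(dat, "a")
  ll <- logLik(fit$model)
  # intercept + 3 slopes + random-intercept and residual variances
  expect_equal(attr(ll, "df"), 4 + 2)
  expect_equal(AIC(fit$model), -2 * as.numeric(ll) + 2 * attr(ll, "df"))
})

test_that("a singular design fails naming the collinear column", {
  set.seed(5)
  dat <- make_lmm_data(200, c(a = 1))
  dat$dup <- dat$a
  expect_error(fit_lmm(dat, c("a", "dup")), "dup")
  expect_error(fit_lmm(dat, "nonexistent"), "missing columns")
})

test_that("all-subsets search enumerates 2^k models exactly once", {
  set.seed(6)
  dat <- make_lmm_data(200, c(a = 1, b = 0))
  dr <- all_subsets_aic(dat, c("a", "b"))
  expect_equal(nrow(dr$models), 4)
  expect_setequal(dr$models$terms, c("", "a", "b", "a+b"))
  expect_equal(nrow(dr$failures), 0)
})

test_that("the search reproduces an independent brute-force AIC table", {
  set.seed(7)
  dat <- make_lmm_data(250, c(a = 0.8, b = 0, c = -0.4))
  dr <- all_subsets_aic(dat, c("a", "b", "c"))
  # independent loop over subsets via direct lme4 calls
  subsets <- unlist(lapply(0:3, function(m)
    utils::combn(c("a", "b", "c"), m, paste, collapse = "+")))
  oracle <- vapply(subsets, function(s) {
    rhs <- paste(c(strsplit(s, "+", fixed = TRUE)[[1]],
                   "detection_year", "neighborhood_wait"), collapse = " + ")
    d2 <- dat
    for (p in c(strsplit(s, "+", fixed = TRUE)[[1]],
                "detection_year", "neighborhood_wait"))
      d2[[p]] <- as.numeric(scale(d2[[p]]))
    AIC(lme4::lmer(as.formula(paste("waiting_time ~", rhs, "+ (1 | level4)")),
                   data = d2, REML = FALSE))
  }, numeric(1))
  expect_equal(sort(dr$models$AIC), sort(unname(oracle)), tolerance = 1e-8)
  expect_equal(dr$models$terms[1], names(which.min(oracle)))
})

test_that("AIC ordering is invariant to predictor standardization", {
  set.seed(8)
  dat <- make_lmm_data(300, c(a = 1, b = 0.3))
  dat$a <- dat$a * 37 + 5   # de-standardize a predictor
  d1 <- all_subsets_aic(dat, c("a", "b"), standardize = TRUE)
  d2 <- all_subsets_aic(dat, c("a", "b"), standardize = FALSE)
  expect_equal(d1$models$terms[order(d1$models$mask)],
               d2$models$terms[order(d2$models$mask)])
  expect_equal(d1$models$AIC[order(d1$models$mask)],
               d2$models$AIC[order(d2$models$mask)], tolerance = 1e-6)
})

test_that("VIF matches its closed form and a regression oracle", {
  # orthogonal predictors -> VIF 1
  X <- cbind(a = c(1, 1, -1, -1, 0, 0), b = c(1, -1, 1, -1, 0, 0))
  expect_equal(unname(vif(X)), c(1, 1))
  # correlation 0.9 -> 1 / (1 - 0.81)
  set.seed(9)
  n <- 5000
  a <- rnorm(n); b <- 0.9 * a + sqrt(1 - 0.81) * rnorm(n)
  v <- vif(cbind(a = a, b = b))
  expect_equal(unname(v[1]), 1 / (1 - cor(a, b)^2), tolerance = 1e-8)
  expect_equal(unname(v[1]), 5.263, tolerance = 0.05 * 5.263)
  # random design vs explicit regression-based oracle
  M <- matrix(rnorm(600), 100)
  colnames(M) <- paste0("v", 1:6)
  v2 <- vif(M)
  for (j in 1:6) {
    r2 <- summary(lm(M[, j] ~ M[, -j]))$r.squared
    expect_equal(unname(v2[j]), 1 / (1 - r2), tolerance = 1e-8)
  }
  # perfect collinearity reported as infinite
  expect_true(is.infinite(suppressWarnings(vif(cbind(a = a, b = 2 * a)))[1]))
})

test_that("Nakagawa R2 identities hold exactly", {
  r2 <- r2_components(2, 1, 1)
  expect_equal(r2$r2_marginal, 0.5)
  expect_equal(r2$r2_conditional, 0.75)
  r2b <- r2_components(2, 0, 2)
  expect_equal(r2b$r2_marginal, r2b$r2_conditional)
  expect_error(r2_components(0, 0, 0), "undefined")
})

test_that("R2 components recover their simulated values", {
  set.seed(10)
  # beta (1, 1) on unit-variance predictors: sigma2_f ~ 2, alpha 1, resid 1
  dat <- make_lmm_data(2000, c(a = 1, b = 1), sd_group = 1, sd_resid = 1,
                       n_groups = 40)
  dat$detection_year <- dat$detection_year * 0  # isolate the two drivers
  dat$neighborhood_wait <- dat$neighborhood_wait * 0
  fit <- fit_lmm(dat, c("a", "b"), background = character(0))
  r2 <- r2_nakagawa(fit)
  expect_equal(r2$r2_marginal, 2 / 4, tolerance = 0.05)
  expect_equal(r2$r2_conditional, 3 / 4, tolerance = 0.05)
})

test_that("driver-only R2 partitions the fixed-effect variance", {
  set.seed(11)
  dat <- make_lmm_data(2000, c(a = 1, b = 1), sd_group = 1, sd_resid = 1,
                       n_groups = 40)
  # background carries no signal: driver R2 equals marginal R2
  fit <- fit_lmm(dat, c("a", "b"))
  expect_equal(r2_marginal_drivers(fit), r2_nakagawa(fit)$r2_marginal,
               tolerance = 0.02)
  # no drivers at all -> 0
  fit0 <- fit_lmm(dat, character(0))
  expect_equal(r2_marginal_drivers(fit0), 0)
  # analytic share under independence: beta_a^2 / (sum beta^2 + 1 + 1)
  expect_lt(abs(r2_marginal_drivers(fit, "a") - 1 / 4), 0.05)
})

test_that("glance and tidy expose the fit in broom style", {
  set.seed(12)
  dat <- make_lmm_data(300, c(a = 1))
  fit <- fit_lmm(dat, "a")
  g <- glance(fit)
  expect_true(all(c("AIC", "r2_marginal", "r2_conditional",
                    "r2_marginal_drivers") %in% names(g)))
  expect_true(g$r2_marginal <= g$r2_conditional)
  expect_true(g$r2_conditional <= 1 && g$r2_marginal >= 0)
  td <- tidy(fit)
  expect_true(all(c("(Intercept)", "a") %in% td$term))
})
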