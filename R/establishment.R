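#' MCMC configuration for the local-level establishment model
#'
#' Settings for the per-quadrat Bayesian local-level model
#' `z_t = mu_t + eps_t`, `mu_(t+1) = mu_t + eta_t`, fitted by a Gibbs
#' sampler alternating forward-filter backward-sampling of the level path
#' with conjugate inverse-gamma draws of the two variances. Counts are
#' transformed with `z = log(1 + y)` by default so the Gaussian error model
#' respects nonnegativity; variance priors are weakly informative and
#' scale-adaptive: inverse-gamma(shape, scale_factor * Var(z)).
#'
#' @param iterations Total Gibbs iterations (default 2000).
#' @param burn_in Discarded initial iterations (default 500).
#' @param prior_shape_obs,prior_scale_obs Inverse-gamma shape and
#'   scale factor (times `Var(z)`) for the observation variance.
#' @param prior_shape_level,prior_scale_level Same for the level-innovation
#'   variance; the smaller default factor encodes a slowly drifting level.
#' @param transform `"log1p"` (default) or `"identity"` for sensitivity
#'   checks.
#' @param zero_threshold Count below which a year counts as "zero moths"
#'   (default 0.5: a median that rounds to zero).
#' @param criterion `"forecast"` (default): probability of zero is the
#'   predictive `P(y* < zero_threshold)`. `"level"`: the latent-level
#'   alternative, the posterior probability that the level at the end of
#'   the fitting window lies below `transform(1)`.
#' @param fixed_obs_var,fixed_level_var If both are given, the variances
#'   are held fixed (known-variance mode, used for exact-Kalman checks).
#' @param var_floor Lower bound on the `Var(z)` used to scale the priors
#'   (default 0.5 on the `log1p` scale). Yearly medians are discrete, so a
#'   quadrat can produce a nearly constant transformed series whose sample
#'   variance collapses; the floor keeps the variance priors proper and
#'   guards against overconfident forecasts from such degenerate series.
#' @param init_level_var Diffuse initial-level variance, as a multiple of
#'   `Var(z)`.
#' @param seed Optional integer seed applied before sampling.
#' @return A list of class `wt_mcmc_config`.
#' @export
mcmc_config <- function(iterations = 2000, burn_in = 500,
                        prior_shape_obs = 2, prior_scale_obs = 0.5,
                        prior_shape_level = 2, prior_scale_level = 0.05,
                        transform = c("log1p", "identity"),
                        zero_threshold = 0.5,
                        criterion = c("forecast", "level"),
                        fixed_obs_var = NULL, fixed_level_var = NULL,
                        var_floor = 0.5,
                        init_level_var = 10, seed = NULL) {
  if (burn_in >= iterations) abort("`burn_in` must be smaller than `iterations`")
  if (zero_threshold <= 0) abort("`zero_threshold` must be > 0")
  structure(list(
    iterations = as.integer(iterations), burn_in = as.integer(burn_in),
    prior_shape_obs = prior_shape_obs, prior_scale_obs = prior_scale_obs,
    prior_shape_level = prior_shape_level,
    prior_scale_level = prior_scale_level,
    transform = match.arg(transform),
    zero_threshold = zero_threshold,
    criterion = match.arg(criterion),
    fixed_obs_var = fixed_obs_var, fixed_level_var = fixed_level_var,
    var_floor = var_floor,
    init_level_var = init_level_var, seed = seed
  ), class = "wt_mcmc_config")
}

wt_transform <- function(y, transform) {
  switch(transform, log1p = log1p(y), identity = y)
}
wt_inv_transform <- function(z, transform) {
  switch(transform, log1p = pmax(expm1(z), 0), identity = pmax(z, 0))
}

#' Fit the Bayesian local-level model to one quadrat series
#'
#' Runs the FFBS Gibbs sampler on the (transformed) yearly series. Missing
#' years are handled by skipping the measurement update, so the level
#' diffuses through gaps. Requires at least 10 non-missing observations
#' (the calibration minimum).
#'
#' @param y Numeric vector of yearly median catches, `NA` for years with no
#'   traps; the last element is year `t - 1` when forecasting year `t`.
#' @param config A [mcmc_config()].
#' @return An object of class `wt_llm` holding retained draws of the level
#'   path, both variances, and one-step-ahead predictive draws on the
#'   transformed scale.
#' @export
fit_local_level <- function(y, config = mcmc_config()) {
  stopifnot(inherits(config, "wt_mcmc_config"))
  if (any(!is.finite(y) & !is.na(y)))
    abort("non-finite observations are not allowed")
  n_obs <- sum(!is.na(y))
  if (n_obs < 10)
    abort("insufficient calibration data: need >= 10 non-missing observations")
  z <- wt_transform(y, config$transform)
  vz <- max(var(z, na.rm = TRUE), config$var_floor, 1e-3)

  fix_var <- !is.null(config$fixed_obs_var) && !is.null(config$fixed_level_var)
  if (!is.null(config$seed)) set.seed(config$seed)
  res <- ffbs_gibbs_cpp(
    z, config$iterations, config$burn_in,
    config$prior_shape_obs, config$prior_scale_obs * vz,
    config$prior_shape_level, config$prior_scale_level * vz,
    z[which(!is.na(z))[1]], config$init_level_var * vz,
    fix_var,
    config$fixed_obs_var %||% 0, config$fixed_level_var %||% 0,
    config$prior_scale_obs * vz, config$prior_scale_level * vz
  )
  structure(list(y = y, z = z, draws = res, config = config, n_obs = n_obs),
            class = "wt_llm")
}

#' @export
print.wt_llm <- function(x, ...) {
  cat("Local-level model fit:", length(x$y), "years,", x$n_obs,
      "observed;", nrow(x$draws$level), "retained draws\n")
  cat(sprintf("  posterior mean sigma2_obs = %.4f, sigma2_level = %.4f\n",
              mean(x$draws$sig2_obs), mean(x$draws$sig2_level)))
  invisible(x)
}

#' Posterior summary of the level path
#'
#' @param x A `wt_llm` fit.
#' @param ... Unused.
#' @return A tibble with one row per time point: posterior mean, sd, and
#'   95% credible bounds of the level.
#' @export
tidy.wt_llm <- function(x, ...) {
  L <- x$draws$level
  tibble::tibble(
    time = seq_len(ncol(L)),
    observed = x$z,
    estimate = colMeans(L),
    std.error = apply(L, 2, sd),
    conf.low = apply(L, 2, quantile, 0.025),
    conf.high = apply(L, 2, quantile, 0.975)
  )
}

#' @export
glance.wt_llm <- function(x, ...) {
  tibble::tibble(
    n_years = length(x$y), n_obs = x$n_obs,
    n_draws = nrow(x$draws$level),
    sigma2_obs = mean(x$draws$sig2_obs),
    sigma2_level = mean(x$draws$sig2_level)
  )
}

#' One-step-ahead predictive draws on the count scale
#'
#' For each retained draw the level is propagated one step with a fresh
#' innovation, observation noise is added, and the count transform is
#' inverted (`y* = exp(z*) - 1`, floored at 0, under the default
#' `log1p` transform).
#'
#' @param fit A [fit_local_level()] result.
#' @return Numeric vector of predictive count draws, with the
#'   transformed-scale draws attached as attribute `z_draws` and the
#'   final-level draws as attribute `level_draws`.
#' @export
forecast_one_step <- function(fit) {
  stopifnot(inherits(fit, "wt_llm"))
  zf <- fit$draws$z_forecast
  out <- wt_inv_transform(zf, fit$config$transform)
  attr(out, "z_draws") <- zf
  attr(out, "level_draws") <- fit$draws$level[, ncol(fit$draws$level)]
  out
}

#' Probability that a year's median catch is zero
#'
#' The fraction of one-step predictive draws falling below the zero
#' threshold (default 0.5 moths: a median that rounds to zero).
#'
#' @param draws Predictive count draws from [forecast_one_step()].
#' @param threshold Count threshold (default 0.5).
#' @return A probability in \[0, 1\].
#' @export
prob_zero <- function(draws, threshold = 0.5) {
  if (length(draws) == 0) abort("empty draw set")
  mean(draws < threshold)
}

#' Establishment year from a probability-of-zero series
#'
#' The earliest year at or after the detection year in which the
#' probability of a zero-moth median drops below `alpha` (default 0.01, a
#' conservative establishment definition, strict inequality). Years before
#' detection are ignored.
#'
#' @param p Numeric vector of probabilities of zero.
#' @param years Integer years aligned with `p`.
#' @param detection_year First year with median catch at detection level.
#' @param alpha Threshold (default 0.01).
#' @return The establishment year, or `NA` if none qualifies.
#' @export
establishment_year <- function(p, years, detection_year, alpha = 0.01) {
  if (is.na(detection_year))
    abort("missing detection year: quadrat was never detected")
  ok <- !is.na(p) & p < alpha & years >= detection_year
  if (!any(ok)) return(NA_integer_)
  as.integer(min(years[ok]))
}

#' Waiting time from detection to establishment
#'
#' @param detection_year,establishment_year Integer years (vectorized).
#' @return `establishment_year - detection_year`, in years.
#' @export
waiting_time <- function(detection_year, establishment_year) {
  bad <- !is.na(detection_year) & !is.na(establishment_year) &
    establishment_year < detection_year
  if (any(bad))
    abort("establishment year precedes detection year: pipeline bug")
  as.integer(establishment_year - detection_year)
}

#' Establishment analysis for all quadrats
#'
#' The per-quadrat waiting-time pipeline: for each eligible quadrat, an
#' expanding-window local-level fit per target year (the first target year
#' leaves `calibration` years of history) yields the one-step predictive
#' probability of a zero-moth median; the first year at or after detection
#' with probability below `alpha` is the establishment year, and the
#' waiting time is its distance from the detection year.
#'
#' @param series Output of [median_series()].
#' @param statuses Optional output of [apply_inclusion_filters()];
#'   computed with defaults when omitted.
#' @param config A [mcmc_config()]; its `seed` (default 1 when unset) seeds
#'   the whole stage once, making the stage deterministic.
#' @param alpha Establishment threshold on the probability of zero.
#' @param calibration Minimum calibration years before the first target
#'   year (default 10).
#' @param stop_at_establishment Stop fitting a quadrat once establishment
#'   is found (default `TRUE`); set `FALSE` to keep the full probability
#'   series for every target year.
#' @return A tibble of class `wt_establishment`: `row`, `col`,
#'   `detection_year`, `establishment_year`, `waiting_time`, `status`, and
#'   list-columns `prob_zero` (tibbles `year`, `p`) and `forecasts`
#'   (tibbles `year`, `forecast`, `observed`).
#' @export
establish_quadrats <- function(series, statuses = NULL,
                               config = mcmc_config(),
                               alpha = 0.01, calibration = 10,
                               stop_at_establishment = TRUE) {
  if (is.null(statuses)) statuses <- apply_inclusion_filters(series)
  years <- seq(min(series$year), max(series$year))
  first_target <- years[1] + calibration
  if (first_target > years[length(years)])
    abort("series too short for the calibration window")
  set.seed(config$seed %||% 1L)
  fit_cfg <- config
  fit_cfg$seed <- NULL

  by_quadrat <- split(series, paste(series$row, series$col))
  key <- paste(statuses$row, statuses$col)

  records <- purrr::map(seq_len(nrow(statuses)), function(i) {
    st <- statuses[i, ]
    rec <- tibble::tibble(
      row = st$row, col = st$col, detection_year = st$detection_year,
      establishment_year = NA_integer_, waiting_time = NA_integer_,
      status = st$status,
      prob_zero = list(tibble::tibble(year = integer(), p = numeric())),
      forecasts = list(tibble::tibble(year = integer(), forecast = numeric(),
                                      observed = numeric()))
    )
    if (st$status != "ELIGIBLE") return(rec)
    if (is.na(st$detection_year)) {
      rec$status <- "EXCLUDED_NEVER_ESTABLISHED"
      return(rec)
    }
    sq <- by_quadrat[[paste(st$row, st$col)]]
    y_full <- rep(NA_real_, length(years))
    y_full[match(sq$year, years)] <- sq$median
    start_t <- max(first_target, st$detection_year)
    p_year <- integer(0); p_val <- numeric(0)
    f_year <- integer(0); f_mean <- numeric(0); f_obs <- numeric(0)
    E <- NA_integer_
    for (t in seq(start_t, years[length(years)])) {
      hist <- y_full[years < t]
      if (sum(!is.na(hist)) < calibration) next
      fit <- fit_local_level(hist, fit_cfg)
      draws <- forecast_one_step(fit)
      p <- if (config$criterion == "level") {
        prob_zero(attr(draws, "level_draws"),
                  wt_transform(1, config$transform))
      } else {
        prob_zero(draws, config$zero_threshold)
      }
      p_year <- c(p_year, t); p_val <- c(p_val, p)
      f_year <- c(f_year, t); f_mean <- c(f_mean, mean(draws))
      f_obs <- c(f_obs, y_full[match(t, years)])
      if (is.na(E) && p < alpha) {
        E <- t
        if (stop_at_establishment) break
      }
    }
    if (is.na(E) && length(p_val) > 0)
      E <- establishment_year(p_val, p_year, st$detection_year, alpha)
    rec$prob_zero <- list(tibble::tibble(year = p_year, p = p_val))
    rec$forecasts <- list(tibble::tibble(year = f_year, forecast = f_mean,
                                         observed = f_obs))
    if (is.na(E)) {
      rec$status <- "EXCLUDED_NEVER_ESTABLISHED"
    } else {
      rec$establishment_year <- E
      rec$waiting_time <- waiting_time(st$detection_year, E)
      rec$status <- "INCLUDED"
    }
    rec
  })
  out <- dplyr::bind_rows(records)
  class(out) <- c("wt_establishment", class(out))
  out
}

#' Forecast validation: predicted vs observed correlation
#'
#' Pearson correlation between the one-step predictive mean catch and the
#' observed yearly median, pooled across quadrat-years, as a check of the
#' time-series model's predictive value.
#'
#' @param records A [establish_quadrats()] result.
#' @return The correlation coefficient.
#' @export
validate_forecasts <- function(records) {
  pairs <- tidyr::unnest(records[, "forecasts"], "forecasts")
  pairs <- pairs[!is.na(pairs$observed) & !is.na(pairs$forecast), ]
  if (nrow(pairs) < 3) abort("need at least 3 forecast/observed pairs")
  if (sd(pairs$forecast) == 0 || sd(pairs$observed) == 0)
    abort("zero-variance inputs: correlation undefined")
  cor(pairs$forecast, pairs$observed)
}
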