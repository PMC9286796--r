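#' Configuration for the synthetic invasion simulator
#'
#' Bundles every knob of the synthetic trap-catch generator: a traveling
#' invasion wave crosses a grid of 5 x 5 km quadrats, each quadrat's waiting
#' time from arrival to establishment is an additive function of spatially
#' smooth covariate fields plus a level-IV eco-region random intercept and
#' residual noise, and a pheromone-trap network samples the latent abundance
#' with negative-binomial counts. Treatments are yearly discs covering a
#' small, bounded fraction of the area.
#'
#' Defaults emulate a transition-zone monitoring campaign: 1985-2015, a wave
#' entering at one corner at 6 km/yr, a mean lag of 7 years from arrival to
#' establishment, ten named driver fields, and a two-level (level II over
#' level IV) eco-region hierarchy.
#'
#' @param n_rows,n_cols Grid extent in 5 km cells.
#' @param cell_size Cell edge length in meters.
#' @param years Integer vector of consecutive study years.
#' @param origin_cell `c(row, col)` (0-based) source of the invasion
#'   wave; may lie outside the grid (the default places it beyond the
#'   southwest corner so the front sweeps the whole grid mid-study).
#' @param speed_km_yr Wave speed in km per year (> 0).
#' @param drivers Tibble with columns `name`, `corr_length` (cells),
#'   `mean`, `sd` describing one spatially autocorrelated field per driver.
#' @param beta Named vector of true lag effects, in years per standard
#'   deviation of the named driver field. Names must match `drivers$name`.
#' @param mean_lag Mean waiting time (years) from arrival to establishment.
#' @param level4_sd Standard deviation (years) of the level-IV eco-region
#'   random intercepts on the lag.
#' @param resid_sd Residual standard deviation (years) of the lag.
#' @param n_level2 Number of level-II subregions (>= 2).
#' @param n_level4 Level-IV units per subregion (>= 2).
#' @param plateau Latent founder abundance held between arrival and
#'   establishment (moths per trap at detection scale 1).
#' @param carrying_capacity Latent abundance reached after establishment.
#' @param growth_rate Logistic growth rate (per year) from the founder
#'   plateau toward carrying capacity once establishment occurs.
#' @param traps_front,traps_rear Traps per cell ahead of / behind the
#'   early invasion front (the monitoring network is denser at the front).
#' @param detection_scale Expected trap catch per unit latent abundance
#'   (k >= 0); the negative-binomial mean is `k * N`.
#' @param nb_size Negative-binomial dispersion (size); larger = less noise.
#' @param treat_frac Fraction of the area treated per year, in
#'   \[0, 0.02\].
#' @param treat_radius Treatment disc radius in meters.
#' @param seed Integer seed; all stage randomness derives from it.
#'
#' @return A list of class `wt_sim_config`.
#' @export
sim_config <- function(n_rows = 20, n_cols = 20, cell_size = 5000,
                       years = 1985:2015,
                       origin_cell = c(-6, -6), speed_km_yr = 6,
                       drivers = default_drivers(),
                       beta = c(winter_temp = -1.5, spring_tmax = 1,
                                anthro_frag = 0.8),
                       mean_lag = 7, level4_sd = 1, resid_sd = 1.5,
                       n_level2 = 3, n_level4 = 4,
                       plateau = 1, carrying_capacity = 100, growth_rate = 3,
                       traps_front = 3, traps_rear = 1,
                       detection_scale = 1, nb_size = 5,
                       treat_frac = 0.01, treat_radius = 2000,
                       seed = 1) {
  if (speed_km_yr <= 0) abort("`speed_km_yr` must be > 0")
  if (treat_frac < 0 || treat_frac > 0.02)
    abort("`treat_frac` must lie in [0, 0.02]")
  if (any(c(level4_sd, resid_sd, drivers$sd) < 0))
    abort("standard deviations must be >= 0")
  if (n_level2 < 2 || n_level4 < 2)
    abort("need >= 2 level-II subregions each containing >= 2 level-IV units")
  if (!all(names(beta) %in% drivers$name))
    abort("names of `beta` must match `drivers$name`")
  full_beta <- setNames(numeric(nrow(drivers)), drivers$name)
  full_beta[names(beta)] <- beta
  structure(list(
    n_rows = n_rows, n_cols = n_cols, cell_size = cell_size, years = years,
    origin_cell = origin_cell, speed_km_yr = speed_km_yr,
    drivers = drivers, beta = full_beta, mean_lag = mean_lag,
    level4_sd = level4_sd, resid_sd = resid_sd,
    n_level2 = n_level2, n_level4 = n_level4,
    plateau = plateau, carrying_capacity = carrying_capacity,
    growth_rate = growth_rate,
    traps_front = traps_front, traps_rear = traps_rear,
    detection_scale = detection_scale, nb_size = nb_size,
    treat_frac = treat_frac, treat_radius = treat_radius,
    seed = as.integer(seed)
  ), class = "wt_sim_config")
}

#' Default driver field specifications
#'
#' Ten driver fields mirroring the environmental and anthropogenic factors
#' used in the waiting-time regressions: seasonal climate, elevation, host
#' abundance, and human-footprint variables. `corr_length` is the Gaussian
#' correlation length in grid cells; `mean`/`sd` are marginal moments.
#'
#' @return A tibble with columns `name`, `corr_length`, `mean`, `sd`.
#' @export
default_drivers <- function() {
  tibble::tribble(
    ~name,              ~corr_length, ~mean, ~sd,
    "winter_temp",      4,            -4,    3,
    "spring_tmax",      4,            22,    2,
    "summer_precip",    4,            100,   25,
    "elevation",        5,            300,   150,
    "host_basal_area",  3,            10,    4,
    "pop_density",      2,            50,    40,
    "wood_use",         2,            200,   120,
    "highway_density",  2,            0.5,   0.3,
    "anthro_frag",      3,            0.2,   0.1,
    "natural_frag",     3,            0.3,   0.1
  )
}

# Stage-specific sub-seeds derived from the single config seed, so each
# stage can be regenerated independently and deterministically.
stage_seed <- function(seed, stage) {
  stages <- c("landscape", "invasion", "traps", "counts", "treatments")
  idx <- match(stage, stages)
  if (is.na(idx)) abort(paste0("unknown rng stage: ", stage))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, length(stages))[idx]
}

# Spatially autocorrelated Gaussian field: white noise smoothed with a
# separable Gaussian kernel (edge-renormalized), then standardized to the
# requested marginal mean/sd. corr_length 0 => i.i.d.; sd 0 => constant.
gaussian_field <- function(n_rows, n_cols, corr_length, mean, sd) {
  if (sd == 0) return(matrix(mean, n_rows, n_cols))
  f <- matrix(rnorm(n_rows * n_cols), n_rows, n_cols)
  if (corr_length > 0) {
    L <- ceiling(3 * corr_length)
    w <- exp(-(seq(-L, L))^2 / (2 * corr_length^2))
    smooth1 <- function(v) {
      n <- length(v)
      vapply(seq_len(n), function(i) {
        j <- max(1, i - L):min(n, i + L)
        wi <- w[j - i + L + 1]
        sum(wi * v[j]) / sum(wi)
      }, numeric(1))
    }
    f <- apply(f, 2, smooth1)
    f <- t(apply(f, 1, smooth1))
  }
  mean + sd * (f - base::mean(f)) / stats::sd(f)
}

#' Generate synthetic covariate fields and eco-region labels
#'
#' Produces one spatially autocorrelated Gaussian field per configured
#' driver, standardized to its stated marginal mean and sd, plus nested
#' eco-region labels (level-II subregions as vertical bands, each split into
#' level-IV units by rows) tiling the grid.
#'
#' @param config A [sim_config()].
#' @return A tibble (class `wt_landscape`) with one row per cell: `row`,
#'   `col` (0-based), cell-center `x`, `y` in meters, `level2`, `level4`,
#'   and one column per driver.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "wt_sim_config"))
  nr <- config$n_rows; nc <- config$n_cols
  if (nr < 3 || nc < 3)
    abort("grid extent must be at least 3 x 3 cells")
  set.seed(stage_seed(config$seed, "landscape"))
  cells <- tidyr::expand_grid(row = 0:(nr - 1), col = 0:(nc - 1))
  cells$x <- (cells$col + 0.5) * config$cell_size
  cells$y <- (cells$row + 0.5) * config$cell_size

  l2_names <- c("northern_mixed_wood_shield", "central_plains",
                "southeastern_forests_plains")
  if (config$n_level2 > 3)
    l2_names <- c(l2_names, paste0("region_", 4:config$n_level2))
  l2_names <- l2_names[seq_len(config$n_level2)]
  band <- pmin(floor(cells$col / (nc / config$n_level2)), config$n_level2 - 1)
  sub <- pmin(floor(cells$row / (nr / config$n_level4)), config$n_level4 - 1)
  cells$level2 <- l2_names[band + 1]
  cells$level4 <- paste0(cells$level2, "_", sub + 1)

  for (i in seq_len(nrow(config$drivers))) {
    d <- config$drivers[i, ]
    f <- gaussian_field(nr, nc, d$corr_length, d$mean, d$sd)
    cells[[d$name]] <- f[cbind(cells$row + 1, cells$col + 1)]
  }
  class(cells) <- c("wt_landscape", class(cells))
  cells
}

#' Simulate the invasion wave and per-cell establishment truth
#'
#' A kinematic wave assigns each cell an arrival year from its distance to
#' the wave origin; the waiting time (lag) from arrival to establishment is
#' `max(0, round(mean_lag + sum(beta * x) + level-IV intercept + noise))`
#' with `x` the standardized driver fields. Latent abundance is 0 before
#' arrival, a low founder plateau between arrival and establishment, then
#' grows logistically from the plateau to carrying capacity.
#'
#' @param landscape Output of [generate_landscape()].
#' @param config The same [sim_config()].
#' @return A list of class `wt_truth`: `cells` (per-cell arrival year,
#'   establishment year, waiting time), `abundance` (long tibble `row`,
#'   `col`, `year`, `abundance`), `beta` (true effects), `intercepts`
#'   (level-IV random intercepts).
#' @export
simulate_invasion <- function(landscape, config) {
  stopifnot(inherits(landscape, "wt_landscape"))
  set.seed(stage_seed(config$seed, "invasion"))
  y0 <- config$years[1]
  dist_km <- config$cell_size / 1000 *
    sqrt((landscape$row - config$origin_cell[1])^2 +
         (landscape$col - config$origin_cell[2])^2)
  arrival <- y0 + round(dist_km / config$speed_km_yr)

  x_std <- vapply(config$drivers$name, function(nm) {
    d <- config$drivers[config$drivers$name == nm, ]
    if (d$sd == 0) rep(0, nrow(landscape))
    else (landscape[[nm]] - d$mean) / d$sd
  }, numeric(nrow(landscape)))
  lin <- drop(x_std %*% config$beta)

  l4 <- sort(unique(landscape$level4))
  b4 <- setNames(rnorm(length(l4), 0, config$level4_sd), l4)
  noise <- rnorm(nrow(landscape), 0, config$resid_sd)
  lag <- pmax(0, round(config$mean_lag + lin + b4[landscape$level4] + noise))

  cells <- tibble::tibble(
    row = landscape$row, col = landscape$col,
    level2 = landscape$level2, level4 = landscape$level4,
    arrival_year = as.integer(arrival),
    establishment_year = as.integer(arrival + lag),
    waiting_time = as.integer(lag)
  )

  K <- config$carrying_capacity; P <- config$plateau; g <- config$growth_rate
  ab <- tidyr::expand_grid(
    cells[, c("row", "col", "arrival_year", "establishment_year")],
    year = config$years
  )
  since_est <- ab$year - ab$establishment_year + 1
  ab$abundance <- ifelse(
    ab$year < ab$arrival_year, 0,
    ifelse(ab$year < ab$establishment_year, P,
           K / (1 + (K - P) / P * exp(-g * since_est)))
  )
  truth <- list(
    cells = cells,
    abundance = ab[, c("row", "col", "year", "abundance")],
    beta = config$beta,
    intercepts = b4
  )
  class(truth) <- "wt_truth"
  truth
}

#' Simulate the trapping network, counts, and treatment events
#'
#' Lays out traps (denser ahead of the early invasion front, sparser in
#' long-invaded cells), draws yearly negative-binomial counts with mean
#' `detection_scale * abundance`, and places yearly treatment discs whose
#' total footprint stays within the configured area fraction.
#'
#' @param truth Output of [simulate_invasion()].
#' @param landscape Output of [generate_landscape()].
#' @param config The same [sim_config()].
#' @return A list with tibbles `traps` (`trap_id`, `x`, `y`, `year`,
#'   `count`) and `treatments` (`x`, `y`, `radius`, `year`).
#' @export
simulate_trapping <- function(truth, landscape, config) {
  stopifnot(inherits(truth, "wt_truth"))
  if (config$detection_scale < 0) abort("`detection_scale` must be >= 0")

  set.seed(stage_seed(config$seed, "traps"))
  early <- truth$cells$arrival_year <= config$years[1] + 5
  n_traps <- ifelse(early, config$traps_rear, config$traps_front)
  cs <- config$cell_size
  trap_cells <- truth$cells[rep(seq_len(nrow(truth$cells)), n_traps),
                            c("row", "col")]
  traps <- tibble::tibble(
    trap_id = sprintf("T%05d", seq_len(nrow(trap_cells))),
    row = trap_cells$row, col = trap_cells$col,
    x = (trap_cells$col + runif(nrow(trap_cells))) * cs,
    y = (trap_cells$row + runif(nrow(trap_cells))) * cs
  )

  set.seed(stage_seed(config$seed, "counts"))
  obs <- tidyr::expand_grid(traps, year = config$years)
  obs <- dplyr::left_join(obs, truth$abundance,
                          by = c("row", "col", "year"))
  mu <- config$detection_scale * obs$abundance
  obs$count <- as.integer(rnbinom(nrow(obs), size = config$nb_size, mu = mu))
  trap_tbl <- dplyr::arrange(
    obs[, c("trap_id", "x", "y", "year", "count")],
    .data$trap_id, .data$year
  )

  set.seed(stage_seed(config$seed, "treatments"))
  area_total <- config$n_rows * config$n_cols * (cs / 1000)^2
  disc_area <- pi * (config$treat_radius / 1000)^2
  n_discs <- floor(config$treat_frac * area_total / disc_area)
  if (n_discs > 0) {
    treat <- tidyr::expand_grid(year = config$years, disc = seq_len(n_discs))
    treat$x <- runif(nrow(treat), 0, config$n_cols * cs)
    treat$y <- runif(nrow(treat), 0, config$n_rows * cs)
    treat$radius <- config$treat_radius
    treatments <- treat[, c("x", "y", "radius", "year")]
  } else {
    treatments <- tibble::tibble(x = numeric(), y = numeric(),
                                 radius = numeric(), year = integer())
  }
  list(traps = trap_tbl, treatments = treatments)
}

#' Run all simulator stages from one configuration
#'
#' @param config A [sim_config()].
#' @return A list: `landscape`, `truth`, `traps`, `treatments`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  landscape <- generate_landscape(config)
  truth <- simulate_invasion(landscape, config)
  obs <- simulate_trapping(truth, landscape, config)
  list(landscape = landscape, truth = truth,
       traps = obs$traps, treatments = obs$treatments)
}
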