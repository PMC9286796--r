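#' Pipeline configuration
#'
#' Collects every constant of the end-to-end analysis in one auditable
#' object: the simulator settings, grid, MCMC settings, filter thresholds
#' (treatment buffer 1500 m, low-catch total 10, detection median 1,
#' establishment alpha 0.01, calibration 10 years), the regression
#' candidate set, output directory, and the global seed. Can be written
#' to / read from YAML.
#'
#' @param stages Stages to run, in order, a subset of
#'   `c("simulate", "grid", "establish", "assemble", "regress")`.
#' @param sim A [sim_config()] (used by the `simulate` stage and to derive
#'   the default grid).
#' @param mcmc A [mcmc_config()].
#' @param treatment_radius Trap exclusion buffer, meters.
#' @param low_catch Minimum total catch for inclusion.
#' @param detection_threshold Detection threshold on the yearly median.
#' @param alpha Establishment threshold on the probability of zero.
#' @param calibration Calibration years before the first target year.
#' @param drivers Candidate drivers for the regression (default: all
#'   simulated drivers).
#' @param subregion Optional level-II subregion to restrict the regression
#'   to (default `NULL`: range-wide).
#' @param inputs Optional named list of input paths (`traps`,
#'   `treatments`, `covariates`, `ecoregions`) used when the `simulate`
#'   stage is disabled.
#' @param outdir Output directory (`NULL`: keep everything in memory).
#' @param seed Global seed; overrides `sim$seed` and `mcmc$seed`.
#' @return A list of class `wt_pipeline_config`.
#' @export
pipeline_config <- function(stages = c("simulate", "grid", "establish",
                                       "assemble", "regress"),
                            sim = sim_config(), mcmc = mcmc_config(),
                            treatment_radius = 1500, low_catch = 10,
                            detection_threshold = 1, alpha = 0.01,
                            calibration = 10,
                            drivers = NULL, subregion = NULL,
                            inputs = NULL, outdir = NULL, seed = 1) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (any(c(treatment_radius, low_catch, detection_threshold, alpha,
            calibration) <= 0))
    abort("all thresholds must be positive")
  sim$seed <- as.integer(seed)
  mcmc$seed <- as.integer(seed)
  structure(list(
    stages = stages, sim = sim, mcmc = mcmc,
    treatment_radius = treatment_radius, low_catch = low_catch,
    detection_threshold = detection_threshold, alpha = alpha,
    calibration = calibration,
    drivers = drivers %||% sim$drivers$name,
    subregion = subregion, inputs = inputs, outdir = outdir,
    seed = as.integer(seed)
  ), class = "wt_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level YAML keys mirror the arguments of [pipeline_config()];
#' `sim:` and `mcmc:` sub-maps override the corresponding defaults.
#'
#' @param path YAML file path.
#' @return A `wt_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- do.call(sim_config, y$sim %||% list())
  mcmc <- do.call(mcmc_config, y$mcmc %||% list())
  args <- y[setdiff(names(y), c("sim", "mcmc"))]
  do.call(pipeline_config, c(list(sim = sim, mcmc = mcmc), args))
}

#' Run the end-to-end waiting-time pipeline
#'
#' Executes the enabled stages in order — simulate the dataset, grid the
#' trap records into quadrat median series, estimate per-quadrat
#' establishment years, assemble the regression table, and run the
#' all-subsets AIC regression — writing stage outputs as delimited text
#' (and treatments as GeoJSON) when `outdir` is set, plus a JSON manifest
#' of seeds, row counts and runtimes. Identical config and seed reproduce
#' identical outputs.
#'
#' @param config A [pipeline_config()] or path to a YAML file.
#' @return A list of class `wt_run`: the stage results plus `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "wt_pipeline_config"))
  outdir <- config$outdir
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  res <- list()
  manifest <- list(package = "waitest",
                   version = as.character(utils::packageVersion("waitest")),
                   r_version = R.version.string,
                   seed = config$seed, stages = config$stages,
                   counts = list(), runtime_s = list())
  t_all <- proc.time()[3]

  run_stage <- function(name, fn) {
    t0 <- proc.time()[3]
    out <- tryCatch(fn(), error = function(e)
      abort(paste0("stage `", name, "` failed: ", conditionMessage(e))))
    manifest$runtime_s[[name]] <<- round(proc.time()[3] - t0, 2)
    out
  }

  grid <- grid_spec(origin = c(0, 0), cell_size = config$sim$cell_size,
                    n_rows = config$sim$n_rows, n_cols = config$sim$n_cols)

  if ("simulate" %in% config$stages) {
    res$sim <- run_stage("simulate", function() simulate_dataset(config$sim))
    manifest$counts$traps <- nrow(res$sim$traps)
    manifest$counts$treatments <- nrow(res$sim$treatments)
    if (!is.null(outdir)) {
      write_trap_records(res$sim$traps, file.path(outdir, "traps.csv"))
      write_treatments(res$sim$treatments,
                       file.path(outdir, "treatments.geojson"))
      readr::write_csv(res$sim$landscape, file.path(outdir, "landscape.csv"))
      readr::write_csv(res$sim$truth$cells, file.path(outdir, "truth.csv"))
    }
  }

  if ("grid" %in% config$stages) {
    res$series <- run_stage("grid", function() {
      traps <- res$sim$traps %||% read_trap_records(config$inputs$traps)
      treatments <- res$sim$treatments %||%
        (if (!is.null(config$inputs$treatments))
           read_treatments(config$inputs$treatments) else NULL)
      kept <- exclude_treated(traps, treatments, config$treatment_radius)
      median_series(assign_quadrats(kept, grid))
    })
    res$statuses <- apply_inclusion_filters(
      res$series, config$low_catch,
      detection_threshold = config$detection_threshold)
    manifest$counts$quadrats <- nrow(res$statuses)
    manifest$counts$eligible <- sum(res$statuses$status == "ELIGIBLE")
    if (!is.null(outdir)) {
      readr::write_csv(res$series, file.path(outdir, "quadrat_series.csv"))
      readr::write_csv(res$statuses, file.path(outdir, "inclusion.csv"))
    }
  }

  if ("establish" %in% config$stages) {
    res$establishment <- run_stage("establish", function()
      establish_quadrats(res$series, res$statuses, config$mcmc,
                         alpha = config$alpha,
                         calibration = config$calibration))
    manifest$counts$included <-
      sum(res$establishment$status == "INCLUDED")
    if (!is.null(outdir)) {
      flat <- res$establishment[, c("row", "col", "detection_year",
                                    "establishment_year", "waiting_time",
                                    "status")]
      readr::write_csv(flat, file.path(outdir, "establishment.csv"))
      pz <- tidyr::unnest(res$establishment[, c("row", "col", "prob_zero")],
                          "prob_zero")
      readr::write_csv(pz, file.path(outdir, "prob_zero.csv"))
    }
  }

  if ("assemble" %in% config$stages) {
    res$analysis <- run_stage("assemble", function() {
      if (!is.null(res$sim)) {
        covs <- res$sim$landscape[, c("row", "col", config$sim$drivers$name)]
        labels <- res$sim$landscape[, c("row", "col", "level2", "level4")]
      } else {
        covs <- readr::read_csv(config$inputs$covariates,
                                show_col_types = FALSE)
        labels <- read_ecoregions(config$inputs$ecoregions)
      }
      assemble_table(res$establishment, covs, labels)
    })
    manifest$counts$analysis_rows <- nrow(res$analysis)
    if (!is.null(outdir))
      readr::write_csv(res$analysis, file.path(outdir, "analysis_table.csv"))
  }

  if ("regress" %in% config$stages) {
    res$regression <- run_stage("regress", function() {
      tab <- res$analysis
      if (!is.null(config$subregion))
        tab <- tab[tab$level2 == config$subregion, , drop = FALSE]
      all_subsets_aic(tab, config$drivers)
    })
    manifest$counts$models <- nrow(res$regression$models)
    if (!is.null(outdir)) {
      readr::write_csv(res$regression$models,
                       file.path(outdir, "model_selection.csv"))
      readr::write_csv(tidy(res$regression$best),
                       file.path(outdir, "coefficients.csv"))
      readr::write_csv(glance(res$regression$best),
                       file.path(outdir, "fit_summary.csv"))
    }
  }

  manifest$runtime_s$total <- round(proc.time()[3] - t_all, 2)
  res$manifest <- manifest
  if (!is.null(outdir))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  class(res) <- "wt_run"
  res
}

#' @export
print.wt_run <- function(x, ...) {
  cat("waitest pipeline run (seed", x$manifest$seed, ")\n")
  for (nm in names(x$manifest$counts))
    cat(sprintf("  %-14s %d\n", nm, x$manifest$counts[[nm]]))
  invisible(x)
}

#' Summary statistics of waiting times
#'
#' Mean, median, quartiles and counts of the waiting time to
#' establishment, overall and per level-II subregion.
#'
#' @param records A [establish_quadrats()] result (INCLUDED rows are
#'   used).
#' @param labels Optional tibble `row`, `col`, `level2` for the subregion
#'   breakdown.
#' @return A tibble with one row per subregion plus an overall row.
#' @export
summarize_waiting_times <- function(records, labels = NULL) {
  inc <- records[records$status == "INCLUDED" &
                   !is.na(records$waiting_time), ]
  if (nrow(inc) == 0) abort("no included quadrats to summarize")
  stats_of <- function(w, label) {
    tibble::tibble(subregion = label, n = length(w), mean = mean(w),
                   median = stats::median(w),
                   q25 = quantile(w, 0.25), q75 = quantile(w, 0.75))
  }
  out <- stats_of(inc$waiting_time, "overall")
  if (!is.null(labels)) {
    inc2 <- dplyr::inner_join(inc[, c("row", "col", "waiting_time")],
                              labels[, c("row", "col", "level2")],
                              by = c("row", "col"))
    subs <- unique(labels$level2)
    for (s in subs) {
      w <- inc2$waiting_time[inc2$level2 == s]
      if (length(w) == 0) {
        inform(paste0("subregion `", s, "` has no included quadrats; omitted"))
        next
      }
      out <- dplyr::bind_rows(out, stats_of(w, s))
    }
  }
  out
}
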