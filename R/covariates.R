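#' Per-quadrat mean of a gridded covariate layer
#'
#' Arithmetic mean of all layer cells whose centers fall inside each
#' quadrat (half-open cells, matching [assign_quadrats()]); missing cell
#' values are excluded from the mean. Quadrats overlapped by no cell are
#' reported missing with a message.
#'
#' @param layer Tibble `x`, `y`, `value`: cell-center coordinates (meters)
#'   and the layer value.
#' @param grid A [grid_spec()].
#' @return A tibble `row`, `col`, `mean` for every quadrat in the grid.
#' @export
quadrat_covariate_means <- function(layer, grid) {
  stopifnot(inherits(grid, "wt_grid"))
  pts <- assign_quadrats(layer, grid)
  means <- pts |>
    dplyr::group_by(.data$row, .data$col) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     .groups = "drop")
  full <- tidyr::expand_grid(row = 0:(grid$n_rows - 1),
                             col = 0:(grid$n_cols - 1))
  out <- dplyr::left_join(full, means, by = c("row", "col"))
  out$mean[is.nan(out$mean)] <- NA_real_
  n_empty <- sum(is.na(out$mean))
  if (n_empty > 0)
    inform(paste0(n_empty, " quadrat(s) overlap no layer cells; mean set missing"))
  out
}

#' Multi-year average of annual covariate layers
#'
#' Per-cell arithmetic mean across a stack of annual layers on a common
#' grid (e.g. a 20-year climate average over the establishment window).
#'
#' @param layers A list of tibbles `x`, `y`, `value`, one per year, all on
#'   the same cell centers.
#' @return A single layer tibble `x`, `y`, `value`.
#' @export
climate_average <- function(layers) {
  if (length(layers) < 2) abort("need at least 2 annual layers")
  key0 <- paste(layers[[1]]$x, layers[[1]]$y)
  for (l in layers[-1]) {
    if (nrow(l) != length(key0) || !all(paste(l$x, l$y) == key0))
      abort("annual layers are not on a common grid")
  }
  vals <- rowMeans(vapply(layers, function(l) l$value,
                          numeric(nrow(layers[[1]]))))
  tibble::tibble(x = layers[[1]]$x, y = layers[[1]]$y, value = vals)
}

#' Neighborhood mean waiting time
#'
#' For each quadrat, the mean waiting time over the surrounding 3 x 3
#' neighborhood (the up-to-8 adjacent quadrats; the focal quadrat is
#' excluded by default). Neighbors with no waiting time are ignored; the
#' result is missing when no neighbor has one.
#'
#' @param records Tibble with `row`, `col`, `waiting_time` (`NA` allowed).
#' @param include_focal Include the focal quadrat in the average
#'   (default `FALSE`).
#' @return `records` with a `neighborhood_wait` column added.
#' @export
neighborhood_mean_waiting <- function(records, include_focal = FALSE) {
  offsets <- tidyr::expand_grid(dr = -1:1, dc = -1:1)
  if (!include_focal) offsets <- offsets[!(offsets$dr == 0 & offsets$dc == 0), ]
  w <- records[!is.na(records$waiting_time),
               c("row", "col", "waiting_time")]
  nb <- tidyr::expand_grid(records[, c("row", "col")], offsets) |>
    dplyr::mutate(nrow_ = .data$row + .data$dr, ncol_ = .data$col + .data$dc) |>
    dplyr::left_join(w, by = c(nrow_ = "row", ncol_ = "col")) |>
    dplyr::group_by(.data$row, .data$col) |>
    dplyr::summarise(
      neighborhood_wait = if (all(is.na(.data$waiting_time))) NA_real_
                          else mean(.data$waiting_time, na.rm = TRUE),
      .groups = "drop")
  dplyr::left_join(records, nb, by = c("row", "col"))
}

#' Assemble the regression analysis table
#'
#' Joins establishment records (restricted to `INCLUDED` quadrats) with
#' per-quadrat driver means and eco-region labels, and adds the two
#' background variables: year of first detection and the 3 x 3
#' neighborhood mean waiting time (computed over all quadrats with a
#' waiting time, before restriction). Rows with any missing field are
#' dropped with a message.
#'
#' @param records A [establish_quadrats()] result (or any tibble with
#'   `row`, `col`, `status`, `detection_year`, `waiting_time`).
#' @param covariates Tibble `row`, `col` plus one column per driver.
#' @param labels Tibble `row`, `col`, `level2`, `level4`.
#' @param include_focal Passed to [neighborhood_mean_waiting()].
#' @return A tibble of class `wt_analysis` with attribute `drivers`; one
#'   row per included, complete quadrat.
#' @export
assemble_table <- function(records, covariates, labels,
                           include_focal = FALSE) {
  for (nm in c("records", "covariates", "labels")) {
    d <- get(nm)
    if (anyDuplicated(d[, c("row", "col")]) > 0)
      abort(paste0("duplicate quadrat keys in `", nm, "`"))
  }
  drivers <- setdiff(names(covariates), c("row", "col", "x", "y"))
  nbw <- neighborhood_mean_waiting(
    records[, c("row", "col", "waiting_time")], include_focal)
  tab <- records[records$status == "INCLUDED",
                 c("row", "col", "detection_year", "establishment_year",
                   "waiting_time")] |>
    dplyr::inner_join(nbw[, c("row", "col", "neighborhood_wait")],
                      by = c("row", "col")) |>
    dplyr::inner_join(covariates[, c("row", "col", drivers)],
                      by = c("row", "col")) |>
    dplyr::inner_join(labels[, c("row", "col", "level2", "level4")],
                      by = c("row", "col"))
  complete <- stats::complete.cases(
    tab[, c("waiting_time", "detection_year", "neighborhood_wait", drivers,
            "level2", "level4")])
  if (any(!complete))
    inform(paste0("dropped ", sum(!complete),
                  " quadrat(s) with missing fields from the analysis table"))
  out <- tab[complete, , drop = FALSE]
  attr(out, "drivers") <- drivers
  class(out) <- c("wt_analysis", class(out))
  out
}
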