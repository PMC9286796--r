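#' Quadrat grid specification
#'
#' Defines the grid used to aggregate trap catches: half-open square cells
#' `[edge, edge + size)` in both axes, indexed by 0-based `(row, col)`.
#'
#' @param origin `c(x0, y0)` of the grid's lower-left corner, meters.
#' @param cell_size Cell edge length in meters (default 5000: 5 x 5 km).
#' @param n_rows,n_cols Grid extent.
#' @return A list of class `wt_grid`.
#' @export
grid_spec <- function(origin = c(0, 0), cell_size = 5000,
                      n_rows, n_cols) {
  if (cell_size <= 0) abort("`cell_size` must be > 0")
  structure(list(origin = origin, cell_size = cell_size,
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols)),
            class = "wt_grid")
}

#' Drop trap-years near treated areas
#'
#' Removes trap-year records whose location lies strictly within `radius`
#' meters of any treatment footprint active in the same year; records of the
#' same trap in other years are retained. A treatment is a disc (`x`, `y`,
#' `radius`, `year`); the distance used is the distance to the disc edge.
#' A trap exactly `radius` meters from the footprint is kept.
#'
#' @param traps Tibble `trap_id`, `x`, `y`, `year`, `count`.
#' @param treatments Tibble `x`, `y`, `radius`, `year` (planar meters,
#'   same frame as the traps).
#' @param radius Exclusion buffer in meters (default 1500).
#' @return The surviving trap records, same columns.
#' @export
exclude_treated <- function(traps, treatments, radius = 1500) {
  if (radius < 0) abort("`radius` must be >= 0")
  if (is.null(treatments) || nrow(treatments) == 0) return(traps)
  drop <- rep(FALSE, nrow(traps))
  for (i in seq_len(nrow(treatments))) {
    tr <- treatments[i, ]
    same_year <- traps$year == tr$year
    d_edge <- sqrt((traps$x - tr$x)^2 + (traps$y - tr$y)^2) - tr$radius
    drop <- drop | (same_year & pmax(d_edge, 0) < radius)
  }
  traps[!drop, , drop = FALSE]
}

#' Assign traps to grid quadrats
#'
#' `col = floor((x - x0) / size)`, `row = floor((y - y0) / size)`; cells are
#' half-open, so a trap exactly on an interior edge belongs to the
#' higher-index cell. Traps outside the grid extent are dropped with a
#' message stating how many.
#'
#' @param traps Tibble with `x`, `y` in meters.
#' @param grid A [grid_spec()].
#' @return `traps` with integer `row`, `col` columns added.
#' @export
assign_quadrats <- function(traps, grid) {
  stopifnot(inherits(grid, "wt_grid"))
  col <- floor((traps$x - grid$origin[1]) / grid$cell_size)
  row <- floor((traps$y - grid$origin[2]) / grid$cell_size)
  inside <- row >= 0 & row < grid$n_rows & col >= 0 & col < grid$n_cols
  if (any(!inside))
    inform(paste0("dropped ", sum(!inside), " trap record(s) outside the grid extent"))
  out <- traps[inside, , drop = FALSE]
  out$row <- as.integer(row[inside])
  out$col <- as.integer(col[inside])
  out
}

#' Per-quadrat yearly median catch series
#'
#' For every quadrat-year with at least one reporting trap, the sample
#' median of the trap counts (even counts of traps average the two middle
#' values); years with no traps are absent from the output. The total raw
#' catch per quadrat (sum of all counts over all traps and years) is
#' carried along for the low-catch inclusion filter.
#'
#' @param traps Trap records annotated with `row`, `col` (see
#'   [assign_quadrats()]).
#' @param grid Optional [grid_spec()]; if supplied and `traps` lack
#'   `row`/`col`, they are assigned first.
#' @return A tibble `row`, `col`, `year`, `median`, `n_traps`,
#'   `total_catch` (per-quadrat constant), one row per observed
#'   quadrat-year.
#' @export
median_series <- function(traps, grid = NULL) {
  if (!all(c("row", "col") %in% names(traps))) {
    if (is.null(grid)) abort("traps lack `row`/`col`; supply `grid`")
    traps <- assign_quadrats(traps, grid)
  }
  out <- traps |>
    dplyr::group_by(.data$row, .data$col, .data$year) |>
    dplyr::summarise(median = stats::median(.data$count),
                     n_traps = dplyr::n(), .groups = "drop_last") |>
    dplyr::ungroup()
  totals <- traps |>
    dplyr::group_by(.data$row, .data$col) |>
    dplyr::summarise(total_catch = sum(.data$count), .groups = "drop")
  dplyr::left_join(out, totals, by = c("row", "col")) |>
    dplyr::arrange(.data$row, .data$col, .data$year)
}

#' First detection year per quadrat
#'
#' The earliest year whose (non-missing) median catch reaches the detection
#' threshold (default: a median of at least one moth); `NA` if no such year.
#'
#' @param series Output of [median_series()].
#' @param threshold Detection threshold on the yearly median (default 1).
#' @return A tibble `row`, `col`, `detection_year`.
#' @export
first_detection_year <- function(series, threshold = 1) {
  series |>
    dplyr::group_by(.data$row, .data$col) |>
    dplyr::summarise(
      detection_year = if (any(!is.na(.data$median) & .data$median >= threshold))
        min(.data$year[!is.na(.data$median) & .data$median >= threshold])
      else NA_integer_,
      .groups = "drop")
}

#' Provisional inclusion filtering of quadrats
#'
#' Applies the two a-priori exclusions, in this order: quadrats with fewer
#' than `low_catch` moths caught in total across all traps and years
#' (`EXCLUDED_LOW_CATCH`), then quadrats whose first recorded yearly median
#' is greater than zero, i.e. likely already established when trapping
#' began (`EXCLUDED_PRE_ESTABLISHED`). Remaining quadrats are `ELIGIBLE`;
#' the establishment stage later resolves them to `INCLUDED` or
#' `EXCLUDED_NEVER_ESTABLISHED`.
#'
#' @param series Output of [median_series()].
#' @param low_catch Minimum total catch (default 10).
#' @param use_medians If `TRUE`, the low-catch total sums yearly medians
#'   instead of raw counts (default `FALSE`: raw counts).
#' @param detection_threshold Passed to [first_detection_year()].
#' @return A tibble `row`, `col`, `status`, `detection_year`, `total_catch`.
#' @export
apply_inclusion_filters <- function(series, low_catch = 10,
                                    use_medians = FALSE,
                                    detection_threshold = 1) {
  first_recorded <- function(m, y) {
    ok <- !is.na(m)
    if (!any(ok)) NA_real_ else m[ok][which.min(y[ok])]
  }
  totals <- series |>
    dplyr::group_by(.data$row, .data$col) |>
    dplyr::summarise(
      total_catch = if (use_medians) sum(.data$median, na.rm = TRUE)
                    else .data$total_catch[1],
      first_median = first_recorded(.data$median, .data$year),
      .groups = "drop")
  det <- first_detection_year(series, detection_threshold)
  out <- dplyr::left_join(totals, det, by = c("row", "col"))
  out$status <- dplyr::case_when(
    out$total_catch < low_catch ~ "EXCLUDED_LOW_CATCH",
    !is.na(out$first_median) & out$first_median > 0 ~ "EXCLUDED_PRE_ESTABLISHED",
    TRUE ~ "ELIGIBLE"
  )
  out[, c("row", "col", "status", "detection_year", "total_catch")]
}
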