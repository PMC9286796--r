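#' Read and write the package's delimited-text interchange formats
#'
#' Trap records are CSV with header `trap_id,x,y,year,count`; quadrat
#' series are long CSV `row,col,year,median,n_traps,total_catch`;
#' covariate layers are CSV `x,y,value`; eco-region labels are CSV
#' `row,col,level2,level4`. Treatments are GeoJSON point features with
#' `radius_m` and `year` properties (discs). All coordinates are planar
#' meters.
#'
#' @param path File path.
#' @param x Object to write.
#' @return Readers return tibbles; writers return `x` invisibly.
#' @name waitest-io
NULL

#' @rdname waitest-io
#' @export
read_trap_records <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    trap_id = readr::col_character(), x = readr::col_double(),
    y = readr::col_double(), year = readr::col_integer(),
    count = readr::col_integer()))
}

#' @rdname waitest-io
#' @export
write_trap_records <- function(x, path) {
  readr::write_csv(x[, c("trap_id", "x", "y", "year", "count")], path)
  invisible(x)
}

#' @rdname waitest-io
#' @export
read_treatments <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  tibble::tibble(
    x = vapply(feats, function(f) f$geometry$coordinates[[1]], numeric(1)),
    y = vapply(feats, function(f) f$geometry$coordinates[[2]], numeric(1)),
    radius = vapply(feats, function(f) f$properties$radius_m, numeric(1)),
    year = vapply(feats, function(f) as.integer(f$properties$year),
                  integer(1))
  )
}

#' @rdname waitest-io
#' @export
write_treatments <- function(x, path) {
  feats <- purrr::pmap(x, function(x, y, radius, year, ...) {
    list(type = "Feature",
         geometry = list(type = "Point", coordinates = c(x, y)),
         properties = list(radius_m = radius, year = year))
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats), path,
    auto_unbox = TRUE, digits = NA)
  invisible(x)
}

#' @rdname waitest-io
#' @export
read_covariate_grid <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    x = readr::col_double(), y = readr::col_double(),
    value = readr::col_double()))
}

#' @rdname waitest-io
#' @export
write_covariate_grid <- function(x, path) {
  readr::write_csv(x[, c("x", "y", "value")], path)
  invisible(x)
}

#' @rdname waitest-io
#' @export
read_ecoregions <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    row = readr::col_integer(), col = readr::col_integer(),
    level2 = readr::col_character(), level4 = readr::col_character()))
}

#' @rdname waitest-io
#' @export
read_quadrat_series <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    row = readr::col_integer(), col = readr::col_integer(),
    year = readr::col_integer(), median = readr::col_double(),
    n_traps = readr::col_integer(), total_catch = readr::col_double()))
}
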