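#' Plot probability-of-zero trajectories
#'
#' One line per quadrat: the yearly posterior probability that the median
#' trap catch is zero, with the establishment threshold marked. Quadrats
#' cross below the dashed line in their establishment year.
#'
#' @param object A [establish_quadrats()] result.
#' @param alpha Threshold line (default 0.01).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wt_establishment <- function(object, alpha = 0.01, ...) {
  pz <- tidyr::unnest(
    dplyr::mutate(object[, c("row", "col", "prob_zero")],
                  quadrat = paste0(.data$row, ":", .data$col)),
    "prob_zero")
  ggplot2::ggplot(pz, ggplot2::aes(.data$year, .data$p,
                                   group = .data$quadrat)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::geom_hline(yintercept = alpha, linetype = "dashed") +
    ggplot2::labs(x = "Year", y = "Posterior P(median catch = 0)") +
    ggplot2::theme_minimal()
}

#' Boxplot of waiting times by subregion
#'
#' @param records A [establish_quadrats()] result.
#' @param labels Tibble `row`, `col`, `level2`; omit for an overall box.
#' @return A ggplot object.
#' @export
plot_waiting_times <- function(records, labels = NULL) {
  inc <- records[records$status == "INCLUDED", ]
  if (!is.null(labels)) {
    inc <- dplyr::inner_join(inc, labels[, c("row", "col", "level2")],
                             by = c("row", "col"))
  } else {
    inc$level2 <- "overall"
  }
  ggplot2::ggplot(inc, ggplot2::aes(.data$level2, .data$waiting_time)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "Waiting time to establishment (yr)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20,
                                                       hjust = 1))
}

#' Map of waiting times on the quadrat grid
#'
#' @param records A [establish_quadrats()] result.
#' @return A ggplot object (tiles colored by waiting time; excluded
#'   quadrats in grey).
#' @export
plot_waiting_map <- function(records) {
  ggplot2::ggplot(records, ggplot2::aes(.data$col, .data$row,
                                        fill = .data$waiting_time)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey80",
                                  name = "Waiting time (yr)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Column", y = "Row") +
    ggplot2::theme_minimal()
}

#' Coefficient dot-whisker plot for a fitted mixed model
#'
#' Standardized fixed-effect estimates with +-1 SE whiskers, drivers and
#' background variables on a common axis.
#'
#' @param object A `wt_lmm` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wt_lmm <- function(object, ...) {
  co <- tidy(object)
  co <- co[co$term != "(Intercept)", ]
  ggplot2::ggplot(co, ggplot2::aes(.data$estimate,
                                   stats::reorder(.data$term,
                                                  abs(.data$estimate)))) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$estimate - .data$std.error,
                   xmax = .data$estimate + .data$std.error),
      height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Standardized coefficient (yr per SD)", y = NULL) +
    ggplot2::theme_minimal()
}
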