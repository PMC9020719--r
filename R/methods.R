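#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a spatial-lag fit
#'
#' @param x A `lucc_slm`.
#' @param ... Unused.
#' @return A tibble `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, including the `rho` row.
#' @method tidy lucc_slm
#' @export
tidy.lucc_slm <- function(x, ...) {
  est <- c(x$coefficients, rho = x$rho)
  se <- x$std_errors[names(est)]
  tibble::tibble(term = names(est), estimate = unname(est),
                 std.error = unname(se),
                 statistic = unname(est / se),
                 p.value = unname(x$p_values[names(est)]))
}

#' Glance at a spatial-lag fit
#'
#' @param x A `lucc_slm`.
#' @param ... Unused.
#' @return A one-row tibble with `pseudo.r.squared`, `rho`, `sigma2`,
#'   `logLik`, `AIC`, `nobs`, `df`, and the model-selection flags.
#' @method glance lucc_slm
#' @export
glance.lucc_slm <- function(x, ...) {
  tibble::tibble(pseudo.r.squared = x$pseudo_r2, rho = x$rho,
                 sigma2 = x$sigma2, logLik = x$loglik, AIC = x$aic,
                 nobs = x$n, df = x$k,
                 meets_p_filter = x$meets_p_filter, meets_r2 = x$meets_r2)
}

#' Glance at a scenario run
#'
#' @param x A `lucc_run`.
#' @param ... Unused.
#' @return One row per class with the start/end areas, signed change and
#'   trend direction.
#' @method glance lucc_run
#' @export
glance.lucc_run <- function(x, ...) run_directions(x)

grid_long <- function(grid, columns) {
  tidyr::pivot_longer(
    dplyr::filter(tibble::as_tibble(grid), .data$valid),
    dplyr::all_of(columns), names_to = "field", values_to = "value")
}

#' Map the class fractions of a grid
#'
#' @param object A [lucc_grid()].
#' @param classes Columns to draw (default: dynamic classes).
#' @param ... Unused.
#' @return A ggplot: one facet per class, fill = percent of cell.
#' @method autoplot lucc_grid
#' @export
autoplot.lucc_grid <- function(object, classes = NULL, ...) {
  classes <- classes %||% grid_meta(object)$classes
  grid_long(object, classes) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$col, y = -.data$row,
                                 fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~field) +
    ggplot2::scale_fill_viridis_c(name = "% of cell", limits = c(0, 100)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Land-use fractions, %d",
                                  grid_meta(object)$year)) +
    ggplot2::theme_minimal()
}

#' Plot a demand table
#'
#' @param series A tibble from [demand_series()].
#' @return A ggplot of annual target areas per class.
#' @export
plot_demand <- function(series) {
  ggplot2::ggplot(series, ggplot2::aes(x = .data$year, y = .data$area_km2,
                                       colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "year", y = "target area (km²)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the similarity-by-window profile of a validation report
#'
#' @param report A `lucc_validation` from [validate_maps()].
#' @return A ggplot of NS against window size per class.
#' @export
plot_similarity <- function(report) {
  ggplot2::ggplot(report$similarity,
                  ggplot2::aes(x = .data$window, y = .data$ns,
                               colour = .data$class)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_continuous(trans = "log2") +
    ggplot2::labs(x = "window size (cells)", y = "similarity NS (%)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
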