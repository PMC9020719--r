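#' Demand endpoints for a land-use class
#'
#' A demand endpoint states the national area of one class at the first and
#' last year of the simulated period; the demand component interpolates
#' between them linearly, one step per year.
#'
#' @param class Land-use class id.
#' @param initial_year,final_year Period bounds (`final_year > initial_year`).
#' @param initial_area_km2,final_area_km2 National areas in km2 (>= 0).
#' @return A one-row tibble with the endpoint columns; bind rows to build a
#'   full endpoint table.
#' @export
#' @examples
#' demand_endpoint("forestry", 2000, 2050, 55983, 26881)
demand_endpoint <- function(class, initial_year, final_year,
                            initial_area_km2, final_area_km2) {
  ep <- tibble::tibble(class = class,
                       initial_year = as.integer(initial_year),
                       final_year = as.integer(final_year),
                       initial_area_km2 = as.numeric(initial_area_km2),
                       final_area_km2 = as.numeric(final_area_km2))
  check_endpoints(ep)
  ep
}

check_endpoints <- function(endpoints) {
  req <- c("class", "initial_year", "final_year",
           "initial_area_km2", "final_area_km2")
  if (!all(req %in% names(endpoints))) {
    stop_config(sprintf("endpoint table must have columns: %s",
                        paste(req, collapse = ", ")))
  }
  if (any(endpoints$final_year <= endpoints$initial_year)) {
    stop_config("final_year must exceed initial_year for every endpoint")
  }
  if (any(endpoints$initial_area_km2 < 0 | endpoints$final_area_km2 < 0)) {
    stop_config("endpoint areas must be non-negative")
  }
  invisible(endpoints)
}

#' Annual change in area implied by a demand endpoint
#'
#' The yearly increment `C_ca = (L(t_f) - L(t_i)) / n_t`, where `n_t` is the
#' number of years in the period. The sign carries the direction of change.
#'
#' @param endpoints An endpoint table (see [demand_endpoint()]).
#' @return The table with an `annual_change_km2` column appended.
#' @export
annual_change <- function(endpoints) {
  check_endpoints(endpoints)
  dplyr::mutate(tibble::as_tibble(endpoints),
    annual_change_km2 = (.data$final_area_km2 - .data$initial_area_km2) /
      (.data$final_year - .data$initial_year))
}

#' Annual demand series from endpoints
#'
#' Builds the per-class annual target areas by the recursion
#' `D(t_k) = D(t_k-1) + C_ca`, starting from the observed initial area, so
#' that `D(t_i)` equals the initial endpoint exactly and `D(t_f)` closes on
#' the final endpoint to floating-point accuracy.
#'
#' @param endpoints An endpoint table, one row per class.
#' @return A tibble `class`, `year`, `area_km2` covering every year of each
#'   class's period.
#' @export
#' @examples
#' eps <- scenario_endpoints("ssp1")
#' dplyr::filter(demand_series(eps), year == 2050)
demand_series <- function(endpoints) {
  endpoints <- annual_change(endpoints)
  purrr::pmap_dfr(endpoints, function(class, initial_year, final_year,
                                      initial_area_km2, final_area_km2,
                                      annual_change_km2, ...) {
    years <- initial_year:final_year
    area <- purrr::accumulate(years[-1], function(prev, yr) prev + annual_change_km2,
                              .init = initial_area_km2)
    tibble::tibble(class = class, year = years, area_km2 = area)
  })
}

#' Published scenario demand endpoints (2000--2050)
#'
#' National area endpoints for the six dynamic classes under the three
#' regionalised scenarios: `"ssp1"` (sustainable development, SSP1/RCP1.9),
#' `"ssp2"` (middle of the road, SSP2/RCP4.5) and `"ssp3"` (strong
#' inequality, SSP3/RCP7.0). 2000 areas are the observed national totals;
#' 2050 areas are the scenario targets downscaled from the global
#' integrated-assessment projections.
#'
#' @param scenario One of `"ssp1"`, `"ssp2"`, `"ssp3"`.
#' @return An endpoint table (see [demand_endpoint()]), one row per class.
#' @export
scenario_endpoints <- function(scenario = c("ssp1", "ssp2", "ssp3")) {
  scenario <- match.arg(scenario)
  initial <- c(forest_vegetation = 3771677, grassland_vegetation = 2112947,
               planted_pasture = 402529, agriculture = 624941,
               mosaic_of_occupation = 1405301, forestry = 55983)
  final <- switch(scenario,
    ssp1 = c(4232402, 1517633, 445974, 328444, 1822044, 26881),
    ssp2 = c(2975314, 1012637, 670850, 856018, 2788498, 70060),
    ssp3 = c(2846765, 772878, 714860, 1077091, 2873629, 88154))
  tibble::tibble(class = lucc_class_names(),
                 initial_year = 2000L, final_year = 2050L,
                 initial_area_km2 = unname(initial),
                 final_area_km2 = final)
}

#' Full demand table for a scenario configuration
#'
#' Convenience wrapper: validates that every dynamic class has exactly one
#' endpoint and returns the six annual series 2000--2050.
#'
#' @param endpoints An endpoint table or a [scenario_config()] (its
#'   `endpoints` element is used).
#' @return A tibble `class`, `year`, `area_km2` with one series per class.
#' @export
scenario_demand_table <- function(endpoints) {
  if (inherits(endpoints, "lucc_scenario_config")) endpoints <- endpoints$endpoints
  check_endpoints(endpoints)
  missing <- setdiff(lucc_class_names(), endpoints$class)
  if (length(missing) > 0) {
    stop_config(sprintf("missing demand endpoint for class(es): %s",
                        paste(missing, collapse = ", ")))
  }
  dup <- endpoints$class[duplicated(endpoints$class)]
  if (length(dup) > 0) {
    stop_config(sprintf("duplicate demand endpoint for class(es): %s",
                        paste(unique(dup), collapse = ", ")))
  }
  demand_series(endpoints)
}

#' Direction of change implied by demand endpoints
#'
#' @param endpoints An endpoint table.
#' @return A tibble `class`, `change_km2`, `direction` (+1 increase, -1
#'   reduction, 0 constant) and a human-readable `trend`.
#' @export
demand_directions <- function(endpoints) {
  endpoints <- annual_change(endpoints)
  dplyr::transmute(endpoints, class = .data$class,
    change_km2 = .data$final_area_km2 - .data$initial_area_km2,
    direction = sign(.data$change_km2),
    trend = dplyr::case_when(.data$direction > 0 ~ "increase",
                             .data$direction < 0 ~ "reduction",
                             TRUE ~ "constant"))
}
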