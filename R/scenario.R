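#' Scenario configuration
#'
#' Bundles everything that distinguishes one scenario run: demand endpoints,
#' the restriction-mask schedule, scheduled driver-field updates, allocation
#' parameters and the seed. Scenario premises are data, not code: the three
#' standard scenarios differ only in their endpoint tables and schedules
#' (e.g. road-network updates in 2025/2030/2040, protection weakening at
#' 2030 under strong inequality).
#'
#' @param name Scenario label (free text, e.g. `"ssp2"`).
#' @param endpoints Demand endpoint table (see [demand_endpoint()],
#'   [scenario_endpoints()]).
#' @param mask_schedule Optional restriction schedule (see
#'   [apply_restrictions()]).
#' @param driver_schedule Optional tibble `year_from`, `driver`, `values`
#'   (list-column of per-cell vectors, or scalars recycled to the grid);
#'   from `year_from` on, the named driver column is replaced.
#' @param allocation An [allocation_params()].
#' @param years Simulated year range (default `2000:2050`).
#' @param snapshot_years Years whose grids are kept in the result; default
#'   all years.
#' @param seed Integer seed recorded for provenance (the engine itself is
#'   deterministic; the seed matters for synthetic inputs).
#' @return A `lucc_scenario_config` list.
#' @export
scenario_config <- function(name, endpoints, mask_schedule = NULL,
                            driver_schedule = NULL,
                            allocation = allocation_params(),
                            years = 2000:2050, snapshot_years = NULL,
                            seed = NULL) {
  check_endpoints(endpoints)
  if (!is.null(mask_schedule) && nrow(mask_schedule) > 0 &&
      (min(mask_schedule$year_from) < min(years) ||
       max(mask_schedule$year_from) > max(years))) {
    stop_config("mask schedule years must lie within the simulated period")
  }
  structure(list(name = name, endpoints = endpoints,
                 mask_schedule = mask_schedule,
                 driver_schedule = driver_schedule,
                 allocation = allocation, years = years,
                 snapshot_years = snapshot_years %||% years,
                 seed = seed),
            class = "lucc_scenario_config")
}

apply_driver_schedule <- function(grid, schedule, year) {
  if (is.null(schedule) || nrow(schedule) == 0) return(grid)
  active <- schedule |>
    dplyr::filter(.data$year_from <= year) |>
    dplyr::group_by(.data$driver) |>
    dplyr::slice_max(.data$year_from, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  for (i in seq_len(nrow(active))) {
    v <- active$values[[i]]
    grid[[active$driver[i]]] <- if (length(v) == 1) rep(v, nrow(grid)) else v
  }
  grid
}

#' Run a scenario simulation
#'
#' Simulates land-use change year by year: update scheduled drivers,
#' recompute each class's potential surface from the current map (the
#' potential is dynamic), damp it with the active restriction masks, and
#' allocate that year's demanded change. The run is deterministic given the
#' configuration, the initial grid and the fitted models.
#'
#' @param initial The [lucc_grid()] at the first simulated year; its year
#'   stamp must match the demand initial year.
#' @param config A [scenario_config()].
#' @param models Named list of fitted `lucc_slm` models, one per dynamic
#'   class.
#' @param weights A [lucc_weights()] on the initial grid.
#' @return A `lucc_run` with `snapshots` (named list of grids by year),
#'   `reports` (per-year allocation reports), `demand` (the demand table),
#'   `config`, `config_hash` and `seed`.
#' @export
run_scenario <- function(initial, config, models, weights) {
  meta <- grid_meta(initial)
  check_endpoints(config$endpoints)
  miss_d <- setdiff(meta$classes, config$endpoints$class)
  if (length(miss_d) > 0) {
    stop_config(sprintf("missing demand endpoint for class(es): %s",
                        paste(miss_d, collapse = ", ")))
  }
  demand <- demand_series(config$endpoints)
  y0 <- min(config$years)
  if (meta$year != y0) {
    stop_config(sprintf("initial grid year (%d) must equal the first simulated year (%d)",
                        meta$year, y0))
  }
  miss <- setdiff(meta$classes, names(models))
  if (length(miss) > 0) {
    stop_config(sprintf("no potential model for class(es): %s", paste(miss, collapse = ", ")))
  }
  grid <- initial
  snapshots <- list()
  if (y0 %in% config$snapshot_years) snapshots[[as.character(y0)]] <- grid
  reports <- list()
  for (year in config$years[-1]) {
    grid <- apply_driver_schedule(grid, config$driver_schedule, year)
    surfaces <- purrr::map(meta$classes, function(cl) {
      compute_potential(models[[cl]], grid, weights, class = cl, year = year)
    })
    surface <- dplyr::bind_rows(surfaces)
    surface <- apply_restrictions(surface, grid, config$mask_schedule, year)
    demand_t <- demand[demand$year == year, c("class", "area_km2")]
    step <- withCallingHandlers(
      allocate_year(grid, surface, demand_t, config$allocation),
      error = function(e) {
        if (inherits(e, "lucc_convergence_error")) {
          rlang::abort(sprintf("scenario `%s`: %s", config$name, conditionMessage(e)),
                       class = "lucc_convergence_error", report = e$report,
                       parent = e)
        }
      })
    grid <- step$grid
    reports[[as.character(year)]] <- step$report
    if (year %in% config$snapshot_years) snapshots[[as.character(year)]] <- grid
  }
  structure(list(snapshots = snapshots,
                 reports = dplyr::bind_rows(reports),
                 demand = demand, config = config,
                 config_hash = config_hash(config),
                 seed = config$seed,
                 version = as.character(utils::packageVersion("luccr"))),
            class = "lucc_run")
}

#' @export
print.lucc_run <- function(x, ...) {
  yrs <- as.integer(names(x$snapshots))
  cat(sprintf("<lucc_run> scenario `%s`: %d snapshot(s), %d--%d\n",
              x$config$name, length(yrs), min(yrs), max(yrs)))
  cat(sprintf("  all years converged: %s\n", all(x$reports$converged)))
  invisible(x)
}

#' Summarise a run into national class areas
#'
#' @param run A `lucc_run`.
#' @param regions Optional per-cell region labels (character vector in
#'   row-major cell order); areas are then reported per region.
#' @return A tibble `year`, (`region`,) `class`, `area_km2`.
#' @export
summarize_run <- function(run, regions = NULL) {
  purrr::imap_dfr(run$snapshots, function(grid, yr) {
    meta <- grid_meta(grid)
    if (is.null(regions)) {
      out <- grid_areas(grid)
    } else {
      if (length(regions) != nrow(grid)) stop_config("`regions` must label every cell")
      out <- grid |>
        dplyr::filter(.data$valid) |>
        dplyr::mutate(region = regions[.data$cell_id + 1L]) |>
        tidyr::pivot_longer(dplyr::all_of(meta$classes),
                            names_to = "class", values_to = "pct") |>
        dplyr::group_by(.data$region, .data$class) |>
        dplyr::summarise(area_km2 = sum(.data$pct) / 100 * meta$cell_area_km2,
                         .groups = "drop")
    }
    dplyr::mutate(out, year = as.integer(yr), .before = 1)
  })
}

#' Direction of change over a run
#'
#' Signed 2000-to-final change per class with the direction symbol used in
#' scenario summaries.
#'
#' @param run A `lucc_run`.
#' @return A tibble `class`, `initial_km2`, `final_km2`, `change_km2`,
#'   `direction`, `trend`.
#' @export
run_directions <- function(run) {
  yrs <- names(run$snapshots)
  a0 <- grid_areas(run$snapshots[[yrs[1]]])
  a1 <- grid_areas(run$snapshots[[yrs[length(yrs)]]])
  tibble::tibble(class = a0$class,
                 initial_km2 = a0$area_km2, final_km2 = a1$area_km2,
                 change_km2 = a1$area_km2 - a0$area_km2) |>
    dplyr::mutate(direction = sign(.data$change_km2),
                  trend = dplyr::case_when(.data$direction > 0 ~ "increase",
                                           .data$direction < 0 ~ "reduction",
                                           TRUE ~ "constant"))
}
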