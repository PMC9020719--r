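#' Write a grid to a cell-table CSV
#'
#' One row per cell: `cell_id`, `row`, `col`, `valid`, the class percent
#' columns (on-disk unit is percent, matching the published map format),
#' then driver and mask columns. Grid metadata (cell side, year, column
#' roles, projection tag) travels in `#luccr` comment header lines, so a
#' written table reads back into an equivalent grid.
#'
#' @param grid A [lucc_grid()].
#' @param path Output CSV path.
#' @param projection Free-text projection tag recorded in the header
#'   (default `"EPSG:5880"`, the projected national grid of the published
#'   dataset).
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(grid, path, projection = "EPSG:5880") {
  meta <- grid_meta(grid)
  hdr <- c(
    sprintf("#luccr cell_side_km=%s year=%d projection=%s",
            format(meta$cell_side_km), meta$year, projection),
    sprintf("#luccr classes=%s", paste(meta$classes, collapse = ",")),
    sprintf("#luccr drivers=%s", paste(meta$drivers, collapse = ",")),
    sprintf("#luccr masks=%s", paste(meta$masks, collapse = ",")))
  writeLines(hdr, path)
  readr::write_csv(tibble::as_tibble(grid), path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

parse_header_field <- function(lines, key) {
  hit <- grep(paste0("\\b", key, "="), lines, value = TRUE)
  if (length(hit) == 0) return(NULL)
  val <- sub(paste0(".*", key, "=([^ ]*).*"), "\\1", hit[1])
  if (identical(val, "")) character(0) else val
}

#' Read a grid from a cell-table CSV
#'
#' Inverse of [write_cell_table()]. The loaded grid is validated: fraction
#' sums off 100 beyond `tol` raise an error naming the offending cells.
#'
#' @param path CSV path.
#' @param tol Fraction-sum tolerance (default 1e-6).
#' @return A [lucc_grid()].
#' @export
read_cell_table <- function(path, tol = 1e-6) {
  hdr <- grep("^#luccr", readLines(path, n = 10), value = TRUE)
  cells <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  req <- c("row", "col")
  if (!all(req %in% names(cells))) {
    rlang::abort(sprintf("cell table must have columns: %s",
                         paste(req, collapse = ", ")),
                 class = "lucc_parse_error")
  }
  split_field <- function(key) {
    v <- parse_header_field(hdr, key)
    if (is.null(v) || length(v) == 0) character(0) else strsplit(v, ",")[[1]]
  }
  side <- parse_header_field(hdr, "cell_side_km")
  year <- parse_header_field(hdr, "year")
  classes <- split_field("classes")
  g <- lucc_grid(cells,
                 cell_side_km = if (is.null(side)) 10 else as.numeric(side),
                 year = if (is.null(year)) 2000L else as.integer(year),
                 classes = if (length(classes)) classes else NULL,
                 drivers = split_field("drivers"), masks = split_field("masks"),
                 validate = FALSE)
  validate_lucc_grid(g, tol = tol)
  g
}

#' Write the demand series as CSV
#' @param series A demand table from [demand_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_demand_series <- function(series, path) {
  readr::write_csv(series, path)
  invisible(path)
}

#' Write fitted potential models to a coefficients CSV
#'
#' Human-readable long format: one row per class and term (drivers,
#' intercept, `rho`, `sigma2`, `AIC`, `pseudo_R2`, `logLik`).
#'
#' @param models Named list of `lucc_slm` fits.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_coefficients <- function(models, path) {
  out <- purrr::imap_dfr(models, function(m, cl) {
    dplyr::bind_rows(
      tibble::tibble(class = cl, term = names(m$coefficients),
                     estimate = unname(m$coefficients),
                     p_value = unname(m$p_values[names(m$coefficients)])),
      tibble::tibble(class = cl,
                     term = c("rho", "sigma2", "AIC", "pseudo_R2", "logLik"),
                     estimate = c(m$rho, m$sigma2, m$aic, m$pseudo_r2, m$loglik),
                     p_value = c(unname(m$p_values["rho"]), NA, NA, NA, NA)))
  })
  readr::write_csv(out, path)
  invisible(path)
}

#' Stable hash of a configuration
#'
#' MD5 of the canonical JSON serialisation (names sorted recursively), so
#' the hash is invariant under key reordering.
#'
#' @param x Any list-like configuration.
#' @return A 32-character hex string.
#' @export
config_hash <- function(x) {
  canon <- function(v) {
    if (is.list(v)) {
      v <- purrr::map(v, canon)
      nm <- names(v)
      if (!is.null(nm) && any(nzchar(nm))) v <- v[order(nm)]
    }
    v
  }
  x <- canon(unclass_deep(x))
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  unname(tools::md5sum(tmp))
}

unclass_deep <- function(x) {
  if (is.environment(x) || is.function(x)) return(NULL)
  if (is.list(x)) {
    x <- lapply(x, unclass_deep)
    attributes(x) <- list(names = names(x))
  } else if (is.object(x)) {
    x <- unclass(x)
  }
  x
}

#' Run manifest
#'
#' Provenance record emitted alongside run outputs: package version, config
#' hash, input checksums, timestamps and collected warnings.
#'
#' @param config The configuration used.
#' @param inputs Named character vector of input file paths to checksum.
#' @param warnings Character vector of warnings raised during the run.
#' @param started,finished POSIXct timestamps (defaults: now).
#' @return A list of class `lucc_manifest`.
#' @export
run_manifest <- function(config, inputs = character(), warnings = character(),
                         started = Sys.time(), finished = Sys.time()) {
  sums <- if (length(inputs)) vapply(inputs, function(p) {
    unname(tools::md5sum(p))
  }, character(1)) else character()
  structure(list(tool = "luccr",
                 version = as.character(utils::packageVersion("luccr")),
                 config_hash = config_hash(config),
                 input_checksums = as.list(sums),
                 started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
                 finished = format(finished, "%Y-%m-%dT%H:%M:%S%z"),
                 warnings = warnings),
            class = "lucc_manifest")
}

#' Write a manifest as JSON
#' @param manifest A [run_manifest()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass_deep(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' Write a run to a directory
#'
#' Emits one cell-table CSV per snapshot year, the allocation reports, the
#' demand series and a manifest.
#'
#' @param run A `lucc_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- purrr::imap_chr(run$snapshots, function(grid, yr) {
    write_cell_table(grid, file.path(dir, sprintf("grid_%s.csv", yr)))
  })
  readr::write_csv(run$reports, file.path(dir, "allocation_reports.csv"))
  write_demand_series(run$demand, file.path(dir, "demand_series.csv"))
  write_manifest(run_manifest(run$config, inputs = paths),
                 file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Write a validation report
#'
#' Emits the per-class adjustment/error table and the similarity-by-window
#' table as two CSVs.
#'
#' @param report A `lucc_validation` from [validate_maps()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_validation_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$errors, file.path(dir, "spatial_adjustment.csv"))
  readr::write_csv(report$similarity, file.path(dir, "similarity_by_window.csv"))
  invisible(dir)
}

#' Read a scenario configuration from YAML
#'
#' The file has blocks `name`, `demand` (class -> initial_year, final_year,
#' initial_area_km2, final_area_km2), optional `masks` (list of year_from,
#' mask, class_group, protection_level), optional `allocation`
#' (max_error, max_iterations, itf_gain), `years`, `seed`.
#'
#' @param path YAML path.
#' @return A [scenario_config()].
#' @export
read_scenario_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$demand)) stop_config("scenario file must have a `demand` block")
  eps <- purrr::imap_dfr(y$demand, function(v, cl) {
    tibble::tibble(class = cl,
                   initial_year = as.integer(v$initial_year),
                   final_year = as.integer(v$final_year),
                   initial_area_km2 = as.numeric(v$initial_area_km2),
                   final_area_km2 = as.numeric(v$final_area_km2))
  })
  masks <- if (!is.null(y$masks)) purrr::map_dfr(y$masks, tibble::as_tibble)
  alloc <- do.call(allocation_params, y$allocation %||% list())
  years <- if (!is.null(y$years)) y$years[[1]]:y$years[[2]] else
    min(eps$initial_year):max(eps$final_year)
  scenario_config(y$name %||% tools::file_path_sans_ext(basename(path)),
                  eps, mask_schedule = masks, allocation = alloc,
                  years = years, seed = y$seed)
}

#' Write a scenario configuration to YAML
#' @param config A [scenario_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scenario_config <- function(config, path) {
  eps <- split(config$endpoints, config$endpoints$class)
  y <- list(
    name = config$name,
    demand = purrr::map(eps, function(e) list(
      initial_year = e$initial_year, final_year = e$final_year,
      initial_area_km2 = e$initial_area_km2, final_area_km2 = e$final_area_km2)),
    allocation = list(max_error = config$allocation$max_error,
                      max_iterations = config$allocation$max_iterations,
                      itf_gain = config$allocation$itf_gain),
    years = list(min(config$years), max(config$years)),
    seed = config$seed)
  if (!is.null(config$mask_schedule)) {
    y$masks <- purrr::transpose(as.list(config$mask_schedule))
  }
  yaml::write_yaml(y, path)
  invisible(path)
}
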