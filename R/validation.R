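# Coerce a per-cell field (matrix, or grid + class column) to a matrix in
# (row, col) layout. Grids are row-major by cell_id.
field_matrix <- function(x, grid = NULL, class = NULL) {
  if (is.matrix(x)) return(x)
  if (is.data.frame(x) && !is.null(class)) {
    meta <- grid_meta(x)
    return(matrix(x[[class]], nrow = meta$n_rows, ncol = meta$n_cols, byrow = TRUE))
  }
  stop_dimension("field must be a matrix or a grid with a class column")
}

check_same_dims <- function(...) {
  dims <- lapply(list(...), dim)
  if (!all(vapply(dims, identical, TRUE, dims[[1]]))) {
    stop_dimension("maps must share the same grid dimensions")
  }
}

# Block sums of a matrix for a given window size; edge blocks are partial.
block_sums <- function(m, w) {
  bi <- (base::row(m) - 1L) %/% w
  bj <- (base::col(m) - 1L) %/% w
  as.numeric(rowsum(as.numeric(m), group = as.vector(bi * (max(bj) + 1L) + bj)))
}

#' Multi-resolution similarity between simulated and observed change
#'
#' Compares the simulated change map against the observed change map for
#' one class at a set of window sizes. At window size `w` the grid is
#' partitioned into `w x w` blocks (partial blocks kept at the edges); per
#' block the observed change `sum(real_tf - real_t0)` and simulated change
#' `sum(sim_tf - real_t0)` are accumulated, and the similarity is
#' `NS_w = (1 - sum_j |dsim_j - dreal_j| / (2 sum_j |dreal_j|)) x 100`.
#' Growing windows degrade resolution, separating location error (low
#' `NS_1`) from pattern error (low `NS` at all windows). When the observed
#' change is zero everywhere, `NS` is 100 if the simulated change is also
#' zero and 0 otherwise.
#'
#' @param real_t0,real_tf,sim_tf Per-cell percent fields for one class:
#'   matrices in map layout, or pass [lucc_grid()]s together with `class`.
#' @param windows Integer window sizes (default `c(1, 2, 4, 8)`).
#' @param class Class column name when grids are supplied.
#' @param valid Optional logical matrix of in-region cells; cells outside
#'   contribute zero change.
#' @return A tibble `window`, `ns` (clamped to `[0, 100]`) and `ns_raw`.
#' @export
multires_similarity <- function(real_t0, real_tf, sim_tf,
                                windows = c(1, 2, 4, 8), class = NULL,
                                valid = NULL) {
  r0 <- field_matrix(real_t0, class = class)
  r1 <- field_matrix(real_tf, class = class)
  s1 <- field_matrix(sim_tf, class = class)
  check_same_dims(r0, r1, s1)
  if (any(windows < 1)) stop_config("window sizes must be >= 1")
  dreal <- r1 - r0
  dsim <- s1 - r0
  if (!is.null(valid)) { dreal[!valid] <- 0; dsim[!valid] <- 0 }
  purrr::map_dfr(windows, function(w) {
    br <- block_sums(dreal, w)
    bs <- block_sums(dsim, w)
    denom <- 2 * sum(abs(br))
    raw <- if (denom == 0) { if (sum(abs(bs)) == 0) 100 else 0 }
      else (1 - sum(abs(bs - br)) / denom) * 100
    tibble::tibble(window = as.integer(w), ns = clamp(raw, 0, 100), ns_raw = raw)
  })
}

#' Pattern and modified-area fits between simulated and observed maps
#'
#' `fit_patterns` is the map-level agreement of the simulated and observed
#' final maps, `(1 - sum|sim_tf - real_tf| / (2 sum real_tf)) x 100`, over
#' all in-region cells; `fit_modified_areas` is the same statistic
#' restricted to cells where the observed change exceeds
#' `change_threshold` percent. When no cell passes the threshold the
#' modified-area fit is undefined and reported as `NA` with a warning.
#'
#' @inheritParams multires_similarity
#' @param change_threshold Percent-change threshold defining a modified
#'   cell (default 0, i.e. any change).
#' @return A tibble `fit_patterns`, `fit_modified_areas`, `n_modified`.
#' @export
fit_decomposition <- function(real_t0, real_tf, sim_tf, change_threshold = 0,
                              class = NULL, valid = NULL) {
  if (change_threshold < 0) stop_validation("change_threshold must be >= 0")
  r0 <- field_matrix(real_t0, class = class)
  r1 <- field_matrix(real_tf, class = class)
  s1 <- field_matrix(sim_tf, class = class)
  check_same_dims(r0, r1, s1)
  keep <- if (is.null(valid)) rep(TRUE, length(r1)) else as.vector(valid)
  agree <- function(sel) {
    denom <- 2 * sum(r1[sel])
    if (denom == 0) return(if (sum(abs(s1[sel] - r1[sel])) == 0) 100 else 0)
    (1 - sum(abs(s1[sel] - r1[sel])) / denom) * 100
  }
  modified <- keep & abs(r1 - r0) > change_threshold
  fm <- if (!any(modified)) {
    rlang::warn("no cell exceeds the change threshold; modified-area fit is undefined")
    NA_real_
  } else agree(modified)
  tibble::tibble(fit_patterns = agree(keep), fit_modified_areas = fm,
                 n_modified = sum(modified))
}

#' Omission and commission errors of simulated change
#'
#' Omission is observed change the simulation missed; commission is
#' simulated change that did not occur. Both are measured per cell on
#' absolute change magnitudes, `pos(|dreal| - |dsim|)` and
#' `pos(|dsim| - |dreal|)`, and expressed as a percentage of the total
#' in-region area.
#'
#' @inheritParams fit_decomposition
#' @return A tibble `omission_pct`, `commission_pct`.
#' @export
omission_commission <- function(real_t0, real_tf, sim_tf, change_threshold = 0,
                                class = NULL, valid = NULL) {
  if (change_threshold < 0) stop_validation("change_threshold must be >= 0")
  r0 <- field_matrix(real_t0, class = class)
  r1 <- field_matrix(real_tf, class = class)
  s1 <- field_matrix(sim_tf, class = class)
  check_same_dims(r0, r1, s1)
  keep <- if (is.null(valid)) rep(TRUE, length(r1)) else as.vector(valid)
  dr <- abs(r1 - r0)[keep]
  ds <- abs(s1 - r0)[keep]
  dr[dr <= change_threshold] <- 0
  n <- sum(keep)
  tibble::tibble(omission_pct = clamp(sum(pmax(dr - ds, 0)) / n, 0, 100),
                 commission_pct = clamp(sum(pmax(ds - dr, 0)) / n, 0, 100))
}

#' Full validation report for simulated versus observed maps
#'
#' Runs the multi-resolution similarity and the pattern / modified-area /
#' omission / commission decomposition for every dynamic class, comparing a
#' simulated final map against the observed initial and final maps.
#'
#' @param real_t0,real_tf,sim_tf [lucc_grid()]s sharing the lattice.
#' @param classes Classes to validate (default: dynamic classes of
#'   `real_t0`).
#' @param windows Window sizes for the similarity profile.
#' @param change_threshold Percent threshold for modified cells and error
#'   accounting.
#' @return A list of class `lucc_validation` with `similarity` (tibble
#'   `class`, `window`, `ns`, `ns_raw`) and `errors` (tibble `class`,
#'   `fit_patterns`, `fit_modified_areas`, `omission_pct`,
#'   `commission_pct`, plus the column averages in the last row).
#' @export
validate_maps <- function(real_t0, real_tf, sim_tf, classes = NULL,
                          windows = c(1, 2, 4, 8), change_threshold = 0) {
  meta <- grid_meta(real_t0)
  classes <- classes %||% meta$classes
  vmat <- matrix(real_t0$valid, nrow = meta$n_rows, ncol = meta$n_cols, byrow = TRUE)
  per_class <- purrr::map(classes, function(cl) {
    m0 <- field_matrix(real_t0, class = cl)
    m1 <- field_matrix(real_tf, class = cl)
    ms <- field_matrix(sim_tf, class = cl)
    list(
      sim = dplyr::mutate(
        multires_similarity(m0, m1, ms, windows = windows, valid = vmat),
        class = cl, .before = 1),
      err = dplyr::bind_cols(
        tibble::tibble(class = cl),
        fit_decomposition(m0, m1, ms, change_threshold, valid = vmat)[, 1:2],
        omission_commission(m0, m1, ms, change_threshold, valid = vmat)))
  })
  errors <- purrr::map_dfr(per_class, "err")
  avg <- dplyr::summarise(errors, class = "average",
                          dplyr::across(dplyr::where(is.numeric),
                                        ~ mean(.x, na.rm = TRUE)))
  structure(list(similarity = purrr::map_dfr(per_class, "sim"),
                 errors = dplyr::bind_rows(errors, avg)),
            class = "lucc_validation")
}

#' @export
print.lucc_validation <- function(x, ...) {
  cat("<lucc_validation>\n\nSpatial adjustment and errors (%):\n")
  print(as.data.frame(x$errors), digits = 4, row.names = FALSE)
  cat("\nSimilarity by window size (first class):\n")
  print(as.data.frame(head(x$similarity, 8)), digits = 4, row.names = FALSE)
  invisible(x)
}
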