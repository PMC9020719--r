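#' Cellular space for land-use fractions and drivers
#'
#' A `lucc_grid` is a tibble with one row per cell of a regular lattice, in
#' row-major order (0-based `row`, `col`, `cell_id = row * n_cols + col`).
#' Each cell carries the percentage of its area occupied by every land-use
#' class (0--100, summing to 100 together with the static `others` class),
#' plus any number of named driver fields and restriction masks. Cells
#' outside the study region are flagged `valid = FALSE` and are excluded
#' from neighbourhoods, regressions and area sums.
#'
#' @param cells A data frame with columns `row`, `col` (0-based), the class
#'   fraction columns (percent), and optionally `cell_id`, `valid`, driver
#'   and mask columns. Missing `valid` defaults to all-`TRUE`.
#' @param cell_side_km Side length of a square cell in km (default 10).
#' @param year Calendar year stamped on the grid.
#' @param classes Names of the dynamic class columns; defaults to the six
#'   standard classes present in `cells`.
#' @param drivers,masks Character vectors naming driver / mask columns.
#' @param validate Check the compositional invariants (default `TRUE`).
#'
#' @return A tibble of class `lucc_grid`, sorted by `cell_id`.
#' @export
#' @examples
#' cells <- tidyr::expand_grid(row = 0:1, col = 0:1)
#' cells$forest_vegetation <- 60
#' cells$grassland_vegetation <- 33
#' cells$others <- 7
#' g <- lucc_grid(cells, classes = c("forest_vegetation", "grassland_vegetation"))
#' grid_areas(g)
lucc_grid <- function(cells, cell_side_km = 10, year = 2000L,
                      classes = NULL, drivers = character(), masks = character(),
                      validate = TRUE) {
  cells <- tibble::as_tibble(cells)
  if (!all(c("row", "col") %in% names(cells))) {
    stop_config("`cells` must have 0-based `row` and `col` columns.")
  }
  n_rows <- max(cells$row) + 1L
  n_cols <- max(cells$col) + 1L
  if (nrow(cells) != n_rows * n_cols) {
    stop_dimension(sprintf(
      "grid must cover the full %d x %d lattice (%d cells expected, %d given)",
      n_rows, n_cols, n_rows * n_cols, nrow(cells)))
  }
  if (!"cell_id" %in% names(cells)) cells$cell_id <- cells$row * n_cols + cells$col
  if (!"valid" %in% names(cells)) cells$valid <- TRUE
  classes <- classes %||% intersect(lucc_class_names(), names(cells))
  if (length(classes) == 0) stop_config("no land-use class columns found")
  if (!lucc_others_name() %in% names(cells)) cells[[lucc_others_name()]] <- 0
  cells <- dplyr::arrange(cells, .data$cell_id)
  front <- c("cell_id", "row", "col", "valid", classes, lucc_others_name())
  cells <- dplyr::relocate(cells, dplyr::all_of(front))
  g <- structure(cells,
    class = c("lucc_grid", class(tibble::tibble())),
    cell_side_km = cell_side_km, year = as.integer(year),
    classes = classes, drivers = drivers, masks = masks)
  if (validate) validate_lucc_grid(g)
  g
}

#' Grid metadata
#'
#' Dimensions, cell size, year and column roles of a [lucc_grid()].
#' Structural fields are re-derived from the `row`/`col` columns so the
#' metadata survives ordinary data-frame manipulation.
#'
#' @param grid A `lucc_grid` (or compatible data frame).
#' @return A list with `n_rows`, `n_cols`, `n_cells`, `cell_side_km`,
#'   `cell_area_km2`, `year`, `classes`, `others`, `drivers`, `masks`.
#' @export
grid_meta <- function(grid) {
  n_rows <- max(grid$row) + 1L
  n_cols <- max(grid$col) + 1L
  classes <- attr(grid, "classes") %||% intersect(lucc_class_names(), names(grid))
  side <- attr(grid, "cell_side_km") %||% 10
  list(
    n_rows = n_rows, n_cols = n_cols, n_cells = n_rows * n_cols,
    cell_side_km = side, cell_area_km2 = side^2,
    year = attr(grid, "year") %||% NA_integer_,
    classes = classes, others = lucc_others_name(),
    drivers = attr(grid, "drivers") %||% character(),
    masks = attr(grid, "masks") %||% character())
}

#' Check the compositional invariants of a grid
#'
#' Every valid cell must have all class fractions in \[0, 100\] and fractions
#' (including `others`) summing to 100 within `tol`.
#'
#' @param grid A `lucc_grid`.
#' @param tol Absolute tolerance on the per-cell sum (default 1e-6).
#' @return `grid`, invisibly; errors describe the offending cells.
#' @export
validate_lucc_grid <- function(grid, tol = 1e-6) {
  meta <- grid_meta(grid)
  cols <- c(meta$classes, meta$others)
  fr <- as.matrix(grid[grid$valid, cols, drop = FALSE])
  if (any(fr < -tol | fr > 100 + tol)) {
    bad <- which(fr < -tol | fr > 100 + tol, arr.ind = TRUE)
    stop_validation(sprintf("class fractions outside [0, 100] in %d cell(s), e.g. cell_id %s",
      nrow(bad), grid$cell_id[grid$valid][bad[1, 1]]))
  }
  sums <- rowSums(fr)
  off <- abs(sums - 100) > tol
  if (any(off)) {
    ids <- grid$cell_id[grid$valid][off]
    stop_validation(sprintf(
      "fraction sums differ from 100 in %d cell(s): cell_id %s (sum %.6f, ...)",
      sum(off), paste(head(ids, 5), collapse = ", "), sums[off][1]),
      cells = ids)
  }
  invisible(grid)
}

#' National class areas of a grid
#'
#' @param grid A `lucc_grid`.
#' @param include_others Include the static class (default `FALSE`).
#' @return A tibble with `class` and `area_km2` summed over valid cells.
#' @export
grid_areas <- function(grid, include_others = FALSE) {
  meta <- grid_meta(grid)
  cols <- if (include_others) c(meta$classes, meta$others) else meta$classes
  fr <- as.matrix(grid[grid$valid, cols, drop = FALSE])
  tibble::tibble(class = cols,
                 area_km2 = unname(colSums(fr)) / 100 * meta$cell_area_km2)
}

#' Total valid study area in km2
#' @param grid A `lucc_grid`.
#' @return Scalar area of the valid region in km2.
#' @export
total_area_km2 <- function(grid) {
  meta <- grid_meta(grid)
  sum(grid$valid) * meta$cell_area_km2
}

#' Contiguity weights on the cell lattice
#'
#' Builds row-standardised first-order contiguity weights over the valid
#' cells of the grid: `queen` (8 neighbours) or `rook` (4 neighbours).
#' Invalid cells receive (and provide) no neighbours; isolated cells keep an
#' empty, all-zero row. The underlying adjacency is symmetric before row
#' standardisation and never includes self-neighbours.
#'
#' @param grid A [lucc_grid()].
#' @param scheme `"queen"` (default) or `"rook"`.
#' @return A `lucc_weights` object wrapping a sparse row-standardised matrix
#'   `W` in row-major cell order, with the scheme, the `valid` flag vector
#'   and an eigenvalue cache used by the spatial-lag likelihood.
#' @export
lucc_weights <- function(grid, scheme = c("queen", "rook")) {
  scheme <- match.arg(scheme)
  meta <- grid_meta(grid)
  if (!any(grid$valid)) stop_config("grid has no valid cells")
  nr <- meta$n_rows; nc <- meta$n_cols
  offs <- switch(scheme,
    rook  = cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1)),
    queen = cbind(rep(-1:1, each = 3), rep(-1:1, 3))[-5, , drop = FALSE])
  row <- grid$row; col <- grid$col; valid <- grid$valid
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(offs))) {
    r2 <- row + offs[k, 1]; c2 <- col + offs[k, 2]
    ok <- valid & r2 >= 0 & r2 < nr & c2 >= 0 & c2 < nc
    j <- r2 * nc + c2
    ok[ok] <- valid[j[ok] + 1L]
    from <- c(from, grid$cell_id[ok]); to <- c(to, j[ok])
  }
  n <- meta$n_cells
  A <- Matrix::sparseMatrix(i = from + 1L, j = to + 1L, x = 1,
                            dims = c(n, n))
  deg <- Matrix::rowSums(A)
  inv <- ifelse(deg > 0, 1 / deg, 0)
  W <- Matrix::Diagonal(n, inv) %*% A
  structure(list(W = methods::as(W, "generalMatrix"), A = A, scheme = scheme,
                 n_rows = nr, n_cols = nc, valid = valid,
                 cache = new.env(parent = emptyenv())),
            class = "lucc_weights")
}

#' @export
print.lucc_weights <- function(x, ...) {
  cat(sprintf("<lucc_weights> %s contiguity, %d x %d lattice, %d valid cells\n",
              x$scheme, x$n_rows, x$n_cols, sum(x$valid)))
  invisible(x)
}

# Eigenvalues of the row-standardised W restricted to valid cells, via the
# similar symmetric matrix D^{-1/2} A D^{-1/2} (same spectrum, real).
# Cached per weights object; used for the spatial-lag log-determinant and
# the admissible rho interval.
weights_eigenvalues <- function(w) {
  if (!is.null(w$cache$ev)) return(w$cache$ev)
  A <- w$A[w$valid, w$valid, drop = FALSE]
  deg <- Matrix::rowSums(A)
  s <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  S <- Matrix::Diagonal(length(s), s) %*% A %*% Matrix::Diagonal(length(s), s)
  ev <- eigen(as.matrix(Matrix::symmpart(S)), symmetric = TRUE,
              only.values = TRUE)$values
  w$cache$ev <- ev
  ev
}

# Admissible open interval for the autoregressive coefficient.
rho_interval <- function(w) {
  ev <- weights_eigenvalues(w)
  lo <- if (min(ev) < 0) 1 / min(ev) else -1
  hi <- if (max(ev) > 0) 1 / max(ev) else 1
  c(lo, hi)
}

# Dimensions of one high-resolution raster block per grid cell.
block_shape <- function(raster, meta) {
  br <- nrow(raster) / meta$n_rows
  bc <- ncol(raster) / meta$n_cols
  if (br != floor(br) || bc != floor(bc)) {
    stop_dimension(sprintf(
      "raster %d x %d is not an integer multiple of the %d x %d grid",
      nrow(raster), ncol(raster), meta$n_rows, meta$n_cols))
  }
  c(as.integer(br), as.integer(bc))
}

# Cell index (0-based, row-major) of every raster pixel.
pixel_cell_index <- function(raster, meta, bs) {
  pr <- (base::row(raster) - 1L) %/% bs[1]
  pc <- (base::col(raster) - 1L) %/% bs[2]
  pr * meta$n_cols + pc
}

#' Aggregate a high-resolution mask to per-cell percentages
#'
#' The cell-filling "percentage of each class" operator: each grid cell
#' receives 100 x (true pixels in its block) / (pixels in its block).
#'
#' @param raster A logical (or 0/1) matrix whose dimensions are integer
#'   multiples of the grid dimensions.
#' @param grid A [lucc_grid()].
#' @return A tibble `cell_id`, `row`, `col`, `percent` in row-major order.
#' @export
aggregate_percentage <- function(raster, grid) {
  meta <- grid_meta(grid)
  bs <- block_shape(raster, meta)
  idx <- pixel_cell_index(raster, meta, bs)
  sums <- rowsum(as.numeric(raster), group = as.vector(idx))
  pct <- numeric(meta$n_cells)
  pct[as.integer(rownames(sums)) + 1L] <- sums[, 1] / prod(bs) * 100
  tibble::tibble(cell_id = grid$cell_id, row = grid$row, col = grid$col,
                 percent = pct[grid$cell_id + 1L])
}

#' Aggregate a feature mask to per-cell minimum distances
#'
#' The cell-filling "minimum distance" operator: for each cell, the minimum
#' Euclidean distance (km, projected plane) from the cell centroid to the
#' centroid of any true pixel. A cell whose own block contains a true pixel
#' gets distance 0. An all-false mask yields the `sentinel` distance
#' everywhere, with a warning.
#'
#' @inheritParams aggregate_percentage
#' @param sentinel Distance assigned when the mask has no true pixel
#'   (default 1e6 km).
#' @return A tibble `cell_id`, `row`, `col`, `distance_km`.
#' @export
aggregate_min_distance <- function(raster, grid, sentinel = 1e6) {
  meta <- grid_meta(grid)
  bs <- block_shape(raster, meta)
  tr <- which(raster != 0, arr.ind = TRUE)
  out <- tibble::tibble(cell_id = grid$cell_id, row = grid$row, col = grid$col)
  if (nrow(tr) == 0) {
    rlang::warn("mask has no true pixel; returning sentinel distances")
    out$distance_km <- sentinel
    return(out)
  }
  px_km <- meta$cell_side_km / bs[1]
  py_km <- meta$cell_side_km / bs[2]
  # pixel centroids in km (x along columns, y along rows; origin top-left)
  sx <- (tr[, 1] - 0.5) * px_km
  sy <- (tr[, 2] - 0.5) * py_km
  cx <- (grid$row + 0.5) * meta$cell_side_km
  cy <- (grid$col + 0.5) * meta$cell_side_km
  d2 <- outer(cx, sx, "-")^2 + outer(cy, sy, "-")^2
  dist <- sqrt(apply(d2, 1, min))
  # containment overrides centroid distance
  hit_cells <- unique(((tr[, 1] - 1L) %/% bs[1]) * meta$n_cols +
                      ((tr[, 2] - 1L) %/% bs[2]))
  dist[match(hit_cells, grid$cell_id)] <- 0
  out$distance_km <- dist
  out
}
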