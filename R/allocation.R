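#' Allocation parameters
#'
#' Controls of the iterative CLUE-like allocation loop.
#'
#' @param max_error Convergence tolerance as a fraction of total study area
#'   (default 0.005, i.e. every class's allocated total must come within
#'   0.5% of study area of its demand).
#' @param max_iterations Iteration cap per simulated year (default 1000).
#' @param itf_gain Gain `lambda` of the multiplicative iteration-factor
#'   update, in `(0, 2]` (default 0.5).
#' @param min_cell_change Percent floor below which a candidate cell delta
#'   is zeroed (default 0).
#' @param pressure_step Demand-pressure increment in potential units
#'   (default 0.02). When a class's gap stops shrinking while its demand is
#'   unmet, its effective potential is shifted by this amount per stalled
#'   iteration in the demand direction, recruiting the next-best cells in
#'   potential order; 0 disables the mechanism, leaving the purely
#'   multiplicative, sign-gated factor.
#' @param on_non_convergence `"error"` (default) or `"warn"`: whether a year
#'   that fails to converge aborts the run or is accepted with a warning.
#' @return A `lucc_allocation_params` list.
#' @export
allocation_params <- function(max_error = 0.005, max_iterations = 1000,
                              itf_gain = 0.5, min_cell_change = 0,
                              pressure_step = 0.02,
                              on_non_convergence = c("error", "warn")) {
  if (max_error <= 0) stop_config("max_error must be positive")
  if (max_iterations < 1) stop_config("max_iterations must be >= 1")
  if (itf_gain <= 0 || itf_gain > 2) stop_config("itf_gain must lie in (0, 2]")
  if (pressure_step < 0) stop_config("pressure_step must be >= 0")
  structure(list(max_error = max_error, max_iterations = as.integer(max_iterations),
                 itf_gain = itf_gain, min_cell_change = min_cell_change,
                 pressure_step = pressure_step,
                 on_non_convergence = match.arg(on_non_convergence)),
            class = "lucc_allocation_params")
}

#' Resolve within-cell competition between class changes
#'
#' Given one cell's current class fractions (percent), requested deltas and
#' the frozen `others` percentage, returns adjusted deltas that (i) keep
#' every resulting fraction in `[0, 100 - others]`, and (ii) sum exactly to
#' zero across the dynamic classes. Requested gains and losses compete: the
#' side with the larger total is scaled down proportionally to its requested
#' magnitudes; if one side is absent the other collapses to zero (an
#' infeasible request resolves to no change).
#'
#' @param fractions Named numeric vector of dynamic class percents.
#' @param deltas Requested percent changes, same order.
#' @param frozen The static `others` percent of the cell.
#' @return Adjusted deltas summing to zero.
#' @export
#' @examples
#' rebalance_cell(c(a = 40, b = 40, c = 13), c(10, 10, -5), frozen = 7)
rebalance_cell <- function(fractions, deltas, frozen = 0) {
  m <- rebalance_matrix(matrix(fractions, nrow = 1),
                        matrix(deltas, nrow = 1), frozen)
  setNames(as.numeric(m), names(fractions))
}

# Vectorised competition over all cells: frac and delta are n_cells x k
# percent matrices, frozen a length-n vector.
rebalance_matrix <- function(frac, delta, frozen) {
  cap <- 100 - frozen
  delta <- pmax(delta, -frac)                      # cannot lose more than held
  delta <- pmin(delta, pmax(cap - frac, 0))        # cannot exceed dynamic space
  gain <- rowSums(pmax(delta, 0))
  loss <- rowSums(pmax(-delta, 0))
  tot <- pmin(gain, loss)                          # feasible exchanged amount
  gscale <- ifelse(gain > 0, tot / gain, 0)
  lscale <- ifelse(loss > 0, tot / loss, 0)
  pos <- delta > 0
  out <- delta
  out[pos] <- delta[pos] * gscale[base::row(delta)[pos]]
  out[!pos] <- delta[!pos] * lscale[base::row(delta)[!pos]]
  out
}

#' Allocate one year of demanded change across the grid
#'
#' The iterative allocation loop: each class's candidate cell change is its
#' effective potential times a per-class iteration factor `ITF_c`,
#' sign-gated to the class's national demand direction; within-cell
#' competition rebalances the candidates so compositions stay valid; and
#' `ITF_c` is updated multiplicatively in proportion to the signed gap
#' between allocated and demanded area, until every class total is within
#' `max_error * total study area` of its demand, or the iteration cap. The
#' effective potential is the model potential plus an adaptive
#' demand-pressure offset (see [allocation_params()]): the multiplier alone
#' can only rescale change within the cells whose potential sign already
#' matches the demand direction, so when that frontier is exhausted the
#' offset recruits further cells, best-potential first.
#'
#' @param grid The [lucc_grid()] at year t-1.
#' @param potentials A potential tibble covering every dynamic class (rows
#'   `cell_id`, `class`, `potential`; bind the per-class surfaces from
#'   [compute_potential()]).
#' @param demand A tibble `class`, `area_km2` (or named vector) of target
#'   national areas for year t.
#' @param params An [allocation_params()].
#' @return A list with `grid` (the year-t [lucc_grid()]) and `report`, a
#'   one-row tibble (`year`, `iterations`, `converged`, `max_gap_km2`) with
#'   the per-class gaps in `attr(report, "gaps")`. Non-convergence raises a
#'   `lucc_convergence_error` carrying the report, unless the params say to
#'   accept with a warning.
#' @export
allocate_year <- function(grid, potentials, demand, params = allocation_params()) {
  meta <- grid_meta(grid)
  classes <- meta$classes
  if (!is.data.frame(demand)) {
    demand <- tibble::tibble(class = names(demand), area_km2 = as.numeric(demand))
  }
  missing <- setdiff(classes, demand$class)
  if (length(missing) > 0) {
    stop_config(sprintf("demand missing for class(es): %s", paste(missing, collapse = ", ")))
  }
  D <- demand$area_km2[match(classes, demand$class)]
  pot_missing <- setdiff(classes, unique(potentials$class))
  if (length(pot_missing) > 0) {
    stop_config(sprintf("potential surface missing for class(es): %s",
                        paste(pot_missing, collapse = ", ")))
  }
  valid <- grid$valid
  nv <- sum(valid)
  cell_area <- meta$cell_area_km2
  total_area <- nv * cell_area
  tol_km2 <- params$max_error * total_area

  frac0 <- as.matrix(grid[valid, classes, drop = FALSE])  # percent
  frozen <- as.numeric(grid[[meta$others]])[valid]
  P <- matrix(0, nv, length(classes), dimnames = list(NULL, classes))
  vid <- grid$cell_id[valid]
  for (cl in classes) {
    pc <- potentials[potentials$class == cl, ]
    P[, cl] <- pc$potential[match(vid, pc$cell_id)]
  }
  P[!is.finite(P)] <- 0

  A0 <- colSums(frac0) / 100 * cell_area
  if (abs(sum(D) - sum(A0)) > tol_km2) {
    stop_config(sprintf(
      "total demand (%.1f km2) differs from current dynamic area (%.1f km2) beyond max_error",
      sum(D), sum(A0)))
  }
  # any demanded change participates in exchange; only an (essentially)
  # exact match sits the year out, otherwise zero-sum gaps can strand a
  # within-tolerance class's slack on another class
  dir <- sign(D - A0)
  dir[abs(D - A0) <= 1e-9 * max(abs(D), 1)] <- 0

  itf <- rep(1, length(classes))
  press <- rep(0, length(classes))
  prev_gap <- rep(Inf, length(classes))
  converged <- FALSE
  frac <- frac0
  gaps <- A0 - D
  it <- 0L
  for (it in seq_len(params$max_iterations)) {
    # effective potential in the demand direction; <= 0 means not a
    # candidate cell for this class at the current demand pressure
    E <- sweep(P, 2, dir, "*") + rep(press, each = nrow(P))
    E[E < 0] <- 0
    delta <- sweep(E, 2, dir * itf, "*") * 100      # percent units
    if (params$min_cell_change > 0) delta[abs(delta) < params$min_cell_change] <- 0
    delta <- rebalance_matrix(frac0, delta, frozen)
    frac <- frac0 + delta
    A <- colSums(frac) / 100 * cell_area
    gaps <- A - D
    if (all(abs(gaps) <= tol_km2)) { converged <- TRUE; break }
    need <- dir * (D - A)                           # > 0: more change needed
    stalled <- abs(gaps) > tol_km2 & need > 0 &
      abs(abs(gaps) - prev_gap) < 0.01 * tol_km2
    press[stalled] <- press[stalled] + params$pressure_step
    prev_gap <- abs(gaps)
    rel <- dir * (D - A) / pmax(abs(D - A0), tol_km2)
    itf <- clamp(itf * clamp(1 + params$itf_gain * rel, 0.5, 2), 1e-9, 1e9)
  }

  new_grid <- grid
  new_grid[valid, classes] <- as.data.frame(frac)
  attr(new_grid, "year") <- meta$year + 1L
  report <- tibble::tibble(year = meta$year + 1L, iterations = it,
                           converged = converged,
                           max_gap_km2 = max(abs(gaps)))
  attr(report, "gaps") <- setNames(gaps, classes)
  if (!converged) {
    msg <- sprintf("allocation did not converge in year %d (max gap %.1f km2 > %.1f km2)",
                   meta$year + 1L, max(abs(gaps)), tol_km2)
    if (params$on_non_convergence == "error") {
      rlang::abort(msg, class = "lucc_convergence_error", report = report)
    }
    rlang::warn(msg)
  }
  validate_lucc_grid(new_grid)
  list(grid = new_grid, report = report)
}
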