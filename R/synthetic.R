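#' Specification of a synthetic study system
#'
#' Describes a complete synthetic landscape: grid shape, driver recipes of
#' the four driver categories (a smooth agronomic suitability field, a
#' distance-to-infrastructure field, a latitudinal gradient standing in for
#' agrarian-structure contrasts, and a restrictive protected-area mask), the
#' true spatial-lag parameters per class, and the static `others` fraction.
#' All randomness is controlled by `seed`: the same spec yields
#' byte-identical landscapes.
#'
#' @param n_rows,n_cols Grid shape (default 50 x 50).
#' @param seed Integer seed.
#' @param cell_side_km Cell side in km (default 10).
#' @param others_pct Static `others` percent per cell (default 7).
#' @param rho True autoregressive coefficient of the latent class scores
#'   (default 0.5).
#' @param sigma True innovation standard deviation (default 0.1).
#' @param beta Driver loading matrix (classes x drivers); a fixed default
#'   separates the six classes along the three drivers.
#' @param temperature Softmax temperature mapping latent scores to
#'   fractions (default 0.75; lower = more dominant classes).
#' @param mask_quantile Smooth-field quantile above which cells belong to
#'   the protected-area mask (default 0.85).
#' @param year Year stamp of generated landscapes (default 2000).
#' @return A `lucc_synthetic_spec` list.
#' @export
synthetic_spec <- function(n_rows = 50, n_cols = 50, seed = 1,
                           cell_side_km = 10, others_pct = 7,
                           rho = 0.5, sigma = 0.1, beta = NULL,
                           temperature = 0.75, mask_quantile = 0.85,
                           year = 2000L) {
  if (abs(rho) >= 1) stop_config("|rho| must be < 1 for row-standardised weights")
  drivers <- c("suitability", "dist_feature", "grad_ns")
  if (is.null(beta)) {
    beta <- matrix(c( 1.0,  0.5,  0.8,
                     -0.5,  0.8, -0.6,
                      0.6, -0.7,  0.2,
                      0.9, -0.9, -0.4,
                     -0.8,  0.3,  0.6,
                      0.2,  0.4, -0.9),
                   nrow = 6, byrow = TRUE,
                   dimnames = list(lucc_class_names(), drivers))
  }
  structure(list(n_rows = n_rows, n_cols = n_cols, seed = as.integer(seed),
                 cell_side_km = cell_side_km, others_pct = others_pct,
                 rho = rho, sigma = sigma, beta = beta, drivers = drivers,
                 temperature = temperature, mask_quantile = mask_quantile,
                 year = as.integer(year)),
            class = "lucc_synthetic_spec")
}

#' Simulate a spatial-lag field
#'
#' Draws `y = (I - rho W)^{-1} (X beta + eps)` with `eps ~ N(0, sigma^2 I)`
#' over the valid cells of a lattice: the exact data-generating process of
#' the spatial-lag regression, used for landscapes and for estimator
#' recovery experiments.
#'
#' @param weights A [lucc_weights()].
#' @param X Optional driver matrix over valid cells (no intercept column);
#'   omitted means a pure noise process.
#' @param beta Coefficients matching `ncol(X)` (prepend the intercept by
#'   adding a constant column yourself if needed).
#' @param rho Autoregressive coefficient inside the admissible interval.
#' @param sigma Innovation standard deviation.
#' @return Numeric vector over all cells (NA for invalid cells).
#' @export
gen_sar_field <- function(weights, X = NULL, beta = NULL, rho = 0.5,
                          sigma = 1) {
  iv <- rho_interval(weights)
  if (rho <= iv[1] || rho >= iv[2]) {
    stop_config(sprintf("rho must lie in (%.4f, %.4f)", iv[1], iv[2]))
  }
  valid <- weights$valid
  nv <- sum(valid)
  mu <- if (is.null(X)) rep(0, nv) else as.numeric(as.matrix(X) %*% beta)
  eps <- rnorm(nv, 0, sigma)
  Wv <- weights$W[valid, valid, drop = FALSE]
  A <- Matrix::Diagonal(nv) - rho * Wv
  yv <- as.numeric(Matrix::solve(A, mu + eps))
  out <- rep(NA_real_, length(valid))
  out[valid] <- yv
  out
}

standardize <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(x - mean(x))
  (x - mean(x)) / s
}

# Driver fields for a synthetic landscape (over an all-valid lattice).
gen_drivers <- function(spec, grid, weights) {
  nr <- spec$n_rows; nc <- spec$n_cols
  suit <- standardize(gen_sar_field(weights, rho = 0.85, sigma = 1))
  feats <- matrix(FALSE, nr, nc)
  feats[cbind(sample.int(nr, 8, replace = TRUE),
              sample.int(nc, 8, replace = TRUE))] <- TRUE
  dist <- aggregate_min_distance(feats, grid)$distance_km
  grad <- grid$row / max(grid$row, 1)
  tibble::tibble(suitability = suit,
                 dist_feature = standardize(dist),
                 grad_ns = standardize(grad))
}

#' Generate a synthetic landscape
#'
#' Builds a complete [lucc_grid()]: driver fields, a protected-area mask,
#' and per-class fractions obtained by drawing one latent spatial-lag score
#' per class from the true process and mapping the standardised scores
#' through a temperature-controlled softmax onto `100 - others_pct`. The
#' softmax guarantees the compositional invariants while preserving the
#' monotone effect of each driver on its classes.
#'
#' @param spec A [synthetic_spec()].
#' @return A [lucc_grid()] with drivers `suitability`, `dist_feature`,
#'   `grad_ns` and mask `protected`.
#' @export
gen_landscape <- function(spec) {
  set.seed(spec$seed)
  cells <- tidyr::expand_grid(row = 0:(spec$n_rows - 1),
                              col = 0:(spec$n_cols - 1))
  base <- lucc_grid(dplyr::mutate(cells, forest_vegetation = 93, others = 7),
                    cell_side_km = spec$cell_side_km, year = spec$year,
                    classes = "forest_vegetation", validate = FALSE)
  w <- lucc_weights(base, "queen")
  drv <- gen_drivers(spec, base, w)
  X <- as.matrix(drv)
  classes <- rownames(spec$beta)
  z <- vapply(classes, function(cl) {
    standardize(gen_sar_field(w, X = X, beta = spec$beta[cl, ],
                              rho = spec$rho, sigma = spec$sigma))
  }, numeric(nrow(cells)))
  ez <- exp(z / spec$temperature)
  frac <- ez / rowSums(ez) * (100 - spec$others_pct)
  colnames(frac) <- classes
  blob <- standardize(gen_sar_field(w, rho = 0.85, sigma = 1))
  protected <- as.numeric(blob > quantile(blob, spec$mask_quantile))
  cells <- dplyr::bind_cols(cells, tibble::as_tibble(frac), drv,
                            tibble::tibble(protected = protected))
  cells$others <- spec$others_pct
  lucc_grid(cells, cell_side_km = spec$cell_side_km, year = spec$year,
            classes = classes, drivers = spec$drivers, masks = "protected")
}

#' Scenario-shaped demand endpoints for a synthetic landscape
#'
#' Takes the national 2000-to-2050 area changes of a published scenario,
#' rescales them to the synthetic study area (preserving exact national
#' area conservation), and anchors them at the landscape's actual class
#' totals, so a forward run is demand-feasible and has the scenario's
#' direction-of-change pattern.
#'
#' @param grid A synthetic [lucc_grid()].
#' @param scenario `"ssp1"`, `"ssp2"` or `"ssp3"`.
#' @param initial_year,final_year Period bounds (default 2000--2050).
#' @param scale Extra multiplier on the rescaled changes (default 1).
#' @return An endpoint table (see [demand_endpoint()]).
#' @export
synthetic_endpoints <- function(grid, scenario = "ssp2",
                                initial_year = 2000, final_year = 2050,
                                scale = 1) {
  a0 <- grid_areas(grid)
  t4 <- scenario_endpoints(scenario)
  t4 <- t4[match(a0$class, t4$class), ]
  # scenario annual change, rescaled to the synthetic area and horizon
  delta <- (t4$final_area_km2 - t4$initial_area_km2) / (t4$final_year - t4$initial_year) *
    (final_year - initial_year) *
    (sum(a0$area_km2) / sum(t4$initial_area_km2)) * scale
  delta <- delta - sum(delta) / length(delta)   # exact national conservation
  final <- a0$area_km2 + delta
  if (any(final < 0)) {
    stop_config("scenario-shaped change exceeds the synthetic class areas; lower `scale`")
  }
  tibble::tibble(class = a0$class,
                 initial_year = as.integer(initial_year),
                 final_year = as.integer(final_year),
                 initial_area_km2 = a0$area_km2,
                 final_area_km2 = final)
}

#' Generate an observed calibration pair from a known forward process
#'
#' Produces a `(t0, tf)` pair of maps the way calibration data arise:
#' `t0` is a synthetic landscape; models are calibrated on it; and `tf` is
#' obtained by running the scenario engine forward under scenario-shaped
#' demands. The pair gives ground truth for calibration-recovery and for
#' validation-metric tests (comparing a simulation against `tf` as the
#' "observed" map).
#'
#' @param spec A [synthetic_spec()].
#' @param years Number of simulated years between t0 and tf (default 10).
#' @param scenario Scenario shape for the demands (default `"ssp2"`).
#' @param scale Demand-change multiplier (see [synthetic_endpoints()]).
#' @param allocation An [allocation_params()].
#' @return A list with `t0`, `tf` ([lucc_grid()]s), `models`, `weights`,
#'   `endpoints`, `run` and the `spec`.
#' @export
gen_observed_pair <- function(spec, years = 10, scenario = "ssp2", scale = 1,
                              allocation = allocation_params()) {
  t0 <- gen_landscape(spec)
  w <- lucc_weights(t0, "queen")
  classes <- grid_meta(t0)$classes
  models <- purrr::map(classes, function(cl) {
    fit_potential_model(t0, cl, spec$drivers, w)
  })
  names(models) <- classes
  eps <- synthetic_endpoints(t0, scenario,
                             initial_year = spec$year,
                             final_year = spec$year + years, scale = scale)
  cfg <- scenario_config(paste0("synthetic-", scenario), eps,
                         allocation = allocation,
                         years = spec$year:(spec$year + years),
                         snapshot_years = c(spec$year, spec$year + years),
                         seed = spec$seed)
  run <- run_scenario(t0, cfg, models, w)
  list(t0 = t0, tf = run$snapshots[[as.character(spec$year + years)]],
       models = models, weights = w, endpoints = eps, run = run, spec = spec)
}
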