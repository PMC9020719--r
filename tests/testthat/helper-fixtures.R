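# Fixtures built in code: small uniform grids, constructed potential models.

# A grid whose valid cells all share the same composition (percent).
uniform_grid <- function(n_rows, n_cols, fractions, others = NULL,
                         year = 2000L, cell_side_km = 10, valid = NULL) {
  others <- others %||% (100 - sum(fractions))
  cells <- tidyr::expand_grid(row = 0:(n_rows - 1), col = 0:(n_cols - 1))
  for (cl in names(fractions)) cells[[cl]] <- fractions[[cl]]
  cells$others <- others
  if (!is.null(valid)) cells$valid <- valid
  lucc_grid(cells, cell_side_km = cell_side_km, year = year,
            classes = names(fractions))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A hand-built spatial-lag "model" with known coefficients (no fitting).
const_model <- function(class, intercept, rho = 0, drivers = character(),
                        beta = NULL) {
  coefs <- c(`(Intercept)` = intercept, beta)
  structure(list(class_id = class, response = class, drivers = drivers,
                 coefficients = coefs, rho = rho, rho_fixed = TRUE,
                 sigma2 = 1e-4,
                 std_errors = setNames(rep(NA_real_, length(coefs) + 1),
                                       c(names(coefs), "rho")),
                 p_values = setNames(rep(NA_real_, length(coefs) + 1),
                                     c(names(coefs), "rho")),
                 pseudo_r2 = NA_real_, loglik = NA_real_, aic = NA_real_,
                 n = NA_integer_, k = length(coefs) + 1,
                 interval = c(-1, 1), meets_p_filter = NA, meets_r2 = NA),
            class = "lucc_slm")
}

# Constant potential surface for one class over a grid.
const_potential <- function(grid, class, value, year = NULL) {
  tibble::tibble(cell_id = grid$cell_id, row = grid$row, col = grid$col,
                 class = class,
                 year = as.integer(year %||% (grid_meta(grid)$year + 1L)),
                 potential = ifelse(grid$valid, value, NA_real_))
}

# Dense brute-force log-likelihood of the spatial-lag model at given
# parameters (independent of the package's concentrated-likelihood path).
brute_slm_loglik <- function(y, X, W_dense, beta, rho, sigma2) {
  n <- length(y)
  e <- y - rho * as.numeric(W_dense %*% y) - as.numeric(X %*% beta)
  ld <- as.numeric(determinant(diag(n) - rho * W_dense, logarithm = TRUE)$modulus)
  -n / 2 * log(2 * pi * sigma2) + ld - sum(e^2) / (2 * sigma2)
}

# Brute-force multi-resolution similarity: explicit double loop over blocks.
brute_ns <- function(real_t0, real_tf, sim_tf, w) {
  nr <- nrow(real_t0); nc <- ncol(real_t0)
  s_abs_diff <- 0; s_abs_real <- 0
  for (bi in seq_len(ceiling(nr / w))) {
    for (bj in seq_len(ceiling(nc / w))) {
      rows <- ((bi - 1) * w + 1):min(bi * w, nr)
      cols <- ((bj - 1) * w + 1):min(bj * w, nc)
      dr <- sum(real_tf[rows, cols] - real_t0[rows, cols])
      ds <- sum(sim_tf[rows, cols] - real_t0[rows, cols])
      s_abs_diff <- s_abs_diff + abs(ds - dr)
      s_abs_real <- s_abs_real + abs(dr)
    }
  }
  if (s_abs_real == 0) return(if (s_abs_diff == 0) 100 else 0)
  (1 - s_abs_diff / (2 * s_abs_real)) * 100
}
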