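#' Screen candidate drivers by pairwise Spearman correlation
#'
#' Keeps a subset of candidate driver fields in which no retained pair has
#' absolute Spearman correlation above `threshold` (default 0.60). Pruning
#' is greedy and deterministic: pairs are visited in descending absolute
#' correlation; from each offending pair the member with the larger mean
#' absolute correlation to the other remaining candidates is dropped (ties
#' resolved toward the driver more correlated with `response`, then toward
#' the earlier-listed driver).
#'
#' @param data A data frame of per-cell fields (a [lucc_grid()] works); rows
#'   with `valid = FALSE` are ignored when present.
#' @param candidates Character vector of candidate column names (>= 1).
#' @param response Optional response column name used only to break ties.
#' @param threshold Maximum retained absolute correlation (default 0.60).
#' @return Character vector of retained driver names (never empty).
#' @export
spearman_screen <- function(data, candidates, response = NULL, threshold = 0.60) {
  if (length(candidates) < 1) stop_config("at least one candidate is required")
  keep_rows <- if ("valid" %in% names(data)) data$valid else rep(TRUE, nrow(data))
  vals <- as.matrix(data[keep_rows, candidates, drop = FALSE])
  if (length(candidates) == 1) return(candidates)
  if (nrow(vals) < 3) stop_config("need at least 3 valid cells to screen drivers")
  const <- apply(vals, 2, function(x) sd(x) == 0 || !is.finite(sd(x)))
  if (any(const)) {
    rlang::warn(sprintf("constant candidate field(s) %s: correlations treated as 0",
                        paste(candidates[const], collapse = ", ")))
  }
  R <- suppressWarnings(cor(vals, method = "spearman"))
  R[!is.finite(R)] <- 0
  diag(R) <- 0
  resp_cor <- if (!is.null(response)) {
    r <- suppressWarnings(cor(vals, data[[response]][keep_rows],
                              method = "spearman"))
    r[!is.finite(r)] <- 0
    abs(as.numeric(r))
  } else rep(0, length(candidates))
  names(resp_cor) <- candidates
  keep <- candidates
  repeat {
    Rk <- abs(R[keep, keep, drop = FALSE])
    if (length(keep) < 2 || max(Rk) <= threshold) break
    ij <- which(Rk == max(Rk), arr.ind = TRUE)[1, ]
    a <- keep[ij[1]]; b <- keep[ij[2]]
    others <- setdiff(keep, c(a, b))
    ma <- if (length(others)) mean(abs(R[a, others])) else 0
    mb <- if (length(others)) mean(abs(R[b, others])) else 0
    drop <- if (ma > mb) a
      else if (mb > ma) b
      else if (resp_cor[a] != resp_cor[b]) c(a, b)[which.min(resp_cor[c(a, b)])]
      else c(a, b)[which.max(match(c(a, b), candidates))]
    keep <- setdiff(keep, drop)
  }
  keep
}

#' Fit a spatial-lag regression by maximum likelihood
#'
#' Fits `y = rho W y + X beta + eps`, `eps ~ N(0, sigma^2 I)`, on the valid
#' cells of the lattice. The likelihood is concentrated in `rho` and
#' maximised over the admissible interval given by the extreme eigenvalues
#' of `W`; the Jacobian term `log|I - rho W|` is evaluated exactly from the
#' (cached) eigenvalues, so small-grid fits are reproducible to machine
#' precision. Standard errors come from the inverse numerical Hessian of the
#' full log-likelihood at the optimum.
#'
#' @param data A data frame of per-cell fields aligned with `weights`
#'   (row-major cell order); a [lucc_grid()] works directly.
#' @param response Name of the response column. For land-use modelling this
#'   is a class fraction scaled to `[0, 1]` (see [fit_potential_model()]).
#' @param drivers Character vector of driver column names.
#' @param weights A [lucc_weights()] built on the same grid.
#' @param rho Optional fixed autoregressive coefficient; `rho = 0` reduces
#'   the fit to ordinary least squares.
#' @param tol Convergence tolerance of the one-dimensional `rho` search.
#' @return A `lucc_slm` object with coefficients, `rho`, `sigma2`,
#'   p-values, pseudo-R2 (squared correlation of observed and predicted
#'   response), log-likelihood and AIC. Supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
fit_spatial_lag <- function(data, response, drivers, weights, rho = NULL,
                            tol = 1e-8) {
  valid <- weights$valid
  if (nrow(data) != length(valid)) {
    stop_dimension("`data` rows must match the weights lattice")
  }
  y <- as.numeric(data[[response]])[valid]
  X <- cbind(`(Intercept)` = 1,
             as.matrix(data[valid, drivers, drop = FALSE]))
  storage.mode(X) <- "double"
  n <- length(y); p <- ncol(X)
  if (n <= p + 1) stop_config("more parameters than valid cells")
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
    rlang::abort(sprintf("collinear driver column(s): %s",
                         paste(bad, collapse = ", ")),
                 class = "lucc_collinearity_error", columns = bad)
  }
  Wv <- weights$W[valid, valid, drop = FALSE]
  Wy <- as.numeric(Wv %*% y)
  e0 <- qr.resid(qx, y)
  ed <- qr.resid(qx, Wy)
  ev <- weights_eigenvalues(weights)
  interval <- rho_interval(weights)
  log_jac <- function(r) sum(log1p(-r * ev))
  conc_ll <- function(r) {
    e <- e0 - r * ed
    s2 <- sum(e^2) / n
    -n / 2 * (log(2 * pi * s2) + 1) + log_jac(r)
  }
  fixed <- !is.null(rho)
  if (fixed) {
    if (rho <= interval[1] || rho >= interval[2]) {
      stop_config(sprintf("rho must lie in (%.4f, %.4f)", interval[1], interval[2]))
    }
    rho_hat <- rho
  } else {
    pad <- 1e-6 * diff(interval)
    opt <- optimize(conc_ll, interval = c(interval[1] + pad, interval[2] - pad),
                    maximum = TRUE, tol = tol)
    rho_hat <- opt$maximum
  }
  beta <- qr.coef(qx, y - rho_hat * Wy)
  e <- e0 - rho_hat * ed
  sigma2 <- sum(e^2) / n
  loglik <- conc_ll(rho_hat)
  k <- p + 1 + as.integer(!fixed)            # beta, sigma2, and rho if free
  aic <- 2 * k - 2 * loglik
  yhat <- rho_hat * Wy + as.numeric(X %*% beta)
  pseudo_r2 <- suppressWarnings(cor(y, yhat)^2)
  negll <- function(theta) {
    b <- theta[seq_len(p)]
    r <- if (fixed) rho_hat else theta[p + 1]
    ls2 <- theta[length(theta)]
    res <- y - r * Wy - as.numeric(X %*% b)
    -(-n / 2 * (log(2 * pi) + ls2) + log_jac(r) -
        sum(res^2) / (2 * exp(ls2)))
  }
  theta <- if (fixed) c(beta, log(sigma2)) else c(beta, rho_hat, log(sigma2))
  se <- rep(NA_real_, p + 1)
  names(se) <- c(colnames(X), "rho")
  vc <- try(solve(pracma::hessian(negll, theta)), silent = TRUE)
  if (!inherits(vc, "try-error") && all(is.finite(diag(vc))) &&
      all(diag(vc) >= 0)) {
    se[seq_len(p)] <- sqrt(diag(vc)[seq_len(p)])
    if (!fixed) se["rho"] <- sqrt(diag(vc)[p + 1])
  } else {
    rlang::warn("could not invert the likelihood Hessian; standard errors are NA")
  }
  est <- c(beta, rho = rho_hat)
  zval <- est / se
  pval <- 2 * pnorm(-abs(zval))
  structure(list(
    class_id = NULL, response = response, drivers = drivers,
    coefficients = beta, rho = rho_hat, rho_fixed = fixed, sigma2 = sigma2,
    std_errors = se, p_values = pval, pseudo_r2 = pseudo_r2,
    loglik = loglik, aic = aic, n = n, k = k, interval = interval,
    meets_p_filter = NA, meets_r2 = NA), class = "lucc_slm")
}

#' @export
print.lucc_slm <- function(x, ...) {
  cat(sprintf("<lucc_slm>%s spatial-lag fit, n = %d\n",
              if (!is.null(x$class_id)) paste0(" ", x$class_id), x$n))
  cat(sprintf("  rho = %.4f%s  sigma2 = %.3g  pseudo-R2 = %.3f  AIC = %.2f\n",
              x$rho, if (x$rho_fixed) " (fixed)" else "", x$sigma2,
              x$pseudo_r2, x$aic))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Fit the change-potential regression for one land-use class
#'
#' Convenience wrapper around [fit_spatial_lag()]: the response is the
#' class's cell fraction rescaled to `[0, 1]`, so that the potential surface
#' (prediction minus current fraction) is naturally bounded in `[-1, 1]`.
#'
#' @param grid A [lucc_grid()].
#' @param class Land-use class id (a fraction column of `grid`).
#' @param drivers Driver column names.
#' @param weights A [lucc_weights()] on the same grid.
#' @param ... Passed to [fit_spatial_lag()].
#' @return A `lucc_slm` with `class_id` set.
#' @export
fit_potential_model <- function(grid, class, drivers, weights, ...) {
  dat <- tibble::as_tibble(grid)
  dat$.response <- dat[[class]] / 100
  m <- fit_spatial_lag(dat, ".response", drivers, weights, ...)
  m$response <- class
  m$class_id <- class
  m
}

#' Select a potential model among candidate driver sets
#'
#' Fits one spatial-lag model per candidate specification and returns the
#' minimum-AIC model among those whose driver coefficients are all
#' significant at `p_max`. If no specification passes the significance
#' filter, the overall minimum-AIC model is returned flagged non-compliant,
#' with a warning. Whether the pseudo-R2 reaches `r2_min` is recorded as a
#' flag, not enforced: the R2 criterion applies on average across classes.
#'
#' @param grid A [lucc_grid()].
#' @param class Land-use class id.
#' @param candidates List of character vectors, one candidate driver set per
#'   specification.
#' @param weights A [lucc_weights()].
#' @param p_max Significance level for driver coefficients (default 0.05).
#' @param r2_min Pseudo-R2 reference level (default 0.75).
#' @param ... Passed to [fit_potential_model()].
#' @return The selected `lucc_slm`, with `meets_p_filter` and `meets_r2`
#'   flags and the per-candidate `selection_table` attached.
#' @export
select_model <- function(grid, class, candidates, weights,
                         p_max = 0.05, r2_min = 0.75, ...) {
  if (length(candidates) < 1) stop_config("at least one candidate set is required")
  if (is.character(candidates)) candidates <- list(candidates)
  fits <- purrr::map(candidates, function(drv) {
    fit_potential_model(grid, class, drv, weights, ...)
  })
  passes <- purrr::map_lgl(fits, function(m) {
    pv <- m$p_values[m$drivers]
    all(is.finite(pv)) && all(pv < p_max)
  })
  aics <- purrr::map_dbl(fits, "aic")
  pick <- if (any(passes)) which(passes)[which.min(aics[passes])] else {
    rlang::warn("no candidate passes the significance filter; returning the minimum-AIC model flagged non-compliant")
    which.min(aics)
  }
  best <- fits[[pick]]
  best$meets_p_filter <- passes[pick]
  best$meets_r2 <- isTRUE(best$pseudo_r2 > r2_min)
  best$selection_table <- tibble::tibble(
    spec = seq_along(fits),
    drivers = purrr::map_chr(candidates, paste, collapse = "+"),
    aic = aics, pseudo_r2 = purrr::map_dbl(fits, "pseudo_r2"),
    passes_p = passes, selected = seq_along(fits) == pick)
  best
}

#' Per-cell change potential for one class and year
#'
#' The potential is the regression prediction minus the current fraction,
#' `Pot = clamp(rho W y + X beta - y, -1, 1)`, with `y` the previous year's
#' class fraction in `[0, 1]` units. Prediction is conditional on the
#' observed neighbouring fractions, so potentials stay dynamic: they are
#' recomputed from the current map every simulated year.
#'
#' @param model A fitted `lucc_slm` with `class_id` set (or pass `class`).
#' @param grid The current [lucc_grid()] (year t-1 state).
#' @param weights A [lucc_weights()] on the same grid.
#' @param class Land-use class id; defaults to `model$class_id`.
#' @param year Year stamp for the surface; defaults to grid year + 1.
#' @return A tibble `cell_id`, `row`, `col`, `class`, `year`, `potential`
#'   with potentials in `[-1, 1]` (NA outside the study region).
#' @export
compute_potential <- function(model, grid, weights, class = model$class_id,
                              year = NULL) {
  if (is.null(class)) stop_config("`class` must be given when the model has no class_id")
  missing <- setdiff(model$drivers, names(grid))
  if (length(missing) > 0) {
    stop_config(sprintf("driver(s) missing from grid: %s",
                        paste(missing, collapse = ", ")))
  }
  meta <- grid_meta(grid)
  year <- year %||% (meta$year + 1L)
  valid <- grid$valid
  y <- grid[[class]] / 100
  yv <- y[valid]
  Wv <- weights$W[valid, valid, drop = FALSE]
  X <- cbind(1, as.matrix(grid[valid, model$drivers, drop = FALSE]))
  yhat <- model$rho * as.numeric(Wv %*% yv) +
    as.numeric(X %*% model$coefficients)
  pot <- rep(NA_real_, nrow(grid))
  pot[valid] <- clamp(yhat - yv, -1, 1)
  tibble::tibble(cell_id = grid$cell_id, row = grid$row, col = grid$col,
                 class = class, year = as.integer(year), potential = pot)
}

#' Apply scenario restriction masks to a potential surface
#'
#' Restriction masks (protected areas, settlements, ...) damp positive
#' expansion potential of restricted classes: in a masked cell the positive
#' potential is multiplied by `1 - protection_level * mask`, with mask
#' values in `[0, 1]`. Negative potentials (regeneration / contraction) are
#' never affected. The schedule is a table of entries
#' `(year_from, mask, class_group, protection_level)`; for each mask and
#' class group the entry with the latest `year_from <= year` is active,
#' which encodes scenario premises such as protection weakening after 2030.
#'
#' @param surface A potential tibble from [compute_potential()] (one or more
#'   classes bound together).
#' @param grid The [lucc_grid()] carrying the mask columns.
#' @param schedule A tibble with columns `year_from`, `mask`,
#'   `class_group` (`"anthropic"`, `"all"`, or a class id) and
#'   `protection_level` in `[0, 1]`.
#' @param year Simulation year being restricted.
#' @return The surface with damped potentials.
#' @export
apply_restrictions <- function(surface, grid, schedule, year) {
  if (is.null(schedule) || nrow(schedule) == 0) return(surface)
  req <- c("year_from", "mask", "class_group", "protection_level")
  if (!all(req %in% names(schedule))) {
    stop_config(sprintf("schedule must have columns: %s", paste(req, collapse = ", ")))
  }
  if (any(schedule$protection_level < 0 | schedule$protection_level > 1)) {
    stop_validation("protection_level must lie in [0, 1]")
  }
  active <- schedule |>
    dplyr::filter(.data$year_from <= year) |>
    dplyr::group_by(.data$mask, .data$class_group) |>
    dplyr::slice_max(.data$year_from, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  if (nrow(active) == 0) return(surface)
  for (i in seq_len(nrow(active))) {
    mname <- active$mask[i]
    if (!mname %in% names(grid)) stop_config(sprintf("mask `%s` not found in grid", mname))
    m <- as.numeric(grid[[mname]])
    if (any(m < 0 | m > 1, na.rm = TRUE)) {
      stop_validation(sprintf("mask `%s` has values outside [0, 1]", mname))
    }
    cls <- switch(active$class_group[i],
                  anthropic = lucc_anthropic_classes(),
                  all = unique(surface$class),
                  active$class_group[i])
    damp <- 1 - active$protection_level[i] * m[match(surface$cell_id, grid$cell_id)]
    hit <- surface$class %in% cls & !is.na(surface$potential) & surface$potential > 0
    surface$potential[hit] <- surface$potential[hit] * damp[hit]
  }
  surface
}
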