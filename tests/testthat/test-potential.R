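test_that("Spearman screening prunes correlated candidates deterministically", {
  set.seed(10)
  n <- 400
  d <- tibble::tibble(a = rnorm(n))
  d$b <- d$a                      # identical to a
  d$c <- rnorm(n)                 # independent
  kept <- spearman_screen(d, c("a", "b"))
  expect_length(kept, 1)
  kept2 <- spearman_screen(d, c("a", "c"))
  expect_setequal(kept2, c("a", "c"))
  expect_equal(spearman_screen(d, "a"), "a")
  expect_true(all(abs(suppressWarnings(
    cor(d[spearman_screen(d, c("a", "b", "c"))], method = "spearman")
  )[upper.tri(diag(2))]) <= 0.6))
  d$k <- 1                        # constant field
  expect_warning(spearman_screen(d, c("a", "c", "k")), "constant")
})

test_that("fixing rho at zero reduces the fit to ordinary least squares", {
  set.seed(21)
  g <- uniform_grid(10, 10, c(forest_vegetation = 93))
  g$x1 <- rnorm(100); g$x2 <- runif(100)
  g$y <- 0.3 + 0.5 * g$x1 - 0.2 * g$x2 + rnorm(100, 0, 0.05)
  w <- lucc_weights(g)
  m0 <- fit_spatial_lag(g, "y", c("x1", "x2"), w, rho = 0)
  ols <- lm(y ~ x1 + x2, data = g)
  expect_equal(unname(m0$coefficients), unname(coef(ols)), tolerance = 1e-10)
  # the free fit can only improve the likelihood (nesting)
  m1 <- fit_spatial_lag(g, "y", c("x1", "x2"), w)
  expect_gte(m1$loglik, m0$loglik - 1e-8)
  # and on rho = 0 data its estimates stay close to OLS
  expect_lt(abs(m1$rho), 0.15)
  expect_equal(unname(m1$coefficients[-1]), unname(coef(ols)[-1]),
               tolerance = 0.02)
})

test_that("the concentrated likelihood matches a dense brute-force evaluation", {
  set.seed(33)
  g <- uniform_grid(12, 12, c(forest_vegetation = 93))
  n <- 144
  g$x1 <- rnorm(n)
  w <- lucc_weights(g)
  Wd <- as.matrix(w$W)
  y <- as.numeric(solve(diag(n) - 0.4 * Wd, 0.2 + 0.8 * g$x1 + rnorm(n, 0, 0.1)))
  g$y <- y
  m <- fit_spatial_lag(g, "y", "x1", w)
  # loglik at the reported MLE agrees with the dense formula
  ll_dense <- brute_slm_loglik(y, cbind(1, g$x1), Wd,
                               m$coefficients, m$rho, m$sigma2)
  expect_equal(m$loglik, ll_dense, tolerance = 1e-6)
  # no rho on a fine grid beats the reported optimum
  profile <- sapply(seq(-0.9, 0.95, by = 0.01), function(r) {
    b <- qr.coef(qr(cbind(1, g$x1)), y - r * as.numeric(Wd %*% y))
    e <- y - r * as.numeric(Wd %*% y) - as.numeric(cbind(1, g$x1) %*% b)
    brute_slm_loglik(y, cbind(1, g$x1), Wd, b, r, sum(e^2) / n)
  })
  expect_gte(m$loglik, max(profile) - 1e-6)
  expect_equal(m$aic, 2 * 4 - 2 * m$loglik)
})

test_that("the estimator recovers known parameters on the SAR process", {
  set.seed(99)
  g <- uniform_grid(50, 50, c(forest_vegetation = 93))
  g$x1 <- rnorm(2500)
  w <- lucc_weights(g)
  g$y <- gen_sar_field(w, X = cbind(1, g$x1), beta = c(1, 2),
                       rho = 0.5, sigma = 0.1)
  m <- fit_spatial_lag(g, "y", "x1", w)
  expect_lt(abs(m$rho - 0.5), 0.05)
  expect_lt(abs(m$coefficients["x1"] - 2) / 2, 0.05)
  expect_gt(m$pseudo_r2, 0.9)
  # Wald p-value of a strong effect is tiny
  expect_lt(m$p_values[["x1"]], 1e-6)
})

test_that("collinear drivers are reported by name", {
  g <- uniform_grid(6, 6, c(forest_vegetation = 93))
  g$x1 <- rnorm(36); g$x2 <- 2 * g$x1
  g$y <- rnorm(36)
  w <- lucc_weights(g)
  err <- tryCatch(fit_spatial_lag(g, "y", c("x1", "x2"), w), error = identity)
  expect_s3_class(err, "lucc_collinearity_error")
  expect_match(conditionMessage(err), "x2")
})

test_that("model selection follows AIC among significant specifications", {
  set.seed(5)
  spec <- synthetic_spec(n_rows = 15, n_cols = 15, seed = 5)
  g <- gen_landscape(spec)
  g$noise <- rnorm(nrow(g))
  w <- lucc_weights(g)
  m <- select_model(g, "forest_vegetation",
                    list(c("suitability", "grad_ns"),
                         c("suitability", "grad_ns", "noise")), w)
  # the pure-noise driver cannot buy its AIC penalty back on average;
  # whichever wins must be significant and minimum-AIC among passers
  tab <- m$selection_table
  expect_true(tab$selected[which.min(ifelse(tab$passes_p, tab$aic, Inf))] ||
                !any(tab$passes_p))
  expect_true(is.logical(m$meets_p_filter))
  single <- select_model(g, "forest_vegetation", list("suitability"), w)
  expect_equal(single$drivers, "suitability")
})

test_that("selection falls back to minimum AIC when nothing is significant", {
  set.seed(6)
  g <- uniform_grid(8, 8, c(forest_vegetation = 93))
  g$n1 <- rnorm(64); g$n2 <- rnorm(64)
  g$.y <- rnorm(64, 0.5, 0.01)
  g$forest_vegetation <- 100 * pmin(pmax(g$.y, 0), 0.93)
  g$others <- 100 - g$forest_vegetation
  w <- lucc_weights(g)
  expect_warning(m <- select_model(g, "forest_vegetation",
                                   list("n1", "n2"), w),
                 "significance filter")
  expect_false(m$meets_p_filter)
})

test_that("potentials are the clamped prediction minus the current fraction", {
  g <- uniform_grid(5, 5, c(forest_vegetation = 50, grassland_vegetation = 43))
  w <- lucc_weights(g)
  # equilibrium: prediction equals the current fraction everywhere
  m_eq <- const_model("forest_vegetation", intercept = 0.5, rho = 0)
  pot <- compute_potential(m_eq, g, w)
  expect_equal(pot$potential, rep(0, 25))
  # clamp at +1: huge prediction
  m_hi <- const_model("forest_vegetation", intercept = 1.5, rho = 0)
  expect_equal(compute_potential(m_hi, g, w)$potential, rep(1, 25))
  # rho = 0: surface equals X beta - y
  m_lo <- const_model("grassland_vegetation", intercept = 0.13, rho = 0)
  expect_equal(compute_potential(m_lo, g, w)$potential,
               rep(0.13 - 0.43, 25), tolerance = 1e-12)
  # missing driver is a configuration error
  m_bad <- const_model("forest_vegetation", 0.5, drivers = "absent",
                       beta = c(absent = 1))
  expect_error(compute_potential(m_bad, g, w), class = "lucc_config_error")
})

test_that("restriction masks damp positive anthropic potential only", {
  g <- uniform_grid(4, 4, c(agriculture = 40, forest_vegetation = 53))
  g$pa <- rep(c(1, 0), each = 8)
  surface <- dplyr::bind_rows(
    const_potential(g, "agriculture", 0.4),
    const_potential(g, "forest_vegetation", -0.3))
  sched <- tibble::tibble(year_from = 2000, mask = "pa",
                          class_group = "anthropic", protection_level = 1)
  out <- apply_restrictions(surface, g, sched, 2010)
  ag <- dplyr::filter(out, class == "agriculture")
  expect_true(all(ag$potential[g$pa == 1] == 0))     # fully suppressed
  expect_true(all(ag$potential[g$pa == 0] == 0.4))
  fv <- dplyr::filter(out, class == "forest_vegetation")
  expect_equal(fv$potential, rep(-0.3, 16))          # regeneration untouched
  # protection 0 is the identity
  sched0 <- dplyr::mutate(sched, protection_level = 0)
  expect_equal(apply_restrictions(surface, g, sched0, 2010)$potential,
               surface$potential)
  # a schedule step down in protection raises masked-cell potential
  sched2 <- tibble::tibble(year_from = c(2000, 2030), mask = "pa",
                           class_group = "anthropic",
                           protection_level = c(1, 0.3))
  p2029 <- dplyr::filter(apply_restrictions(surface, g, sched2, 2029),
                         class == "agriculture")$potential
  p2030 <- dplyr::filter(apply_restrictions(surface, g, sched2, 2030),
                         class == "agriculture")$potential
  expect_true(all(p2030[g$pa == 1] > p2029[g$pa == 1]))
  # invalid mask values are rejected
  g$pa[1] <- 2
  expect_error(apply_restrictions(surface, g, sched, 2010),
               class = "lucc_validation_error")
})

test_that("tidy and glance expose the fit in broom form", {
  set.seed(11)
  g <- uniform_grid(8, 8, c(forest_vegetation = 93))
  g$x1 <- rnorm(64)
  g$y <- 0.4 + 0.2 * g$x1 + rnorm(64, 0, 0.05)
  w <- lucc_weights(g)
  m <- fit_spatial_lag(g, "y", "x1", w)
  td <- generics::tidy(m)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_true("rho" %in% td$term)
  gl <- generics::glance(m)
  expect_equal(gl$nobs, 64)
  expect_equal(gl$AIC, m$aic)
})
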