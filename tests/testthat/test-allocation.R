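test_that("within-cell competition scales the oversubscribed side", {
  # already balanced: untouched
  expect_equal(unname(rebalance_cell(c(a = 40, b = 40, c = 13),
                                     c(10, -10, 0), frozen = 7)),
               c(10, -10, 0))
  # gains (+10, +10) vs losses (-5): gains scaled to (+2.5, +2.5)
  expect_equal(unname(rebalance_cell(c(a = 40, b = 40, c = 13),
                                     c(10, 10, -5), frozen = 7)),
               c(2.5, 2.5, -5))
  # all-zero identity
  expect_equal(unname(rebalance_cell(c(a = 40, b = 40, c = 13),
                                     c(0, 0, 0), frozen = 7)),
               c(0, 0, 0))
  # no loss available: gains collapse to zero
  expect_equal(unname(rebalance_cell(c(a = 40, b = 53), c(10, 0), frozen = 7)),
               c(0, 0))
})

test_that("competition respects bounds and zero-sum on random cells", {
  set.seed(14)
  for (i in 1:200) {
    k <- sample(2:6, 1)
    frozen <- runif(1, 0, 20)
    fr <- runif(k); fr <- fr / sum(fr) * (100 - frozen)
    dl <- runif(k, -30, 30)
    out <- rebalance_cell(fr, dl, frozen)
    expect_lt(abs(sum(out)), 1e-9)
    expect_true(all(fr + out >= -1e-9))
    expect_true(all(fr + out <= 100 - frozen + 1e-9))
    # adjusted deltas never exceed requests in magnitude or flip sign
    expect_true(all(abs(out) <= abs(dl) + 1e-9))
    expect_true(all(out * dl >= -1e-12))
  }
})

test_that("allocation converges instantly when demand equals current areas", {
  g <- uniform_grid(6, 6, c(forest_vegetation = 50, agriculture = 43))
  pots <- dplyr::bind_rows(const_potential(g, "forest_vegetation", 0.1),
                           const_potential(g, "agriculture", -0.1))
  demand <- grid_areas(g)
  out <- allocate_year(g, pots, demand)
  expect_true(out$report$converged)
  expect_equal(out$report$iterations, 1L)
  expect_equal(as.matrix(out$grid[, c("forest_vegetation", "agriculture")]),
               as.matrix(g[, c("forest_vegetation", "agriculture")]))
  expect_equal(grid_meta(out$grid)$year, 2001L)
})

test_that("uniform potential and headroom spread change uniformly", {
  g <- uniform_grid(10, 10, c(forest_vegetation = 50, agriculture = 43))
  pots <- dplyr::bind_rows(const_potential(g, "forest_vegetation", -0.05),
                           const_potential(g, "agriculture", 0.05))
  # move 500 km2 (out of 10,000) from forest to agriculture
  demand <- tibble::tibble(class = c("forest_vegetation", "agriculture"),
                           area_km2 = c(4500, 4800))
  out <- allocate_year(g, pots, demand)
  expect_true(out$report$converged)
  a <- grid_areas(out$grid)
  tol <- 0.005 * total_area_km2(g)
  expect_lt(abs(a$area_km2[a$class == "agriculture"] - 4800), tol)
  # symmetry: every cell receives the same delta
  dag <- out$grid$agriculture - g$agriculture
  expect_lt(diff(range(dag)), 1e-9)
  expect_equal(dag, -(out$grid$forest_vegetation - g$forest_vegetation))
})

test_that("the frozen class is bit-identical through allocation", {
  set.seed(2)
  g <- uniform_grid(8, 8, c(forest_vegetation = 60, agriculture = 33))
  pots <- dplyr::bind_rows(
    const_potential(g, "forest_vegetation", 0) |>
      dplyr::mutate(potential = rnorm(64, 0, 0.05)),
    const_potential(g, "agriculture", 0) |>
      dplyr::mutate(potential = rnorm(64, 0, 0.05)))
  demand <- tibble::tibble(class = c("forest_vegetation", "agriculture"),
                           area_km2 = c(60 * 64 - 150, 33 * 64 + 150))
  out <- allocate_year(g, pots, demand)
  expect_identical(out$grid$others, g$others)
  sums <- rowSums(as.matrix(
    out$grid[, c("forest_vegetation", "agriculture", "others")]))
  expect_true(all(abs(sums - 100) < 1e-6))
})

test_that("a growing class with no positive potential cannot converge under the literal mechanism", {
  g <- uniform_grid(6, 6, c(forest_vegetation = 50, agriculture = 43))
  pots <- dplyr::bind_rows(const_potential(g, "forest_vegetation", 0.02),
                           const_potential(g, "agriculture", -0.02))
  # agriculture must grow but its potential is negative everywhere
  demand <- tibble::tibble(class = c("forest_vegetation", "agriculture"),
                           area_km2 = c(50 * 36 - 300, 43 * 36 + 300))
  params <- allocation_params(pressure_step = 0, max_iterations = 50)
  err <- tryCatch(allocate_year(g, pots, demand, params), error = identity)
  expect_s3_class(err, "lucc_convergence_error")
  expect_s3_class(err$report, "tbl_df")
  expect_false(err$report$converged)
  # with warning-mode the degraded grid is still returned
  params_w <- allocation_params(pressure_step = 0, max_iterations = 50,
                                on_non_convergence = "warn")
  expect_warning(out <- allocate_year(g, pots, demand, params_w),
                 "did not converge")
  expect_s3_class(out$grid, "lucc_grid")
  # the demand-pressure offset recruits cells and satisfies the demand
  out2 <- allocate_year(g, pots, demand, allocation_params())
  expect_true(out2$report$converged)
})

test_that("raising one cell's potential never lowers its allocated gain", {
  set.seed(8)
  g <- uniform_grid(8, 8, c(forest_vegetation = 50, agriculture = 43))
  base_pot <- runif(64, 0.01, 0.1)
  mk <- function(p_ag) dplyr::bind_rows(
    const_potential(g, "forest_vegetation", -0.05),
    const_potential(g, "agriculture", 0) |> dplyr::mutate(potential = p_ag))
  demand <- tibble::tibble(class = c("forest_vegetation", "agriculture"),
                           area_km2 = c(50 * 64 - 400, 43 * 64 + 400))
  g1 <- allocate_year(g, mk(base_pot), demand)$grid
  bumped <- base_pot; bumped[17] <- bumped[17] * 3
  g2 <- allocate_year(g, mk(bumped), demand)$grid
  expect_gte(g2$agriculture[17] - g$agriculture[17],
             g1$agriculture[17] - g$agriculture[17] - 1e-9)
})

test_that("mismatched total demand is rejected", {
  g <- uniform_grid(4, 4, c(forest_vegetation = 93))
  pots <- const_potential(g, "forest_vegetation", 0.1)
  expect_error(allocate_year(g, pots, c(forest_vegetation = 93 * 16 + 500)),
               "differs from current", class = "lucc_config_error")
  expect_error(allocate_year(g, pots, tibble::tibble(class = "agriculture",
                                                     area_km2 = 1)),
               class = "lucc_config_error")
})
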