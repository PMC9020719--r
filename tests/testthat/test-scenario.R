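test_that("a constant-demand scenario leaves the landscape unchanged", {
  g <- uniform_grid(6, 6, c(forest_vegetation = 50, grassland_vegetation = 20,
                            planted_pasture = 6, agriculture = 6,
                            mosaic_of_occupation = 6, forestry = 5))
  w <- lucc_weights(g)
  a0 <- grid_areas(g)
  eps <- tibble::tibble(class = a0$class, initial_year = 2000L,
                        final_year = 2005L,
                        initial_area_km2 = a0$area_km2,
                        final_area_km2 = a0$area_km2)
  models <- lapply(setNames(a0$class, a0$class), function(cl) {
    const_model(cl, intercept = 0.2, rho = 0)
  })
  cfg <- scenario_config("flat", eps, years = 2000:2005)
  run <- run_scenario(g, cfg, models, w)
  expect_equal(length(run$snapshots), 6)
  final <- run$snapshots[["2005"]]
  expect_equal(as.matrix(final[, a0$class]), as.matrix(g[, a0$class]))
  expect_true(all(run$reports$converged))
  expect_equal(run$reports$iterations, rep(1L, 5))
  dirs <- run_directions(run)
  expect_true(all(dirs$change_km2 == 0))
})

test_that("identical configurations give bit-identical runs", {
  spec <- synthetic_spec(n_rows = 12, n_cols = 12, seed = 4)
  p1 <- gen_observed_pair(spec, years = 3)
  p2 <- gen_observed_pair(spec, years = 3)
  expect_identical(as.data.frame(p1$tf), as.data.frame(p2$tf))
  expect_identical(p1$run$reports, p2$run$reports)
  expect_identical(p1$run$config_hash, p2$run$config_hash)
})

test_that("scenario-shaped runs satisfy their demand endpoints", {
  spec <- synthetic_spec(n_rows = 20, n_cols = 20, seed = 9)
  pair <- gen_observed_pair(spec, years = 10, scenario = "ssp1")
  expect_true(all(pair$run$reports$converged))
  a_end <- grid_areas(pair$tf)
  tol <- 0.005 * total_area_km2(pair$t0)
  gaps <- abs(a_end$area_km2 -
                pair$endpoints$final_area_km2[match(a_end$class,
                                                    pair$endpoints$class)])
  expect_true(all(gaps <= tol))
  # direction of change matches the scenario's endpoint signs where the
  # demanded change exceeds the convergence tolerance
  d <- run_directions(pair$run)
  eps_dir <- demand_directions(pair$endpoints)
  big <- abs(eps_dir$change_km2) > tol
  expect_equal(d$direction[match(eps_dir$class[big], d$class)],
               eps_dir$direction[big])
})

test_that("scheduled driver updates change the potential inputs", {
  g <- uniform_grid(5, 5, c(forest_vegetation = 50, grassland_vegetation = 43))
  g$dist_road <- 1
  w <- lucc_weights(g)
  a0 <- grid_areas(g)
  eps <- tibble::tibble(class = a0$class, initial_year = 2000L,
                        final_year = 2003L, initial_area_km2 = a0$area_km2,
                        final_area_km2 = a0$area_km2)
  models <- lapply(setNames(a0$class, a0$class), function(cl) {
    const_model(cl, intercept = 0.2, rho = 0)
  })
  sched <- tibble::tibble(year_from = 2002, driver = "dist_road",
                          values = list(0.25))
  cfg <- scenario_config("roads", eps, driver_schedule = sched,
                         years = 2000:2003)
  run <- run_scenario(g, cfg, models, w)
  expect_equal(unique(run$snapshots[["2001"]]$dist_road), 1)
  expect_equal(unique(run$snapshots[["2003"]]$dist_road), 0.25)
})

test_that("removing a restriction never shrinks anthropic expansion", {
  spec <- synthetic_spec(n_rows = 15, n_cols = 15, seed = 13)
  t0 <- gen_landscape(spec)
  w <- lucc_weights(t0)
  classes <- grid_meta(t0)$classes
  models <- lapply(setNames(classes, classes), function(cl) {
    fit_potential_model(t0, cl, spec$drivers, w)
  })
  eps <- synthetic_endpoints(t0, "ssp3", 2000, 2003)
  sched <- tibble::tibble(year_from = 2000, mask = "protected",
                          class_group = "anthropic", protection_level = 1)
  alloc <- allocation_params(on_non_convergence = "warn")
  run_masked <- suppressWarnings(run_scenario(
    t0, scenario_config("m", eps, mask_schedule = sched, years = 2000:2003,
                        allocation = alloc), models, w))
  run_free <- suppressWarnings(run_scenario(
    t0, scenario_config("f", eps, years = 2000:2003, allocation = alloc),
    models, w))
  anth <- lucc_anthropic_classes()
  masked_cells <- t0$protected == 1
  gain_in_masked <- function(run) {
    tf <- run$snapshots[["2003"]]
    sum(pmax(as.matrix(tf[masked_cells, anth]) -
               as.matrix(t0[masked_cells, anth]), 0))
  }
  expect_lte(gain_in_masked(run_masked), gain_in_masked(run_free) + 1e-9)
})

test_that("summaries report areas in km2 per year and region", {
  g <- uniform_grid(4, 4, c(forest_vegetation = 60, grassland_vegetation = 33))
  w <- lucc_weights(g)
  a0 <- grid_areas(g)
  eps <- tibble::tibble(class = a0$class, initial_year = 2000L,
                        final_year = 2002L, initial_area_km2 = a0$area_km2,
                        final_area_km2 = a0$area_km2)
  models <- lapply(setNames(a0$class, a0$class), function(cl) {
    const_model(cl, intercept = 0.3, rho = 0)
  })
  run <- run_scenario(g, scenario_config("s", eps, years = 2000:2002),
                      models, w)
  s <- summarize_run(run)
  expect_equal(nrow(s), 3 * 2)
  expect_equal(unique(s$area_km2[s$class == "forest_vegetation"]),
               0.6 * 1600)
  regions <- rep(c("north", "south"), each = 8)
  sr <- summarize_run(run, regions)
  expect_setequal(unique(sr$region), c("north", "south"))
  expect_equal(sum(sr$area_km2[sr$year == 2000]), sum(s$area_km2[s$year == 2000]))
  expect_error(summarize_run(run, regions[1:3]), class = "lucc_config_error")
})
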