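# Synthetic scene generator: geometry, truth surfaces, traces,
# demographics, national predictions.

test_that("a 1 km neighborhood tiles into 100 cells and is deterministic", {
  cfg <- scene_config(seed = 11, n_neighborhoods = 1,
                      neighborhood_size_m = 1000)
  sc1 <- generate_scene(cfg)
  expect_equal(nrow(sc1$grid), 100)
  expect_true(all(table(sc1$grid$x0) == 10))
  sc2 <- generate_scene(cfg)
  expect_identical(sc1$grid, sc2$grid)
  expect_identical(sc1$roads, sc2$roads)
  expect_identical(sc1$truth_ufp, sc2$truth_ufp)
  expect_identical(sc1$block_groups, sc2$block_groups)
  # different seed changes stochastic layers
  sc3 <- generate_scene(scene_config(seed = 12, n_neighborhoods = 1,
                                     neighborhood_size_m = 1000))
  expect_false(identical(sc1$food_service, sc3$food_service))
})

test_that("scene invariants hold: coverage, positivity, sparse sources", {
  sc <- generate_scene(scene_config(seed = 5))
  # cells are non-overlapping by construction: unique origins
  expect_equal(anyDuplicated(sc$grid[, c("x0", "y0")]), 0)
  # every cell center lies inside at least one block group
  cx <- sc$grid$x0 + 50; cy <- sc$grid$y0 + 50
  bg <- sc$block_groups
  covered <- vapply(seq_along(cx), function(i) {
    any(cx[i] >= bg$x0 & cx[i] < bg$x1 & cy[i] >= bg$y0 & cy[i] < bg$y1)
  }, logical(1))
  expect_true(all(covered))
  # truth exceeds a positive background everywhere
  expect_true(all(sc$truth_ufp > sc$config$background_ufp))
  expect_true(all(sc$truth_no2 > sc$config$background_no2))
  # sparse source types have zero density somewhere
  m <- suppressWarnings(build_feature_matrix(sc))
  zf <- attr(m, "zero_fraction")
  for (type in c("highway", "onramp", "food_service", "gas_station",
                 "industrial")) {
    expect_gt(zf[[paste0("KLS_", type, "_50")]], 0)
  }
})

test_that("zero source counts produce zero densities", {
  sc <- generate_scene(scene_config(seed = 2, n_neighborhoods = 1,
                                    neighborhood_size_m = 800,
                                    n_food_service = 0, n_gas = 0,
                                    n_industrial_polys = 0))
  expect_equal(nrow(sc$food_service), 0)
  m <- suppressWarnings(build_feature_matrix(sc))
  for (d in c(50, 150, 300)) {
    expect_true(all(m[, paste0("KLS_food_service_", d)] == 0))
    expect_true(all(m[, paste0("KLS_gas_station_", d)] == 0))
    expect_true(all(m[, paste0("KLS_industrial_", d)] == 0))
  }
})

test_that("truth surface follows the exponential kernel", {
  cfg <- scene_config(seed = 1)
  # no sources: background everywhere
  empty <- bare_scene(c(0, 100), c(0, 0))
  tr <- truth_surface(empty, cfg)
  expect_equal(tr$ufp, rep(cfg$background_ufp, 2))
  expect_equal(tr$no2, rep(cfg$background_no2, 2))

  # one point source, decay length 250: excess(50)/excess(300) = e^1
  cfg2 <- cfg
  cfg2$decay_length_m["food_service"] <- 250
  cfg2$source_strengths["food_service", ] <- c(ufp = 10, no2 = 10)
  # cells centered 50 m and 300 m from the source at (1000, 50)
  sc <- bare_scene(c(1000, 1250), c(0, 0),
                   food = tibble::tibble(x = 1000, y = 50))
  tr <- truth_surface(sc, cfg2)
  excess <- tr$ufp - cfg2$background_ufp
  expect_equal(excess[1] / excess[2], exp(1), tolerance = 1e-12)
  # two- to ten-fold decay for every default decay length
  for (L in cfg$decay_length_m) {
    ratio <- exp(-50 / L) / exp(-300 / L)
    expect_gte(ratio, 2); expect_lte(ratio, 10)
  }

  # linearity: duplicated source doubles the excess
  sc2 <- bare_scene(c(1000, 1250), c(0, 0),
                    food = tibble::tibble(x = c(1000, 1000), y = c(50, 50)))
  tr2 <- truth_surface(sc2, cfg2)
  expect_equal(tr2$ufp - cfg2$background_ufp, 2 * excess, tolerance = 1e-12)
})

test_that("noise-free traces carry exact cell truth at weekday daytimes", {
  cfg <- scene_config(seed = 9, n_neighborhoods = 1,
                      neighborhood_size_m = 600, n_drive_passes_per_cell = 3,
                      noise_sd = c(ufp = 0, no2 = 0))
  sc <- generate_scene(cfg)
  tr <- simulate_drive_traces(sc)
  expect_true(all(localdiff:::is_weekday_daytime(tr$t)))
  expect_true(all(diff(tr$t) > 0))
  cell <- localdiff:::match_cells(tr$x, tr$y, sc$grid)
  expect_false(anyNA(cell))
  expect_equal(tr$ufp, sc$truth_ufp[cell])
  expect_equal(tr$no2, sc$truth_no2[cell])
})

test_that("every monitored cell receives the configured number of passes", {
  cfg <- scene_config(seed = 3, n_neighborhoods = 1,
                      neighborhood_size_m = 600, n_drive_passes_per_cell = 5)
  sc <- generate_scene(cfg)
  tr <- simulate_drive_traces(sc)
  mm <- grid_concentration_field(tr, sc$grid)
  expect_true(all(mm$n_passes >= 5))
})

test_that("pass means are unbiased for truth under mean-1 lognormal noise", {
  cfg <- scene_config(seed = 21, n_neighborhoods = 1,
                      neighborhood_size_m = 400,
                      n_drive_passes_per_cell = 500,
                      noise_sd = c(ufp = 0.3, no2 = 0.3))
  sc <- generate_scene(cfg)
  tr <- simulate_drive_traces(sc)
  pts <- assign_to_grid(tr, sc$grid)
  cell <- pts$cell_id[1]
  passes <- isolate_drive_passes(pts[pts$cell_id == cell, ])
  expect_gte(nrow(passes), 500)
  truth <- sc$truth_ufp[sc$grid$cell_id == cell]
  se <- sd(passes$mean_ufp) / sqrt(nrow(passes))
  expect_lt(abs(mean(passes$mean_ufp) - truth), 3 * se)
})

test_that("national predictions are a smooth biased surface", {
  # constant truth: predictions equal that constant plus the bias
  cfg <- scene_config(seed = 8, n_neighborhoods = 1,
                      neighborhood_size_m = 800)
  cfg$source_strengths[] <- 0
  sc <- generate_scene(cfg)
  expect_equal(sc$truth_ufp, rep(cfg$background_ufp, nrow(sc$grid)))
  expect_equal(sc$block_groups$lur_ufp,
               rep(cfg$background_ufp + cfg$lur_bias[["ufp"]],
                   nrow(sc$block_groups)), tolerance = 1e-9)

  # smoother than truth: prediction variance below block-group-mean variance
  sc2 <- generate_scene(scene_config(seed = 8))
  bg <- sc2$block_groups
  cx <- sc2$grid$x0 + 50; cy <- sc2$grid$y0 + 50
  bg_of <- vapply(seq_along(cx), function(i) {
    which(cx[i] >= bg$x0 & cx[i] < bg$x1 & cy[i] >= bg$y0 & cy[i] < bg$y1)[1]
  }, integer(1))
  bg_mean <- tapply(sc2$truth_ufp, bg_of, mean)
  expect_lte(var(bg$lur_ufp[as.integer(names(bg_mean))]),
             var(as.numeric(bg_mean)) + 1e-9)

  # bias bookkeeping: noise-free monitoring gives domain-mean LD near -bias
  cfg3 <- scene_config(seed = 4, noise_sd = c(ufp = 0, no2 = 0),
                       n_drive_passes_per_cell = 2)
  sc3 <- generate_scene(cfg3)
  tr <- simulate_drive_traces(sc3)
  mm <- grid_concentration_field(tr, sc3$grid)
  lur <- areal_resample(sc3$block_groups, "lur_ufp", sc3$grid)
  ld <- compute_ld(mm$mm_ufp, lur[match(mm$cell_id, sc3$grid$cell_id)])
  expect_equal(mean(ld), -cfg3$lur_bias[["ufp"]], tolerance = 0.1)
})

test_that("demographic shares sum to one and respond to demo_source_corr", {
  base <- scene_config(seed = 31, n_neighborhoods = 80,
                       neighborhood_size_m = 600, n_food_service = 0,
                       n_gas = 0, n_industrial_polys = 0)
  sc0 <- generate_scene(base)
  bg <- sc0$block_groups
  expect_gte(nrow(bg), 300)
  sums <- rowSums(as.matrix(bg[, localdiff:::SHARE_COLS]))
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(bg$pop >= 0))

  dens <- localdiff:::bg_source_density(sc0, c("highway", "arterial"))
  expect_lt(abs(cor(bg$share_white, dens)), 0.1)

  neg <- base; neg$demo_source_corr <- -0.8
  scn <- generate_scene(neg)
  densn <- localdiff:::bg_source_density(scn, c("highway", "arterial"))
  expect_lt(cor(scn$block_groups$share_white, densn), -0.3)
})
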