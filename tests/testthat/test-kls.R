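# KLS feature engineering: buffers, densities, the 21-column matrix.

cell0 <- c(0, 0, 100)

test_that("buffer areas follow the closed-form dilation formula", {
  expect_equal(buffer_area_km2(100, 50), (0.2^2 - (4 - pi) * 0.05^2))
  expect_equal(buffer_area_km2(100, 50), 0.0378539816, tolerance = 1e-8)
  expect_equal(buffer_area_km2(100, 0), 0.01)
  expect_equal(buffer_area_km2(100, 300), 0.49 - (4 - pi) * 0.09)
  expect_error(buffer_region(cell0, -5), ">= 0")
  # the buffer contains the cell for every d
  for (d in c(50, 150, 300)) {
    b <- buffer_region(cell0, d)
    clipped <- localdiff:::clip_poly_convex(localdiff:::rect_poly(0, 0, 100, 100),
                                            b$poly)
    expect_equal(localdiff:::poly_area(clipped), 1e4, tolerance = 1e-9)
  }
})

test_that("road density is clipped length over buffered area", {
  expect_equal(road_density(list(), cell0, 50), 0)
  # straight road across the 50 m buffer at the cell midline: 0.2 km inside
  road <- list(cbind(c(-500, 500), c(50, 50)))
  expect_equal(road_density(road, cell0, 50), 0.2 / buffer_area_km2(100, 50))
  expect_equal(road_density(road, cell0, 50), 5.283, tolerance = 1e-3)
  # wholly outside
  far <- list(cbind(c(-500, 500), c(1000, 1000)))
  expect_equal(road_density(far, cell0, 300), 0)
})

test_that("point density counts within the Euclidean dilation", {
  pts <- tibble::tibble(x = c(50, -250), y = c(350, 50))   # both 250 m away
  expect_equal(point_density(pts, cell0, 300),
               2 / buffer_area_km2(100, 300))
  expect_equal(point_density(pts, cell0, 300), 4.846, tolerance = 1e-3)
  expect_equal(point_density(pts, cell0, 150), 0)
  # corner region uses true distance, not bounding box
  corner <- tibble::tibble(x = -40, y = -40)   # sqrt(3200) = 56.6 m
  expect_equal(point_density(corner, cell0, 50), 0)
  expect_equal(point_density(corner, cell0, 150),
               1 / buffer_area_km2(100, 150))
})

test_that("industrial share uses union semantics and caps at one", {
  cover <- tibble::tibble(x0 = -400, y0 = -400, x1 = 500, y1 = 500)
  expect_equal(industrial_share(cover, cell0, 300), 1)
  half <- tibble::tibble(x0 = 0, y0 = 0, x1 = 50, y1 = 100)
  expect_equal(industrial_share(half, cell0, 0), 0.5)
  # duplicated parcel does not inflate the share
  twice <- rbind(half, half)
  expect_equal(industrial_share(twice, cell0, 0),
               industrial_share(half, cell0, 0))
  # partial overlap: union of [0,60] and [40,100] strips covers the cell
  two <- tibble::tibble(x0 = c(0, 40), y0 = 0, x1 = c(60, 100), y1 = 100)
  expect_equal(industrial_share(two, cell0, 0), 1)
  expect_equal(industrial_share(half[0, ], cell0, 50), 0)
})

test_that("feature matrix has fixed layout, locality and sparsity report", {
  grid <- tibble::tibble(cell_id = 1:3, x0 = c(0, 500, 1000), y0 = 0,
                         size = 100)
  empty <- list(roads = tibble::tibble(road_id = integer(0),
                                       class = character(0), geometry = list()),
                food_service = tibble::tibble(x = numeric(0), y = numeric(0)),
                gas_stations = tibble::tibble(x = numeric(0), y = numeric(0)),
                industrial = tibble::tibble(x0 = numeric(0), y0 = numeric(0),
                                            x1 = numeric(0), y1 = numeric(0)))
  m0 <- suppressWarnings(build_feature_matrix(empty, grid))
  expect_equal(dim(m0), c(3, 21))
  expect_equal(colnames(m0), kls_feature_names())
  expect_true(all(m0 == 0))
  w <- capture_warnings(build_feature_matrix(empty, grid))
  expect_true(any(grepl("residential", w)))
  expect_true(any(grepl("food_service", w)))

  # one highway through the first cell: only highway columns, only nearby cells
  hw <- empty
  hw$roads <- tibble::tibble(road_id = 1L, class = "highway",
                             geometry = list(cbind(c(-1000, 2000), c(50, 50))))
  m1 <- suppressWarnings(build_feature_matrix(hw, grid))
  nonhw <- setdiff(colnames(m1), paste0("KLS_highway_", c(50, 150, 300)))
  expect_true(all(m1[, nonhw] == 0))
  expect_true(all(m1[, paste0("KLS_highway_", c(50, 150, 300))] > 0))
  zf <- attr(m1, "zero_fraction")
  expect_equal(unname(zf["KLS_highway_150"]), 0)
  expect_equal(unname(zf["KLS_food_service_50"]), 1)

  # hand-measured three-cell oracle for a vertical arterial at x = 130
  art <- empty
  art$roads <- tibble::tibble(road_id = 1L, class = "arterial",
                              geometry = list(cbind(c(130, 130), c(-1000, 1000))))
  m2 <- suppressWarnings(build_feature_matrix(art, grid))
  # cell 1 (x in [0,100]): offset 30 beyond edge; chord = 100 + 2*sqrt(d^2-30^2)
  for (d in c(50, 150, 300)) {
    chord_km <- (100 + 2 * sqrt(d^2 - 30^2)) / 1000
    expect_equal(unname(m2[1, paste0("KLS_arterial_", d)]),
                 chord_km / buffer_area_km2(100, d), tolerance = 1e-12)
  }
  # cell 2 (x in [500,600]): 370 m away, outside all buffers
  expect_true(all(m2[2, ] == 0))
})

test_that("geometry mismatch across coordinate systems raises an error", {
  grid <- tibble::tibble(cell_id = 1L, x0 = 0, y0 = 0, size = 100)
  lay <- list(roads = tibble::tibble(road_id = 1L, class = "highway",
                                     geometry = list(cbind(c(5e6, 5e6 + 100),
                                                           c(5e6, 5e6)))),
              food_service = NULL, gas_stations = NULL, industrial = NULL)
  expect_error(suppressWarnings(build_feature_matrix(lay, grid)),
               "coordinate system")
})

test_that("densities are translation invariant and scale correctly", {
  sc <- generate_scene(scene_config(seed = 17, n_neighborhoods = 1,
                                    neighborhood_size_m = 600))
  m <- suppressWarnings(build_feature_matrix(sc))

  shift <- c(1234.5, -987.6)
  sc2 <- sc
  sc2$grid$x0 <- sc$grid$x0 + shift[1]; sc2$grid$y0 <- sc$grid$y0 + shift[2]
  sc2$roads$geometry <- lapply(sc$roads$geometry, function(g) {
    cbind(g[, 1] + shift[1], g[, 2] + shift[2])
  })
  sc2$food_service$x <- sc$food_service$x + shift[1]
  sc2$food_service$y <- sc$food_service$y + shift[2]
  sc2$gas_stations$x <- sc$gas_stations$x + shift[1]
  sc2$gas_stations$y <- sc$gas_stations$y + shift[2]
  sc2$industrial$x0 <- sc$industrial$x0 + shift[1]
  sc2$industrial$x1 <- sc$industrial$x1 + shift[1]
  sc2$industrial$y0 <- sc$industrial$y0 + shift[2]
  sc2$industrial$y1 <- sc$industrial$y1 + shift[2]
  m2 <- suppressWarnings(build_feature_matrix(sc2))
  expect_lt(max(abs(m - m2)), 1e-9)

  # doubling all coordinates (cells and buffers scale too): road densities
  # halve, point densities quarter
  sc3 <- sc
  sc3$grid$x0 <- sc$grid$x0 * 2; sc3$grid$y0 <- sc$grid$y0 * 2
  sc3$grid$size <- sc$grid$size * 2
  sc3$roads$geometry <- lapply(sc$roads$geometry, function(g) g * 2)
  sc3$food_service$x <- sc$food_service$x * 2
  sc3$food_service$y <- sc$food_service$y * 2
  sc3$gas_stations$x <- sc$gas_stations$x * 2
  sc3$gas_stations$y <- sc$gas_stations$y * 2
  for (col in c("x0", "x1", "y0", "y1")) {
    sc3$industrial[[col]] <- sc$industrial[[col]] * 2
  }
  m3 <- suppressWarnings(build_feature_matrix(sc3, buffers = 2 * c(50, 150, 300)))
  road_cols <- as.vector(outer(c("residential", "arterial", "highway", "onramp"),
                               c(50, 150, 300),
                               function(a, b) paste0("KLS_", a, "_", b)))
  pt_cols <- as.vector(outer(c("food_service", "gas_station"), c(50, 150, 300),
                             function(a, b) paste0("KLS_", a, "_", b)))
  expect_equal(unname(m3[, paste0("KLS_highway_", c(100, 300, 600))]),
               unname(m[, paste0("KLS_highway_", c(50, 150, 300))] / 2),
               tolerance = 1e-9)
  expect_equal(unname(m3[, paste0("KLS_food_service_", c(100, 300, 600))]),
               unname(m[, paste0("KLS_food_service_", c(50, 150, 300))] / 4),
               tolerance = 1e-9)
  # industrial share is dimensionless: unchanged
  expect_equal(unname(m3[, paste0("KLS_industrial_", c(100, 300, 600))]),
               unname(m[, paste0("KLS_industrial_", c(50, 150, 300))]),
               tolerance = 1e-6)
})
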