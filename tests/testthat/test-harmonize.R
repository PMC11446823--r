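# Areal resampling, population allocation, localized difference, OLS
# comparison.

rectp <- localdiff:::rect_poly

one_cell_grid <- tibble::tibble(cell_id = 1L, x0 = 0, y0 = 0, size = 100)

bg_tbl <- function(geoms, values = NULL, pop = NULL, shares = NULL) {
  out <- tibble::tibble(bg_id = seq_along(geoms), geometry = geoms)
  if (!is.null(values)) out$v <- values
  if (!is.null(pop)) out$pop <- pop
  if (!is.null(shares)) {
    for (k in seq_along(localdiff:::SHARE_COLS)) {
      out[[localdiff:::SHARE_COLS[k]]] <- shares[, k]
    }
  }
  out
}

test_that("areal resampling is the overlap-weighted average", {
  # symmetric 50/50 split
  bg <- bg_tbl(list(rectp(-100, 0, 50, 100), rectp(50, 0, 200, 100)),
               values = c(10, 20))
  expect_equal(unname(areal_resample(bg, "v", one_cell_grid)), 15)
  # wholly inside one block group
  bg2 <- bg_tbl(list(rectp(-50, -50, 150, 150)), values = 8.5)
  expect_equal(unname(areal_resample(bg2, "v", one_cell_grid)), 8.5)
  # hand-computed three-donor weighted mean: areas 6000/3000/1000 m^2
  bg3 <- bg_tbl(list(rectp(0, 0, 60, 100), rectp(60, 0, 90, 100),
                     rectp(90, 0, 100, 100)),
                values = c(10, 20, 40))
  expect_equal(unname(areal_resample(bg3, "v", one_cell_grid)), 16)
  # no overlap -> NA
  bg4 <- bg_tbl(list(rectp(500, 500, 600, 600)), values = 3)
  expect_true(is.na(areal_resample(bg4, "v", one_cell_grid)))
  # constant field resamples to the constant on every covered cell
  grid4 <- tibble::tibble(cell_id = 1:4, x0 = c(0, 100, 0, 100),
                          y0 = c(0, 0, 100, 100), size = 100)
  bg5 <- bg_tbl(list(rectp(-10, -10, 130, 210), rectp(130, -10, 210, 210)),
                values = c(7.7, 7.7))
  expect_equal(unname(areal_resample(bg5, "v", grid4)), rep(7.7, 4))
})

test_that("invalid geometry is reported with the offending block group", {
  bad <- bg_tbl(list(matrix(c(0, 0), 1, 2)), values = 1)
  expect_error(areal_resample(bad, "v", one_cell_grid), "block group 1")
})

test_that("population allocation conserves counts and recomputes shares", {
  grid4 <- tibble::tibble(cell_id = 1:4, x0 = c(0, 100, 0, 100),
                          y0 = c(0, 0, 100, 100), size = 100)
  shares <- matrix(c(0.25, 0.25, 0.1, 0.2, 0.2), 1)
  bg <- bg_tbl(list(rectp(0, 0, 200, 200)), pop = 400, shares = shares)
  out <- allocate_population(bg, grid4)
  expect_equal(out$pop, rep(100, 4))
  expect_equal(out$share_asian, rep(0.25, 4))

  # two donors with orthogonal compositions and equal allocated pop
  shares2 <- rbind(c(1, 0, 0, 0, 0), c(0, 1, 0, 0, 0))
  bg2 <- bg_tbl(list(rectp(0, 0, 100, 100), rectp(0, 0, 100, 100)),
                pop = c(60, 60), shares = shares2)
  out2 <- allocate_population(bg2, one_cell_grid)
  expect_equal(out2$pop, 120)
  expect_equal(out2$share_asian, 0.5)
  expect_equal(out2$share_black, 0.5)
  expect_equal(out2$share_white, 0)

  # degenerate zero-area donor is skipped with a warning
  bg3 <- bg_tbl(list(rectp(0, 0, 100, 100)), pop = 10,
                shares = matrix(c(0, 0, 0, 1, 0), 1))
  bg3$geometry[[1]] <- rbind(c(0, 0), c(100, 0), c(0, 0))
  expect_warning(allocate_population(bg3, one_cell_grid), "zero area")
})

test_that("allocation conserves per-group totals on random scenes", {
  for (seed in c(101, 202)) {
    sc <- generate_scene(scene_config(seed = seed, n_neighborhoods = 2,
                                      neighborhood_size_m = 800))
    out <- allocate_population(sc$block_groups, sc$grid)
    bg <- sc$block_groups
    for (k in seq_along(localdiff:::SHARE_COLS)) {
      grp <- sub("share_", "pop_", localdiff:::SHARE_COLS[k])
      expected <- sum(bg$pop * bg[[localdiff:::SHARE_COLS[k]]])
      if (expected > 0) {
        expect_lt(abs(sum(out[[grp]]) - expected) / expected, 1e-9)
      }
    }
  }
})

test_that("localized difference is mm - lur, antisymmetric, NA-counting", {
  expect_equal(as.numeric(compute_ld(5, 5)), 0)
  expect_equal(as.numeric(compute_ld(23, 11)), 12)
  expect_equal(as.numeric(compute_ld(8.5, 10.2)), -1.7)
  set.seed(3)
  mm <- rnorm(50); lur <- rnorm(50)
  expect_equal(as.numeric(compute_ld(mm, lur)),
               -as.numeric(compute_ld(lur, mm)))
  withna <- compute_ld(c(1, NA, 3), c(1, 1, NA))
  expect_equal(attr(withna, "n_excluded"), 2)
})

test_that("OLS comparison summarizes agreement and flags degeneracy", {
  x <- seq(1, 10, length.out = 50)
  perfect <- suppressWarnings(ols_compare(x, x))  # lm warns on a perfect fit
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$slope, 1)
  expect_equal(perfect$intercept, 0, tolerance = 1e-10)
  expect_equal(perfect$mm_median, median(x))

  set.seed(12)
  noise <- ols_compare(rnorm(1e4), rnorm(1e4))
  expect_lt(noise$r2, 0.01)

  expect_warning(deg <- ols_compare(rnorm(10), rep(2, 10)), "zero-variance")
  expect_true(deg$degenerate)
  expect_true(is.na(deg$slope))
  expect_error(ols_compare(1:2, 1:2), "at least 3")
})
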