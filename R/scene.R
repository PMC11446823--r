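# Synthetic urban scenes with known ground truth.
#
# A scene emulates the structure of a hyperlocal monitoring study: several
# discontiguous square neighborhoods tiled by 100 m grid cells, road networks
# by class, sparse point and polygon sources, census-style block groups
# carrying population and racial/ethnic composition, per-cell ground-truth
# long-term concentrations with exponential near-source decay, and a smooth
# block-group-level "national model" prediction surface.

KLS_TYPES <- c("residential", "arterial", "highway", "onramp",
               "food_service", "gas_station", "industrial")
KLS_BUFFERS <- c(50, 150, 300)
POLLUTANTS <- c("ufp", "no2")
SHARE_COLS <- c("share_asian", "share_black", "share_other",
                "share_white", "share_hispanic")

#' Known-local-source feature names
#'
#' The 21 predictor names used throughout the package: seven source types
#' (four road classes, food service, gas stations, industrial land) at
#' three buffer distances from the grid-cell edge.
#'
#' @param types source type names (default all seven).
#' @param buffers buffer distances in meters (default 50, 150, 300).
#' @return character vector `KLS_<type>_<buffer>` in fixed column order
#'   (type-major, buffer-minor).
#' @export
kls_feature_names <- function(types = KLS_TYPES, buffers = KLS_BUFFERS) {
  as.vector(t(outer(types, buffers, function(a, b) paste0("KLS_", a, "_", b))))
}

#' Configuration for a synthetic monitoring scene
#'
#' Defaults describe a small multi-neighborhood domain with near-source
#' decay calibrated so the excess concentration falls two- to ten-fold
#' between 50 m and 300 m from a source (decay lengths within
#' 250/ln(10) to 250/ln(2) meters), a national-model surface that is smooth
#' at block-group scale and biased low for UFP, and lognormal multiplicative
#' measurement noise with mean 1 so pass means are unbiased for cell truth.
#'
#' @param seed integer RNG seed governing all stochastic layers.
#' @param n_neighborhoods number of discontiguous square neighborhoods.
#' @param neighborhood_size_m side of each neighborhood, a multiple of the
#'   cell size.
#' @param cell_size_m grid cell size (100 m, the analysis resolution).
#' @param road_grid_spacing_m named numeric: spacing of the internal road
#'   grid for `residential`, `arterial` and `highway` classes; `NA` or 0
#'   disables a class.  On-ramps are short connectors generated at
#'   highway/arterial crossings.
#' @param n_food_service,n_gas total point-source counts across the scene,
#'   placed preferentially near arterial roads.
#' @param n_industrial_polys number of rectangular industrial parcels.
#' @param background_ufp,background_no2 regional background levels
#'   (UFP in thousands of particles/cm^3, NO2 in ppb).
#' @param source_strengths 7 x 2 matrix (rows `KLS_TYPES` minus none,
#'   columns `ufp`, `no2`) of peak excess concentrations at a source.
#' @param decay_length_m named numeric, exponential decay length per source
#'   type in meters.
#' @param noise_sd named numeric, lognormal sigma (log scale) of 1 Hz
#'   multiplicative measurement noise per pollutant.
#' @param n_drive_passes_per_cell minimum temporally separated passes each
#'   monitored cell receives.
#' @param demo_source_corr strength in \[-1, 1\] tilting the white
#'   non-Hispanic share of a block group with its local source density:
#'   negative values place people of color preferentially near sources.
#' @param lur_bias named numeric additive bias of the national predictions
#'   per pollutant (negative bias means the national model underpredicts,
#'   producing positive localized difference).
#' @param drive_speed_mps vehicle speed for 1 Hz trace simulation.
#' @param dirichlet_conc concentration of the Dirichlet draw for
#'   racial/ethnic shares (larger = less between-block-group variation).
#' @param pop_density_km2 median population density used to populate block
#'   groups.
#' @return object of class `ld_scene_config` (a validated list).
#' @export
scene_config <- function(seed = 1L,
                         n_neighborhoods = 4L,
                         neighborhood_size_m = 1600L,
                         cell_size_m = 100L,
                         road_grid_spacing_m = c(residential = 200,
                                                 arterial = 600,
                                                 highway = 1600),
                         n_food_service = 12L,
                         n_gas = 8L,
                         n_industrial_polys = 6L,
                         background_ufp = 8,
                         background_no2 = 6,
                         source_strengths = NULL,
                         decay_length_m = c(residential = 160, arterial = 200,
                                            highway = 250, onramp = 200,
                                            food_service = 160,
                                            gas_station = 160,
                                            industrial = 250),
                         noise_sd = c(ufp = 0.35, no2 = 0.25),
                         n_drive_passes_per_cell = 12L,
                         demo_source_corr = 0,
                         lur_bias = c(ufp = -12, no2 = 0.9),
                         drive_speed_mps = 8,
                         dirichlet_conc = 40,
                         pop_density_km2 = 3000) {
  if (is.null(source_strengths)) {
    source_strengths <- rbind(
      residential  = c(ufp = 2,  no2 = 1),
      arterial     = c(ufp = 8,  no2 = 5),
      highway      = c(ufp = 30, no2 = 12),
      onramp       = c(ufp = 15, no2 = 6),
      food_service = c(ufp = 10, no2 = 1),
      gas_station  = c(ufp = 6,  no2 = 2),
      industrial   = c(ufp = 12, no2 = 4)
    )
  }
  cfg <- list(seed = as.integer(seed),
              n_neighborhoods = as.integer(n_neighborhoods),
              neighborhood_size_m = as.integer(neighborhood_size_m),
              cell_size_m = as.integer(cell_size_m),
              road_grid_spacing_m = road_grid_spacing_m,
              n_food_service = as.integer(n_food_service),
              n_gas = as.integer(n_gas),
              n_industrial_polys = as.integer(n_industrial_polys),
              background_ufp = background_ufp,
              background_no2 = background_no2,
              source_strengths = source_strengths,
              decay_length_m = decay_length_m,
              noise_sd = noise_sd,
              n_drive_passes_per_cell = as.integer(n_drive_passes_per_cell),
              demo_source_corr = demo_source_corr,
              lur_bias = lur_bias,
              drive_speed_mps = drive_speed_mps,
              dirichlet_conc = dirichlet_conc,
              pop_density_km2 = pop_density_km2)
  validate_scene_config(cfg)
  class(cfg) <- "ld_scene_config"
  cfg
}

validate_scene_config <- function(cfg) {
  stopifnot_config <- function(ok, msg) if (!ok) stop("invalid scene config: ",
                                                      msg, call. = FALSE)
  stopifnot_config(cfg$n_neighborhoods >= 1, "n_neighborhoods must be >= 1")
  stopifnot_config(cfg$cell_size_m > 0, "cell_size_m must be positive")
  stopifnot_config(cfg$neighborhood_size_m > 0 &&
                     cfg$neighborhood_size_m %% cfg$cell_size_m == 0,
                   "neighborhood_size_m must be a positive multiple of cell_size_m")
  stopifnot_config(cfg$n_drive_passes_per_cell >= 1,
                   "n_drive_passes_per_cell must be >= 1")
  stopifnot_config(cfg$demo_source_corr >= -1 && cfg$demo_source_corr <= 1,
                   "demo_source_corr must lie in [-1, 1]")
  stopifnot_config(cfg$background_ufp > 0 && cfg$background_no2 > 0,
                   "backgrounds must be positive")
  stopifnot_config(all(cfg$decay_length_m > 0), "decay lengths must be positive")
  stopifnot_config(cfg$n_food_service >= 0 && cfg$n_gas >= 0 &&
                     cfg$n_industrial_polys >= 0, "source counts must be >= 0")
  stopifnot_config(all(rownames(cfg$source_strengths) == KLS_TYPES),
                   "source_strengths rows must be the seven KLS types in order")
  invisible(cfg)
}

# interior line offsets at a given spacing; empty when the spacing exceeds
# the neighborhood (no line of that class fits).
line_offsets <- function(sp, S) {
  if (is.null(sp) || is.na(sp) || sp <= 0 || sp / 2 >= S) return(numeric(0))
  seq(sp / 2, S - 1e-9, by = sp)
}

# neighborhood origins: laid out on a coarse lattice with a 100 m gap so the
# domains are discontiguous, like separated study neighborhoods.
neighborhood_origins <- function(cfg) {
  k <- cfg$n_neighborhoods
  ncol_n <- ceiling(sqrt(k))
  step <- cfg$neighborhood_size_m + 100
  idx <- seq_len(k) - 1L
  cbind(x = (idx %% ncol_n) * step, y = (idx %/% ncol_n) * step)
}

#' Generate a complete synthetic scene
#'
#' Builds the geometry (grid, roads, point and polygon sources, block
#' groups), ground-truth concentration surfaces, block-group demographics
#' and national-model predictions, in that order, from a single seed.
#' Identical configurations produce identical scenes.
#'
#' @param config an [scene_config()] object.
#' @return an object of class `ld_scene`: a list with elements `grid`
#'   (tibble: cell_id, x0, y0, size), `roads` (tibble: road_id, class,
#'   geometry list of vertex matrices), `food_service`, `gas_stations`
#'   (tibbles x, y), `industrial` (tibble x0, y0, x1, y1),
#'   `block_groups` (tibble with rectangle bounds, geometry, pop, five
#'   shares, lur_ufp, lur_no2), `truth_ufp`, `truth_no2` (per-cell vectors)
#'   and the `config`.
#' @export
generate_scene <- function(config) {
  validate_scene_config(config)
  set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 4L)

  scene <- build_scene_geometry(config, sub_seeds[1])
  tr <- truth_surface(scene, config)
  scene$truth_ufp <- tr$ufp
  scene$truth_no2 <- tr$no2
  scene$block_groups <- generate_demographics(scene, config, seed = sub_seeds[2])
  scene$block_groups <- generate_national_predictions(scene, config,
                                                      seed = sub_seeds[3])
  scene$trace_seed <- sub_seeds[4]
  scene
}

# Geometry layers only (deterministic given seed).
build_scene_geometry <- function(cfg, seed) {
  set.seed(seed)
  S <- cfg$neighborhood_size_m
  cs <- cfg$cell_size_m
  orig <- neighborhood_origins(cfg)
  ncell_side <- S %/% cs

  # grid cells, half-open [x0, x0+cs) x [y0, y0+cs)
  cells <- do.call(rbind, lapply(seq_len(nrow(orig)), function(i) {
    gx <- orig[i, 1] + (seq_len(ncell_side) - 1L) * cs
    gy <- orig[i, 2] + (seq_len(ncell_side) - 1L) * cs
    expand.grid(x0 = gx, y0 = gy, KEEP.OUT.ATTRS = FALSE)
  }))
  grid <- tibble::tibble(cell_id = seq_len(nrow(cells)),
                         x0 = cells$x0, y0 = cells$y0, size = cs)

  # roads: interior line grids per class, per neighborhood
  spacing <- cfg$road_grid_spacing_m
  roads <- list()
  add_road <- function(class, mat) {
    roads[[length(roads) + 1L]] <<- list(class = class, geometry = mat)
  }
  for (i in seq_len(nrow(orig))) {
    ox <- orig[i, 1]; oy <- orig[i, 2]
    for (cls in c("residential", "arterial", "highway")) {
      offs <- line_offsets(spacing[[cls]], S)
      if (length(offs) == 0) next
      if (cls == "highway") {
        # horizontal only: leaves cells far from any highway
        for (o in offs) add_road(cls, cbind(c(ox, ox + S), c(oy + o, oy + o)))
      } else {
        for (o in offs) {
          add_road(cls, cbind(c(ox + o, ox + o), c(oy, oy + S)))   # vertical
          add_road(cls, cbind(c(ox, ox + S), c(oy + o, oy + o)))   # horizontal
        }
      }
    }
    # on-ramps: short connectors where highways meet vertical arterials
    hy <- line_offsets(spacing[["highway"]], S)
    ax <- line_offsets(spacing[["arterial"]], S)
    if (length(hy) > 0 && length(ax) > 0) {
      cross <- expand.grid(x = ax, y = hy, KEEP.OUT.ATTRS = FALSE)
      keep <- seq_len(nrow(cross)) %% 2L == 1L   # every other crossing
      for (j in which(keep)) {
        cx <- ox + cross$x[j]; cy <- oy + cross$y[j]
        add_road("onramp", cbind(c(cx, cx + 60), c(cy, cy + 60)))
      }
    }
  }
  road_tbl <- tibble::tibble(
    road_id = seq_along(roads),
    class = vapply(roads, `[[`, character(1), "class"),
    geometry = lapply(roads, `[[`, "geometry")
  )

  # point sources near arterial roads (co-location with traffic)
  place_points <- function(n) {
    if (n == 0) return(tibble::tibble(x = numeric(0), y = numeric(0)))
    arterials <- which(road_tbl$class == "arterial")
    xs <- numeric(n); ys <- numeric(n)
    for (j in seq_len(n)) {
      if (length(arterials) > 0) {
        g <- road_tbl$geometry[[sample(arterials, 1L)]]
        t <- stats::runif(1)
        px <- g[1, 1] + t * (g[2, 1] - g[1, 1]) + stats::rnorm(1, 0, 40)
        py <- g[1, 2] + t * (g[2, 2] - g[1, 2]) + stats::rnorm(1, 0, 40)
      } else {
        i <- sample(nrow(orig), 1L)
        px <- orig[i, 1] + stats::runif(1, 0, S)
        py <- orig[i, 2] + stats::runif(1, 0, S)
      }
      # clamp into the nearest neighborhood square
      d <- dist_point_rect(px, py, orig[, 1], orig[, 2],
                           orig[, 1] + S, orig[, 2] + S)
      i <- which.min(d)
      xs[j] <- min(max(px, orig[i, 1]), orig[i, 1] + S)
      ys[j] <- min(max(py, orig[i, 2]), orig[i, 2] + S)
    }
    tibble::tibble(x = xs, y = ys)
  }
  food <- place_points(cfg$n_food_service)
  gas <- place_points(cfg$n_gas)

  # industrial parcels: axis-aligned rectangles inside a neighborhood
  ni <- cfg$n_industrial_polys
  if (ni > 0) {
    nb <- sample(nrow(orig), ni, replace = TRUE)
    w <- stats::runif(ni, 100, 300); h <- stats::runif(ni, 100, 300)
    x0 <- orig[nb, 1] + stats::runif(ni, 0, 1) * (S - w)
    y0 <- orig[nb, 2] + stats::runif(ni, 0, 1) * (S - h)
    industrial <- tibble::tibble(x0 = x0, y0 = y0, x1 = x0 + w, y1 = y0 + h)
  } else {
    industrial <- tibble::tibble(x0 = numeric(0), y0 = numeric(0),
                                 x1 = numeric(0), y1 = numeric(0))
  }

  # block groups: random rectangular partition of each neighborhood with
  # boundaries not aligned to the monitoring grid
  bgs <- list()
  for (i in seq_len(nrow(orig))) {
    nx <- sample(2:3, 1L); ny <- sample(2:3, 1L)
    xc <- c(0, sort(stats::runif(nx - 1L, 0.25, 0.75)), 1) * S + orig[i, 1]
    yc <- c(0, sort(stats::runif(ny - 1L, 0.25, 0.75)), 1) * S + orig[i, 2]
    for (a in seq_len(nx)) for (b in seq_len(ny)) {
      bgs[[length(bgs) + 1L]] <- c(xc[a], yc[b], xc[a + 1L], yc[b + 1L])
    }
  }
  bg_mat <- do.call(rbind, bgs)
  block_groups <- tibble::tibble(
    bg_id = seq_len(nrow(bg_mat)),
    x0 = bg_mat[, 1], y0 = bg_mat[, 2], x1 = bg_mat[, 3], y1 = bg_mat[, 4],
    geometry = lapply(seq_len(nrow(bg_mat)),
                      function(j) rect_poly(bg_mat[j, 1], bg_mat[j, 2],
                                            bg_mat[j, 3], bg_mat[j, 4]))
  )

  structure(list(grid = grid, roads = road_tbl, food_service = food,
                 gas_stations = gas, industrial = industrial,
                 block_groups = block_groups, config = cfg),
            class = "ld_scene")
}

#' @export
print.ld_scene <- function(x, ...) {
  cat("<ld_scene>\n")
  cat("  cells:        ", nrow(x$grid), " (", x$grid$size[1], " m)\n", sep = "")
  cat("  roads:        ", nrow(x$roads), " (",
      paste(names(table(x$roads$class)), table(x$roads$class),
            sep = "=", collapse = ", "), ")\n", sep = "")
  cat("  point sources:", nrow(x$food_service), "food service,",
      nrow(x$gas_stations), "gas stations\n")
  cat("  industrial:   ", nrow(x$industrial), "parcels\n")
  cat("  block groups: ", nrow(x$block_groups), "\n")
  cat("  truth:        ", if (is.null(x$truth_ufp)) "not built" else "built", "\n")
  invisible(x)
}

#' Ground-truth concentration surfaces
#'
#' Truth at a cell is the regional background plus a sum of exponential
#' source kernels, `strength * exp(-d / decay_length)`, over every source
#' feature, with `d` the distance from the cell center to the feature
#' (zero inside industrial parcels).  With decay lengths between
#' 250/ln(10) and 250/ln(2) meters the excess falls two- to ten-fold
#' between 50 m and 300 m of a source.
#'
#' @param scene an `ld_scene` (geometry built).
#' @param config the scene's configuration.
#' @return list with per-cell numeric vectors `ufp` and `no2`.
#' @export
truth_surface <- function(scene, config = scene$config) {
  cx <- scene$grid$x0 + scene$grid$size / 2
  cy <- scene$grid$y0 + scene$grid$size / 2
  n <- length(cx)
  out <- list(ufp = rep(config$background_ufp, n),
              no2 = rep(config$background_no2, n))
  add_kernel <- function(type, d) {
    L <- config$decay_length_m[[type]]
    k <- exp(-d / L)
    for (p in POLLUTANTS) {
      out[[p]] <<- out[[p]] + config$source_strengths[type, p] * k
    }
  }
  for (i in seq_len(nrow(scene$roads))) {
    add_kernel(scene$roads$class[i],
               dist_point_polyline(cx, cy, scene$roads$geometry[[i]]))
  }
  for (i in seq_len(nrow(scene$food_service))) {
    add_kernel("food_service",
               sqrt((cx - scene$food_service$x[i])^2 +
                    (cy - scene$food_service$y[i])^2))
  }
  for (i in seq_len(nrow(scene$gas_stations))) {
    add_kernel("gas_station",
               sqrt((cx - scene$gas_stations$x[i])^2 +
                    (cy - scene$gas_stations$y[i])^2))
  }
  for (i in seq_len(nrow(scene$industrial))) {
    add_kernel("industrial",
               dist_point_rect(cx, cy, scene$industrial$x0[i],
                               scene$industrial$y0[i], scene$industrial$x1[i],
                               scene$industrial$y1[i]))
  }
  out
}

# Seconds since Monday 00:00 of the simulation epoch; weekday daytime window.
DAY_S <- 86400
DRIVE_START_S <- 8 * 3600
DRIVE_END_S <- 18 * 3600

is_weekday_daytime <- function(t) {
  day <- (t %/% DAY_S) %% 7
  tod <- t %% DAY_S
  day <= 4 & tod >= DRIVE_START_S & tod < DRIVE_END_S
}

# map a sequential weekday index (0-based) to a day offset skipping weekends
weekday_offset <- function(k) (k %/% 5L) * 7L + (k %% 5L)

#' Simulate 1 Hz mobile-monitoring drive traces
#'
#' Drives every road polyline `n_drive_passes_per_cell` times at constant
#' speed, emitting one point per second during weekday daytime hours
#' (08:00-18:00).  Each road is driven in its own time slot within a day
#' and successive passes fall on successive weekdays, so every visit to a
#' cell is separated from the next by more than any plausible pass-gap
#' threshold.  Point values are the containing cell's ground truth times
#' mean-1 lognormal noise (`exp(rnorm(0, sd) - sd^2/2)`), making pass means
#' unbiased for truth.
#'
#' @param scene scene with truth surfaces built.
#' @param config the scene's configuration.
#' @param seed RNG seed for measurement noise (defaults to the scene's
#'   derived trace seed).
#' @return tibble of measurement points: `t` (seconds since the simulation
#'   epoch, strictly increasing), `x`, `y` (m), `ufp`, `no2`.
#' @export
simulate_drive_traces <- function(scene, config = scene$config, seed = NULL) {
  if (is.null(scene$truth_ufp)) stop("truth surfaces not built; run generate_scene()")
  if (is.null(seed)) seed <- scene$trace_seed
  if (!is.null(seed)) set.seed(seed)
  speed <- config$drive_speed_mps
  n_pass <- config$n_drive_passes_per_cell

  # positions sampled at 1 Hz along each road
  road_pts <- lapply(scene$roads$geometry, function(g) {
    L <- sum(sqrt(rowSums((g[-1, , drop = FALSE] - g[-nrow(g), , drop = FALSE])^2)))
    s <- seq(0, L, by = speed)
    # single-segment roads: linear interpolation along the segment
    t <- s / L
    cbind(g[1, 1] + t * (g[nrow(g), 1] - g[1, 1]),
          g[1, 2] + t * (g[nrow(g), 2] - g[1, 2]))
  })
  durations <- vapply(road_pts, nrow, integer(1))

  pts <- vector("list", n_pass * length(road_pts))
  k <- 0L
  day_idx <- 0L
  cursor <- DRIVE_START_S
  for (pass in seq_len(n_pass)) {
    for (r in seq_along(road_pts)) {
      dur <- durations[r]
      if (cursor + dur > DRIVE_END_S) {
        day_idx <- day_idx + 1L
        cursor <- DRIVE_START_S
      }
      t0 <- weekday_offset(day_idx) * DAY_S + cursor
      k <- k + 1L
      pts[[k]] <- cbind(t = t0 + seq_len(dur) - 1L, road_pts[[r]])
      cursor <- cursor + dur + 120   # slack between roads within a day
    }
    day_idx <- day_idx + 1L          # next pass starts on a fresh weekday
    cursor <- DRIVE_START_S
  }
  m <- do.call(rbind, pts)
  colnames(m) <- c("t", "x", "y")

  # truth of the containing cell
  cell <- match_cells(m[, "x"], m[, "y"], scene$grid)
  keep <- !is.na(cell)
  m <- m[keep, , drop = FALSE]; cell <- cell[keep]
  noise <- function(sd, n) if (sd == 0) rep(1, n) else
    exp(stats::rnorm(n, 0, sd) - sd^2 / 2)
  n <- nrow(m)
  out <- tibble::tibble(
    t = m[, "t"], x = m[, "x"], y = m[, "y"],
    ufp = scene$truth_ufp[cell] * noise(config$noise_sd[["ufp"]], n),
    no2 = scene$truth_no2[cell] * noise(config$noise_sd[["no2"]], n)
  )
  out[order(out$t), ]
}

# cell index for points, NA when outside every cell (half-open cells).
match_cells <- function(x, y, grid) {
  cs <- grid$size[1]
  key <- paste(grid$x0 %/% cs, grid$y0 %/% cs)
  idx <- stats::setNames(seq_len(nrow(grid)), key)
  unname(idx[paste(floor(x / cs), floor(y / cs))])
}

#' Block-group demographics
#'
#' Draws each block group's racial/ethnic composition from a Dirichlet
#' distribution over the five non-overlapping categories (non-Hispanic
#' Asian, Black, Other, white, and Hispanic/Latino).  The mean white share
#' is tilted on the logit scale by the block group's standardized
#' highway-plus-arterial road density with strength `demo_source_corr`
#' (negative values concentrate people of color near sources).  Population
#' is area times a lognormal density.
#'
#' @param scene scene with geometry built.
#' @param config the scene's configuration.
#' @param seed optional RNG seed.
#' @return the scene's `block_groups` tibble with `pop` and the five
#'   `share_*` columns added (shares sum to one in every row).
#' @export
generate_demographics <- function(scene, config = scene$config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bg <- scene$block_groups
  nb <- nrow(bg)

  dens <- bg_source_density(scene, c("highway", "arterial"))
  z <- if (stats::sd(dens) > 0) (dens - mean(dens)) / stats::sd(dens) else
    rep(0, nb)

  base <- c(asian = 0.20, black = 0.12, other = 0.05, white = 0.42,
            hispanic = 0.21)
  # neighborhood-to-neighborhood heterogeneity: the mean white share varies
  # on the logit scale (source tilt plus an independent composition effect),
  # and the relative mix of the non-white remainder varies independently --
  # real urban domains have Hispanic-, Asian- or Black-predominant areas,
  # not a fixed minority mix.
  m_white <- stats::plogis(stats::qlogis(base[["white"]]) +
                             1.8 * config$demo_source_corr * z +
                             stats::rnorm(nb, 0, 0.6))
  shares <- matrix(0, nb, 5, dimnames = list(NULL, SHARE_COLS))
  conc <- config$dirichlet_conc
  others <- base[c("asian", "black", "other", "hispanic")] /
    sum(base[c("asian", "black", "other", "hispanic")])
  for (i in seq_len(nb)) {
    rel <- stats::rgamma(4, shape = 5 * others)
    rel <- rel / sum(rel)
    alpha <- conc * c(rel * (1 - m_white[i]), white = m_white[i])
    names(alpha) <- c("share_asian", "share_black", "share_other",
                      "share_hispanic", "share_white")
    g <- stats::rgamma(5, shape = alpha)
    shares[i, names(alpha)] <- g / sum(g)
  }
  area_km2 <- (bg$x1 - bg$x0) * (bg$y1 - bg$y0) / 1e6
  bg$pop <- round(area_km2 *
                    stats::rlnorm(nb, log(config$pop_density_km2), 0.5))
  for (col in SHARE_COLS) bg[[col]] <- shares[, col]
  bg
}

# road length (given classes) per km^2 of block group
bg_source_density <- function(scene, classes) {
  bg <- scene$block_groups
  sel <- which(scene$roads$class %in% classes)
  vapply(seq_len(nrow(bg)), function(i) {
    len <- 0
    for (r in sel) {
      g <- scene$roads$geometry[[r]]
      for (s in seq_len(nrow(g) - 1L)) {
        iv <- seg_interval_rect(g[s, ], g[s + 1L, ], bg$x0[i], bg$y0[i],
                                bg$x1[i], bg$y1[i])
        if (!is.null(iv)) {
          len <- len + (iv[2] - iv[1]) * sqrt(sum((g[s + 1L, ] - g[s, ])^2))
        }
      }
    }
    len / ((bg$x1[i] - bg$x0[i]) * (bg$y1[i] - bg$y0[i]) / 1e6) / 1000
  }, numeric(1))
}

#' Synthetic national-model predictions at block-group level
#'
#' Emulates a national regression product: the block-group prediction is
#' the fitted value of a linear model of block-group-mean truth on coarse
#' covariates (total road length in the block group and population), plus a
#' configurable additive bias per pollutant.  Being a linear smoother of
#' block-group means, the prediction surface cannot carry within-block-group
#' extremes, which is exactly the structure the localized difference
#' analysis probes.
#'
#' @param scene scene with truth and demographics built.
#' @param config the scene's configuration.
#' @param seed optional RNG seed (predictions are deterministic given the
#'   scene; the seed only guards against future stochastic components).
#' @return the scene's `block_groups` tibble with `lur_ufp` and `lur_no2`
#'   columns added.
#' @export
generate_national_predictions <- function(scene, config = scene$config,
                                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bg <- scene$block_groups
  if (is.null(bg$pop)) stop("demographics not built; run generate_demographics()")
  cx <- scene$grid$x0 + scene$grid$size / 2
  cy <- scene$grid$y0 + scene$grid$size / 2
  # cell centers never lie on block-group boundaries with probability 1;
  # assign by containment
  bg_of_cell <- rep(NA_integer_, length(cx))
  for (i in seq_len(nrow(bg))) {
    inside <- cx >= bg$x0[i] & cx < bg$x1[i] & cy >= bg$y0[i] & cy < bg$y1[i]
    bg_of_cell[inside] <- i
  }
  road_len <- bg_source_density(scene, unique(scene$roads$class)) *
    ((bg$x1 - bg$x0) * (bg$y1 - bg$y0) / 1e6)
  for (p in POLLUTANTS) {
    truth <- scene[[paste0("truth_", p)]]
    bg_mean <- as.numeric(tapply(truth, factor(bg_of_cell,
                                               levels = seq_len(nrow(bg))),
                                 mean))
    bg_mean[is.na(bg_mean)] <- mean(truth)
    fit <- if (stats::sd(bg_mean) == 0) rep(bg_mean[1], nrow(bg)) else
      stats::fitted(stats::lm(bg_mean ~ road_len + bg$pop))
    bg[[paste0("lur_", p)]] <- as.numeric(fit) + config$lur_bias[[p]]
  }
  bg
}
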