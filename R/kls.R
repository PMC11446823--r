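# Known-local-source (KLS) predictors: seven source types x three buffer
# distances = 21 densities per grid cell.  Road classes are measured as
# km of road per km^2, commercial points as locations per km^2, and
# industrial land as the share of buffered area.  The buffer is the
# Euclidean dilation of the cell square by d ("within d of the grid cell
# edge"), whose area has the closed form (s + 2d)^2 - (4 - pi) d^2.
#
# Density denominators use the buffered-region area, keeping densities
# comparable across buffer distances; the industrial share is the ratio of
# two areas measured on the same polygonal buffer so that a parcel covering
# the whole buffer has share exactly 1.

#' Buffered region of a grid cell
#'
#' Euclidean dilation of the cell square by `d_m` meters: the rectangle
#' grown on each side with quarter-circle corners.
#'
#' @param cell numeric `c(x0, y0, size)` in meters.
#' @param d_m buffer distance in meters (>= 0; 0 degenerates to the cell).
#' @return list with the cell rectangle (`x0`, `y0`, `x1`, `y1`), `d_m`,
#'   the closed-form `area_km2`, and `poly`, a polygonal approximation of
#'   the rounded boundary used for area-in-area computations.
#' @export
buffer_region <- function(cell, d_m) {
  if (d_m < 0) stop("buffer distance must be >= 0")
  x0 <- cell[1]; y0 <- cell[2]; s <- cell[3]
  list(x0 = x0, y0 = y0, x1 = x0 + s, y1 = y0 + s, d_m = d_m,
       area_km2 = buffer_area_km2(s, d_m),
       poly = buffer_poly(x0, y0, x0 + s, y0 + s, d_m))
}

#' @rdname buffer_region
#' @param size_m cell side in meters.
#' @export
buffer_area_km2 <- function(size_m, d_m) {
  ((size_m + 2 * d_m)^2 - (4 - pi) * d_m^2) / 1e6
}

#' Road density within a buffered cell
#'
#' Length of the polylines falling within `d_m` of the cell edge (exact,
#' via parameter-interval intersection with the dilated region) divided by
#' the closed-form buffer area.
#'
#' @param lines list of polyline vertex matrices (one road class).
#' @param cell numeric `c(x0, y0, size)`.
#' @param d_m buffer distance in meters.
#' @return km of road per km^2.
#' @export
road_density <- function(lines, cell, d_m) {
  if (length(lines) == 0) return(0)
  x0 <- cell[1]; y0 <- cell[2]; x1 <- x0 + cell[3]; y1 <- y0 + cell[3]
  len_m <- 0
  for (g in lines) {
    bb <- c(range(g[, 1]), range(g[, 2]))
    if (bb[1] > x1 + d_m || bb[2] < x0 - d_m ||
        bb[3] > y1 + d_m || bb[4] < y0 - d_m) next
    len_m <- len_m + polyline_len_in_buffer(g, x0, y0, x1, y1, d_m)
  }
  (len_m / 1000) / buffer_area_km2(cell[3], d_m)
}

#' Point-source density within a buffered cell
#'
#' @param points tibble/data.frame with `x`, `y` columns.
#' @param cell numeric `c(x0, y0, size)`.
#' @param d_m buffer distance in meters.
#' @return locations per km^2 (points on the buffer boundary count as in).
#' @export
point_density <- function(points, cell, d_m) {
  if (is.null(points) || nrow(points) == 0) return(0)
  x0 <- cell[1]; y0 <- cell[2]; x1 <- x0 + cell[3]; y1 <- y0 + cell[3]
  d <- dist_point_rect(points$x, points$y, x0, y0, x1, y1)
  sum(d <= d_m) / buffer_area_km2(cell[3], d_m)
}

#' Industrial land-use share within a buffered cell
#'
#' Overlapping parcels are unioned before measuring, so duplicated
#' geometry never inflates the share; the result is the unioned area
#' intersected with the buffer divided by the buffer area (both measured
#' on the same polygonal buffer, so full coverage gives exactly 1).
#' Parcels must be convex (axis-aligned rectangles from the synthetic
#' generator always are).
#'
#' @param polys either a tibble of rectangles (`x0`, `y0`, `x1`, `y1`) or a
#'   list of convex polygon vertex matrices.
#' @param cell numeric `c(x0, y0, size)`.
#' @param d_m buffer distance in meters.
#' @return fraction of buffered area labeled industrial, in \[0, 1\].
#' @export
industrial_share <- function(polys, cell, d_m) {
  mats <- industrial_mats(polys)
  if (length(mats) == 0) return(0)
  x0 <- cell[1]; y0 <- cell[2]; x1 <- x0 + cell[3]; y1 <- y0 + cell[3]
  near <- Filter(function(g) {
    bb <- c(range(g[, 1]), range(g[, 2]))
    !(bb[1] > x1 + d_m || bb[2] < x0 - d_m ||
        bb[3] > y1 + d_m || bb[4] < y0 - d_m)
  }, mats)
  if (length(near) == 0) return(0)
  bpoly <- buffer_poly(x0, y0, x1, y1, d_m)
  poly_union_area_in(near, bpoly) / poly_area(bpoly)
}

industrial_mats <- function(polys) {
  if (is.null(polys)) return(list())
  if (is.data.frame(polys)) {
    lapply(seq_len(nrow(polys)), function(i) {
      rect_poly(polys$x0[i], polys$y0[i], polys$x1[i], polys$y1[i])
    })
  } else {
    polys
  }
}

#' Build the cells x 21 KLS feature matrix
#'
#' Computes every source-type density at every buffer distance for every
#' grid cell.  Column order is fixed and documented by
#' [kls_feature_names()] (type-major: residential, arterial, highway,
#' onramp, food_service, gas_station, industrial; buffer-minor 50/150/300);
#' row order follows the grid table.  An absent layer produces a zero
#' column with a warning.
#'
#' @param layers an `ld_scene`, or a list with elements `roads` (tibble
#'   with `class` and `geometry`), `food_service`, `gas_stations` (point
#'   tibbles) and `industrial` (rectangle tibble or polygon list).
#' @param grid the monitoring grid table (defaults to the scene's grid).
#' @param buffers buffer distances in meters.
#' @return numeric matrix (cells x types*buffers) with attribute
#'   `zero_fraction`: per column, the fraction of cells with zero density
#'   (the sparsity regime that produces presence/absence partial-dependence
#'   patterns).
#' @export
build_feature_matrix <- function(layers, grid = NULL, buffers = KLS_BUFFERS) {
  if (inherits(layers, "ld_scene")) {
    if (is.null(grid)) grid <- layers$grid
    layers <- list(roads = layers$roads, food_service = layers$food_service,
                   gas_stations = layers$gas_stations,
                   industrial = layers$industrial)
  }
  if (is.null(grid)) stop("a grid table is required")
  check_layer_extent(layers, grid, max(buffers))
  road_classes <- c("residential", "arterial", "highway", "onramp")
  road_lines <- lapply(road_classes, function(cls) {
    if (is.null(layers$roads) || nrow(layers$roads) == 0) return(list())
    layers$roads$geometry[layers$roads$class == cls]
  })
  names(road_lines) <- road_classes
  for (cls in road_classes) {
    if (length(road_lines[[cls]]) == 0) {
      warning("no `", cls, "` roads; its columns are zero")
    }
  }
  for (nm in c("food_service", "gas_stations", "industrial")) {
    lay <- layers[[nm]]
    if (is.null(lay) || (is.data.frame(lay) && nrow(lay) == 0) ||
        (is.list(lay) && !is.data.frame(lay) && length(lay) == 0)) {
      warning("no `", nm, "` layer; its columns are zero")
    }
  }

  nms <- kls_feature_names(buffers = buffers)
  nc <- nrow(grid)
  mat <- matrix(0, nc, length(nms), dimnames = list(NULL, nms))
  ind_mats <- industrial_mats(layers$industrial)
  x0 <- grid$x0; y0 <- grid$y0; sz <- grid$size
  x1 <- x0 + sz; y1 <- y0 + sz

  for (d in buffers) {
    area <- buffer_area_km2(sz, d)
    for (cls in road_classes) {
      len_m <- numeric(nc)
      for (g in road_lines[[cls]]) {
        for (s in seq_len(nrow(g) - 1L)) {
          len_m <- len_m + seg_len_in_buffer_cells(g[s, ], g[s + 1L, ],
                                                   x0, y0, x1, y1, d)
        }
      }
      mat[, paste0("KLS_", cls, "_", d)] <- (len_m / 1000) / area
    }
    for (lay_nm in c("food_service", "gas_stations")) {
      pts <- layers[[lay_nm]]
      cnt <- numeric(nc)
      if (!is.null(pts) && nrow(pts) > 0) {
        for (k in seq_len(nrow(pts))) {
          cnt <- cnt + (dist_point_rect(pts$x[k], pts$y[k],
                                        x0, y0, x1, y1) <= d)
        }
      }
      col <- if (lay_nm == "food_service") "KLS_food_service_" else
        "KLS_gas_station_"
      mat[, paste0(col, d)] <- cnt / area
    }
    if (length(ind_mats) > 0) {
      near <- rep(FALSE, nc)
      for (g in ind_mats) {
        bb <- c(range(g[, 1]), range(g[, 2]))
        near <- near | !(bb[1] > x1 + d | bb[2] < x0 - d |
                           bb[3] > y1 + d | bb[4] < y0 - d)
      }
      share <- numeric(nc)
      for (i in which(near)) {
        share[i] <- industrial_share(ind_mats, c(x0[i], y0[i], sz[i]), d)
      }
      mat[, paste0("KLS_industrial_", d)] <- share
    }
  }
  attr(mat, "zero_fraction") <- colMeans(mat == 0)
  mat
}

# length of one segment within distance d of every grid cell at once.
# Axis-aligned segments (the common case for gridded road networks) use the
# exact chord-overlap closed form; anything else falls back to the generic
# parameter-interval method per nearby cell.
seg_len_in_buffer_cells <- function(p, q, x0, y0, x1, y1, d) {
  nc <- length(x0)
  out <- numeric(nc)
  if (p[1] == q[1] || p[2] == q[2]) {
    if (p[1] == q[1]) {           # vertical: constant x = a
      a <- p[1]
      dx <- pmax(0, x0 - a, a - x1)
      lo <- min(p[2], q[2]); hi <- max(p[2], q[2])
      extent_lo <- y0; extent_hi <- y1
    } else {                      # horizontal: constant y = a
      a <- p[2]
      dx <- pmax(0, y0 - a, a - y1)
      lo <- min(p[1], q[1]); hi <- max(p[1], q[1])
      extent_lo <- x0; extent_hi <- x1
    }
    ok <- dx <= d
    h <- numeric(nc)
    h[ok] <- sqrt(d^2 - dx[ok]^2)
    ov <- pmax(0, pmin(hi, extent_hi + h) - pmax(lo, extent_lo - h))
    out[ok] <- ov[ok]
    return(out)
  }
  bb <- c(min(p[1], q[1]), max(p[1], q[1]), min(p[2], q[2]), max(p[2], q[2]))
  cand <- which(!(bb[1] > x1 + d | bb[2] < x0 - d |
                    bb[3] > y1 + d | bb[4] < y0 - d))
  for (i in cand) {
    out[i] <- seg_len_in_buffer(p, q, x0[i], y0[i], x1[i], y1[i], d)
  }
  out
}

# error when non-empty layers lie entirely outside the (buffered) grid
# extent, which indicates mismatched coordinate systems.
check_layer_extent <- function(layers, grid, d_max) {
  gx <- range(grid$x0, grid$x0 + grid$size) + c(-d_max, d_max)
  gy <- range(grid$y0, grid$y0 + grid$size) + c(-d_max, d_max)
  xs <- ys <- numeric(0)
  if (!is.null(layers$roads) && nrow(layers$roads) > 0) {
    for (g in layers$roads$geometry) { xs <- c(xs, g[, 1]); ys <- c(ys, g[, 2]) }
  }
  for (nm in c("food_service", "gas_stations")) {
    p <- layers[[nm]]
    if (!is.null(p) && nrow(p) > 0) { xs <- c(xs, p$x); ys <- c(ys, p$y) }
  }
  for (g in industrial_mats(layers$industrial)) {
    xs <- c(xs, g[, 1]); ys <- c(ys, g[, 2])
  }
  if (length(xs) > 0 &&
      (max(xs) < gx[1] || min(xs) > gx[2] ||
       max(ys) < gy[1] || min(ys) > gy[2])) {
    stop("layer extent does not overlap the grid extent; ",
         "check that all inputs share one projected coordinate system")
  }
  invisible(TRUE)
}
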