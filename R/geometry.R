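# Planar geometry toolkit (projected meters, no geodesy).
#
# All polygons are two-column matrices of vertices (x, y), not closed
# (first vertex is not repeated).  Grid cells and buffers are axis-aligned;
# clip regions are convex, so Sutherland-Hodgman clipping is exact.

# Shoelace area (absolute), vertices in any orientation.
poly_area <- function(xy) {
  n <- nrow(xy)
  if (is.null(n) || n < 3) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

poly_signed_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

# Ensure counter-clockwise orientation.
poly_ccw <- function(xy) {
  if (poly_signed_area(xy) < 0) xy[rev(seq_len(nrow(xy))), , drop = FALSE] else xy
}

rect_poly <- function(x0, y0, x1, y1) {
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}

# Sutherland-Hodgman: clip an arbitrary simple polygon against a convex
# clip polygon (CCW).  Exact for convex clip regions; degenerate boundary
# runs produced by non-convex subjects carry zero area.
clip_poly_convex <- function(subject, clip) {
  clip <- poly_ccw(clip)
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (is.null(out) || nrow(out) < 3) return(NULL)
    a <- clip[i, ]; b <- clip[if (i == nc) 1L else i + 1L, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    # signed distance to the left of edge a->b
    side <- ex * (out[, 2] - a[2]) - ey * (out[, 1] - a[1])
    n <- nrow(out)
    nxt <- c(2:n, 1L)
    keep_x <- numeric(0); keep_y <- numeric(0)
    for (j in seq_len(n)) {
      k <- nxt[j]
      in_j <- side[j] >= 0; in_k <- side[k] >= 0
      if (in_j) {
        keep_x <- c(keep_x, out[j, 1]); keep_y <- c(keep_y, out[j, 2])
      }
      if (xor(in_j, in_k)) {
        t <- side[j] / (side[j] - side[k])
        keep_x <- c(keep_x, out[j, 1] + t * (out[k, 1] - out[j, 1]))
        keep_y <- c(keep_y, out[j, 2] + t * (out[k, 2] - out[j, 2]))
      }
    }
    out <- cbind(keep_x, keep_y)
  }
  if (is.null(out) || nrow(out) < 3) NULL else unname(out)
}

# Area of polygon intersected with an axis-aligned rectangle.
poly_rect_area <- function(xy, x0, y0, x1, y1) {
  bb <- c(range(xy[, 1]), range(xy[, 2]))
  if (bb[2] <= x0 || bb[1] >= x1 || bb[4] <= y0 || bb[3] >= y1) return(0)
  clipped <- clip_poly_convex(xy, rect_poly(x0, y0, x1, y1))
  if (is.null(clipped)) 0 else poly_area(clipped)
}

# Euclidean distance from a point to an axis-aligned rectangle (0 inside).
dist_point_rect <- function(px, py, x0, y0, x1, y1) {
  dx <- pmax(x0 - px, 0, px - x1)
  dy <- pmax(y0 - py, 0, py - y1)
  sqrt(dx * dx + dy * dy)
}

# Distance from points to a polyline (matrix of vertices).
dist_point_polyline <- function(px, py, line) {
  n <- nrow(line)
  d2 <- rep(Inf, length(px))
  for (i in seq_len(n - 1L)) {
    ax <- line[i, 1]; ay <- line[i, 2]
    bx <- line[i + 1L, 1]; by <- line[i + 1L, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx * vx + vy * vy
    t <- if (L2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2))
    dx <- px - (ax + t * vx); dy <- py - (ay + t * vy)
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  sqrt(d2)
}

# --- segment-in-buffer length ------------------------------------------------
# The buffered region of a rectangle R at distance d is the union of
#   H = [x0-d, x1+d] x [y0, y1]
#   V = [x0, x1] x [y0-d, y1+d]
#   four disks of radius d at the rectangle corners.
# The portion of a segment inside the union is found exactly as the union of
# parameter intervals.

# t-interval of segment p->q inside an axis rectangle, or NULL.
seg_interval_rect <- function(p, q, x0, y0, x1, y1) {
  t0 <- 0; t1 <- 1
  for (dim in 1:2) {
    a <- p[dim]; b <- q[dim]
    lo <- if (dim == 1) x0 else y0
    hi <- if (dim == 1) x1 else y1
    dv <- b - a
    if (dv == 0) {
      if (a < lo || a > hi) return(NULL)
    } else {
      ta <- (lo - a) / dv; tb <- (hi - a) / dv
      if (ta > tb) { tmp <- ta; ta <- tb; tb <- tmp }
      t0 <- max(t0, ta); t1 <- min(t1, tb)
      if (t0 > t1) return(NULL)
    }
  }
  c(t0, t1)
}

# t-interval of segment inside a disk, or NULL.
seg_interval_disk <- function(p, q, cx, cy, r) {
  dx <- q[1] - p[1]; dy <- q[2] - p[2]
  fx <- p[1] - cx; fy <- p[2] - cy
  a <- dx * dx + dy * dy
  b <- 2 * (fx * dx + fy * dy)
  cc <- fx * fx + fy * fy - r * r
  if (a == 0) return(if (cc <= 0) c(0, 1) else NULL)
  disc <- b * b - 4 * a * cc
  if (disc <= 0) return(NULL)
  s <- sqrt(disc)
  t0 <- max(0, (-b - s) / (2 * a)); t1 <- min(1, (-b + s) / (2 * a))
  if (t0 >= t1) NULL else c(t0, t1)
}

# Measure of the union of [lo, hi] intervals.
interval_union_length <- function(ints) {
  if (length(ints) == 0) return(0)
  m <- do.call(rbind, ints)
  o <- order(m[, 1])
  m <- m[o, , drop = FALSE]
  tot <- 0; cur_lo <- m[1, 1]; cur_hi <- m[1, 2]
  for (i in seq_len(nrow(m))[-1]) {
    if (m[i, 1] > cur_hi) {
      tot <- tot + (cur_hi - cur_lo)
      cur_lo <- m[i, 1]; cur_hi <- m[i, 2]
    } else cur_hi <- max(cur_hi, m[i, 2])
  }
  tot + (cur_hi - cur_lo)
}

# Exact length of the part of segment p->q within distance d of rectangle.
seg_len_in_buffer <- function(p, q, x0, y0, x1, y1, d) {
  ints <- list()
  r1 <- seg_interval_rect(p, q, x0 - d, y0, x1 + d, y1)
  if (!is.null(r1)) ints[[length(ints) + 1L]] <- r1
  r2 <- seg_interval_rect(p, q, x0, y0 - d, x1, y1 + d)
  if (!is.null(r2)) ints[[length(ints) + 1L]] <- r2
  for (cx in c(x0, x1)) for (cy in c(y0, y1)) {
    di <- seg_interval_disk(p, q, cx, cy, d)
    if (!is.null(di)) ints[[length(ints) + 1L]] <- di
  }
  L <- sqrt(sum((q - p)^2))
  L * interval_union_length(ints)
}

# Length of a polyline within distance d of a rectangle.
polyline_len_in_buffer <- function(line, x0, y0, x1, y1, d) {
  tot <- 0
  for (i in seq_len(nrow(line) - 1L)) {
    tot <- tot + seg_len_in_buffer(line[i, ], line[i + 1L, ], x0, y0, x1, y1, d)
  }
  tot
}

# Polygonal approximation of the buffered rectangle (rounded corners),
# n_arc segments per quarter circle.  d = 0 returns the rectangle itself.
buffer_poly <- function(x0, y0, x1, y1, d, n_arc = 24L) {
  if (d == 0) return(rect_poly(x0, y0, x1, y1))
  th <- function(a0, a1) seq(a0, a1, length.out = n_arc + 1L)
  corner <- function(cx, cy, a0, a1)
    cbind(cx + d * cos(th(a0, a1)), cy + d * sin(th(a0, a1)))
  rbind(
    corner(x1, y0, -pi / 2, 0),
    corner(x1, y1, 0, pi / 2),
    corner(x0, y1, pi / 2, pi),
    corner(x0, y0, pi, 3 * pi / 2)
  )
}

# Area of the union of simple convex polygons, each first clipped to the
# convex region `clip`.  Union via connected overlap components and
# inclusion-exclusion (convexity keeps every intersection term convex).
poly_union_area_in <- function(polys, clip) {
  clipped <- list()
  for (p in polys) {
    cp <- clip_poly_convex(p, clip)
    if (!is.null(cp) && poly_area(cp) > 0) clipped[[length(clipped) + 1L]] <- cp
  }
  k <- length(clipped)
  if (k == 0) return(0)
  if (k == 1) return(poly_area(clipped[[1]]))
  # overlap adjacency
  inter <- function(a, b) clip_poly_convex(a, poly_ccw(b))
  adj <- matrix(FALSE, k, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ij <- inter(clipped[[i]], clipped[[j]])
    adj[i, j] <- adj[j, i] <- !is.null(ij) && poly_area(ij) > 0
  }
  comp <- rep(0L, k); nc <- 0L
  for (i in seq_len(k)) if (comp[i] == 0L) {
    nc <- nc + 1L
    stack <- i
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (comp[v] == 0L) {
        comp[v] <- nc
        stack <- c(stack, which(adj[v, ] & comp == 0L))
      }
    }
  }
  total <- 0
  for (cid in seq_len(nc)) {
    idx <- which(comp == cid)
    m <- length(idx)
    if (m == 1) { total <- total + poly_area(clipped[[idx]]); next }
    if (m > 16) stop("too many mutually overlapping polygons for exact union")
    for (s in seq_len(2^m - 1L)) {
      members <- idx[bitwAnd(s, bitwShiftL(1L, seq_len(m) - 1L)) != 0L]
      cur <- clipped[[members[1]]]
      for (mm in members[-1]) {
        cur <- inter(cur, clipped[[mm]])
        if (is.null(cur)) break
      }
      if (!is.null(cur)) {
        sgn <- if (length(members) %% 2 == 1) 1 else -1
        total <- total + sgn * poly_area(cur)
      }
    }
  }
  total
}
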