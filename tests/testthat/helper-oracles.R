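# Independent oracles and small builders shared across tests.
# These re-derive quantities by different routes than the implementation:
# brute-force tree walks, weight-expanded quantiles, fine discretization.

# walk one serialized draw matrix (columns tree/var/split/leaf/left/right,
# 0-based indices) for a single row; independent of the package's C++ path.
oracle_predict_row <- function(tm, X, i, override_var = NA, override_val = NA) {
  roots <- which(c(TRUE, diff(tm[, "tree"]) != 0))
  total <- 0
  for (r in roots) {
    node <- r
    repeat {
      v <- tm[node, "var"]
      if (v < 0) { total <- total + tm[node, "leaf"]; break }
      xv <- if (!is.na(override_var) && v == override_var) override_val else
        X[i, v + 1]
      node <- if (xv < tm[node, "split"]) tm[node, "left"] + 1 else
        tm[node, "right"] + 1
    }
  }
  total
}

oracle_predict <- function(fit, X) {
  nd <- length(fit$draws)
  out <- matrix(0, nd, nrow(X))
  for (d in seq_len(nd)) {
    for (i in seq_len(nrow(X))) {
      out[d, i] <- oracle_predict_row(fit$draws[[d]], X, i)
    }
  }
  (out + 0.5) * fit$transform$range + fit$transform$ymin
}

# brute-force partial dependence: loop over all rows and all retained draws
oracle_pdp <- function(fit, j, eval_values, X = fit$X) {
  nd <- length(fit$draws)
  n <- nrow(X)
  out <- matrix(0, nd, length(eval_values))
  for (d in seq_len(nd)) {
    tm <- fit$draws[[d]]
    for (e in seq_along(eval_values)) {
      s <- 0
      for (i in seq_len(n)) {
        s <- s + oracle_predict_row(tm, X, i, j - 1, eval_values[e])
      }
      out[d, e] <- s / n
    }
  }
  (out + 0.5) * fit$transform$range + fit$transform$ymin
}

# hand-crafted posterior with identity response transform: tree sums ARE the
# predictions.  `draws` is a list of draw matrices in the serialized layout.
make_posterior <- function(draws, X, y = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  structure(list(degenerate = FALSE, draws = draws,
                 sigma2 = rep(1, length(draws)), train_fit_z = NULL,
                 transform = list(ymin = -0.5, ymax = 0.5, range = 1),
                 feature_names = colnames(X), X = X,
                 y = if (is.null(y)) rep(0, nrow(X)) else y,
                 config = bart_config(n_trees = max(draws[[1]][, "tree"]) + 1,
                                      n_burn = 0, n_post = length(draws))),
            class = "ld_bart")
}

# single tree splitting on variable `var` (1-based) at `split`:
# prediction `left` when x < split, `right` otherwise
one_split_draw <- function(var, split, left, right, tree = 0) {
  m <- rbind(c(tree, var - 1, split, 0, 1, 2),
             c(tree, -1, 0, left, -1, -1),
             c(tree, -1, 0, right, -1, -1))
  colnames(m) <- c("tree", "var", "split", "leaf", "left", "right")
  m
}

leaf_only_draw <- function(value, tree = 0) {
  m <- rbind(c(tree, -1, 0, value, -1, -1))
  colnames(m) <- c("tree", "var", "split", "leaf", "left", "right")
  m
}

# weighted quantile oracle: expand integer weights and take type-2 quantiles
expanded_quantile <- function(x, w, probs) {
  stopifnot(all(w == round(w)))
  stats::quantile(rep(x, times = w), probs, type = 2, names = FALSE)
}

# tiny scene-like object for truth-surface tests: a bare grid plus chosen
# source layers, bypassing the generator
bare_scene <- function(cells_x0, cells_y0, size = 100,
                       roads = NULL, food = NULL, gas = NULL,
                       industrial = NULL) {
  structure(list(
    grid = tibble::tibble(cell_id = seq_along(cells_x0), x0 = cells_x0,
                          y0 = cells_y0, size = size),
    roads = if (is.null(roads)) {
      tibble::tibble(road_id = integer(0), class = character(0),
                     geometry = list())
    } else roads,
    food_service = if (is.null(food)) tibble::tibble(x = numeric(0),
                                                     y = numeric(0)) else food,
    gas_stations = if (is.null(gas)) tibble::tibble(x = numeric(0),
                                                    y = numeric(0)) else gas,
    industrial = if (is.null(industrial)) {
      tibble::tibble(x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
                     y1 = numeric(0))
    } else industrial
  ), class = "ld_scene")
}

# grid-free length of a polyline within distance d of a rectangle, by fine
# discretization (independent of the exact interval method)
discretized_len_in_buffer <- function(line, x0, y0, x1, y1, d, step = 0.01) {
  total <- 0
  for (i in seq_len(nrow(line) - 1L)) {
    p <- line[i, ]; q <- line[i + 1L, ]
    L <- sqrt(sum((q - p)^2))
    k <- max(2L, ceiling(L / step))
    t <- (seq_len(k) - 0.5) / k
    px <- p[1] + t * (q[1] - p[1]); py <- p[2] + t * (q[2] - p[2])
    dd <- localdiff:::dist_point_rect(px, py, x0, y0, x1, y1)
    total <- total + L * mean(dd <= d)
  }
  total
}
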