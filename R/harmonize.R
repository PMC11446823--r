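# Harmonization of block-group-level inputs onto the monitoring grid, and
# the localized difference LD = MM - LUR that the whole analysis studies.

# overlap areas between one polygon and candidate grid cells; slivers below
# 1 m^2 are discarded for numerical robustness.
SLIVER_M2 <- 1

bg_cell_overlaps <- function(geometry, grid, bg_label = "?",
                             min_area = SLIVER_M2) {
  if (!is.matrix(geometry) || nrow(geometry) < 3 ||
      !all(is.finite(geometry)) || poly_area(geometry) <= 0) {
    stop("invalid block-group geometry for block group ", bg_label)
  }
  bb <- c(range(geometry[, 1]), range(geometry[, 2]))
  cs <- grid$size
  cand <- which(grid$x0 < bb[2] & grid$x0 + cs > bb[1] &
                  grid$y0 < bb[4] & grid$y0 + cs > bb[3])
  if (length(cand) == 0) return(NULL)
  a <- vapply(cand, function(i) {
    poly_rect_area(geometry, grid$x0[i], grid$y0[i],
                   grid$x0[i] + cs[i], grid$y0[i] + cs[i])
  }, numeric(1))
  keep <- a > min_area
  if (!any(keep)) return(NULL)
  list(cell = cand[keep], area = a[keep])
}

#' Area-weighted resampling of block-group values to grid cells
#'
#' Each cell's value is the overlap-area-weighted average of the block
#' groups intersecting it: `sum(A_g * v_g) / sum(A_g)` over overlap areas
#' `A_g`.  Cells with no overlap get `NA`.  This is how national-model
#' block-group predictions are brought onto the monitoring grid.
#'
#' @param block_groups tibble with a `geometry` list-column of polygon
#'   vertex matrices (projected meters) and the value column.
#' @param value_field name of the value column to resample.
#' @param grid the monitoring grid table (`cell_id`, `x0`, `y0`, `size`).
#' @return numeric vector along `grid` rows (named by `cell_id`).
#' @export
areal_resample <- function(block_groups, value_field, grid) {
  v <- block_groups[[value_field]]
  if (is.null(v)) stop("no column `", value_field, "` in block_groups")
  num <- den <- numeric(nrow(grid))
  for (g in seq_len(nrow(block_groups))) {
    ov <- bg_cell_overlaps(block_groups$geometry[[g]], grid,
                           bg_label = block_groups$bg_id[g] %||% g)
    if (is.null(ov)) next
    num[ov$cell] <- num[ov$cell] + ov$area * v[g]
    den[ov$cell] <- den[ov$cell] + ov$area
  }
  out <- ifelse(den > 0, num / den, NA_real_)
  names(out) <- grid$cell_id
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Allocate block-group population counts to grid cells
#'
#' Population is treated as a count, allocated proportionally to overlap
#' area: block group `g` contributes `pop_g * share_{g,r} * A(g I cell) /
#' A(g)` persons of group `r` to each cell, which conserves every group's
#' total over a fully covered domain.  Cell shares are recomputed from the
#' allocated counts.  (Averaging population counts across unequal-area
#' donors would not conserve people, so the count interpretation is used.)
#'
#' @param block_groups tibble with `geometry`, `pop` and the five
#'   `share_*` columns.
#' @param grid the monitoring grid table.
#' @return tibble along grid rows: `cell_id`, `pop`, the five `share_*`
#'   columns (NA shares where allocated pop is 0) and per-group counts
#'   `pop_asian` ... `pop_hispanic`.
#' @export
allocate_population <- function(block_groups, grid) {
  counts <- matrix(0, nrow(grid), length(SHARE_COLS),
                   dimnames = list(NULL, sub("share_", "pop_", SHARE_COLS)))
  for (g in seq_len(nrow(block_groups))) {
    geom <- block_groups$geometry[[g]]
    a_g <- poly_area(geom)
    if (a_g <= 0) {
      warning("block group ", block_groups$bg_id[g] %||% g,
              " has zero area; skipped")
      next
    }
    # no sliver cutoff here: conservation of counts is the contract
    ov <- bg_cell_overlaps(geom, grid, bg_label = block_groups$bg_id[g] %||% g,
                           min_area = 0)
    if (is.null(ov)) next
    frac <- ov$area / a_g
    for (r in seq_along(SHARE_COLS)) {
      contrib <- block_groups$pop[g] * block_groups[[SHARE_COLS[r]]][g] * frac
      counts[ov$cell, r] <- counts[ov$cell, r] + contrib
    }
  }
  pop <- rowSums(counts)
  out <- tibble::tibble(cell_id = grid$cell_id, pop = pop)
  for (r in seq_along(SHARE_COLS)) {
    out[[SHARE_COLS[r]]] <- ifelse(pop > 0, counts[, r] / pop, NA_real_)
  }
  for (r in seq_along(SHARE_COLS)) out[[colnames(counts)[r]]] <- counts[, r]
  out
}

#' Localized difference
#'
#' `LD = MM - LUR` per cell and pollutant: positive LD marks places where
#' mobile-monitoring observations exceed the national-model prediction
#' (local underprediction), negative LD overprediction.  Cells missing
#' either input yield `NA` and are counted in attribute `n_excluded`.
#'
#' @param mm,lur numeric vectors of mobile-monitoring estimates and
#'   resampled national predictions on the same cells.
#' @return numeric vector of localized differences.
#' @export
compute_ld <- function(mm, lur) {
  if (length(mm) != length(lur)) stop("mm and lur must have equal length")
  ld <- mm - lur
  structure(ld, n_excluded = sum(is.na(mm) | is.na(lur)))
}

#' Compare national predictions with mobile-monitoring estimates
#'
#' The scatter-plot summary of model-vs-observation agreement: ordinary
#' least squares of MM on LUR (slope, intercept, R^2, slope p-value) plus
#' marginal medians and quartiles of both sets.  A zero-variance predictor
#' is flagged and left unfitted.
#'
#' @param mm,lur paired per-cell values (NA pairs dropped).
#' @param pollutant optional label carried into the output row.
#' @return one-row tibble: `pollutant`, `n`, `slope`, `intercept`, `r2`,
#'   `p_value`, `mm_median`, `mm_q25`, `mm_q75`, `lur_median`, `lur_q25`,
#'   `lur_q75`, `degenerate`.
#' @export
ols_compare <- function(mm, lur, pollutant = NA_character_) {
  ok <- !is.na(mm) & !is.na(lur)
  mm <- mm[ok]; lur <- lur[ok]
  if (length(mm) < 3) stop("ols_compare needs at least 3 paired cells")
  qs <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  qm <- qs(mm); ql <- qs(lur)
  degenerate <- stats::sd(lur) == 0
  if (degenerate) {
    warning("zero-variance predictor; OLS fit skipped")
    slope <- intercept <- r2 <- p <- NA_real_
  } else {
    fit <- stats::lm(mm ~ lur)
    sm <- summary(fit)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    r2 <- sm$r.squared
    p <- unname(sm$coefficients[2, 4])
  }
  tibble::tibble(pollutant = pollutant, n = length(mm),
                 slope = slope, intercept = intercept, r2 = r2, p_value = p,
                 mm_median = qm[2], mm_q25 = qm[1], mm_q75 = qm[3],
                 lur_median = ql[2], lur_q25 = ql[1], lur_q75 = ql[3],
                 degenerate = degenerate)
}
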