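# Demographic analyses of localized difference: population-weighted LD
# distributions by racial/ethnic group, the demographics-only Model A, the
# demographics-plus-sources Model B, and the attenuation of demographic
# partial-dependence ranges between them.

# Weighted quantile: left-continuous inverse of the weighted ECDF, with the
# midpoint convention at exact crossings.  With integer weights this equals
# the ordinary (type 2) quantile of the weight-expanded sample.
weighted_quantile <- function(x, w, probs) {
  ok <- !is.na(x) & !is.na(w) & w > 0
  x <- x[ok]; w <- w[ok]
  if (length(x) == 0) return(rep(NA_real_, length(probs)))
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w)
  W <- cw[length(cw)]
  eps <- 1e-9 * W
  vapply(probs, function(p) {
    target <- p * W
    i <- which(cw >= target - eps)[1]
    if (abs(cw[i] - target) <= eps && i < length(x)) {
      (x[i] + x[i + 1]) / 2
    } else {
      x[i]
    }
  }, numeric(1))
}

#' Population-weighted LD distribution by racial/ethnic group
#'
#' For each group, the quartiles of the localized difference weighted by
#' that group's allocated population per cell: the distribution of LD as
#' experienced by that group's residents.  Cells with zero weight are
#' ignored; a group with no weight anywhere is omitted with a warning.
#'
#' @param ld per-cell localized difference.
#' @param group_counts per-cell allocated counts per group: a data frame or
#'   matrix whose columns are groups (e.g. the `pop_*` columns of
#'   [allocate_population()]).
#' @param probs quantile probabilities (default quartiles).
#' @return tibble: `group`, `q25`, `median`, `q75` (or the requested
#'   probabilities as `q<100p>` columns), `total_weight`.
#' @export
population_weighted_quantiles <- function(ld, group_counts,
                                          probs = c(0.25, 0.5, 0.75)) {
  gc <- as.data.frame(group_counts)
  rows <- list()
  for (g in names(gc)) {
    w <- gc[[g]]
    tw <- sum(w[!is.na(ld)], na.rm = TRUE)
    if (tw <= 0) {
      warning("group `", g, "` has zero total weight; omitted")
      next
    }
    q <- weighted_quantile(ld, w, probs)
    row <- tibble::tibble(group = g, total_weight = tw)
    for (k in seq_along(probs)) {
      nm <- if (probs[k] == 0.5) "median" else paste0("q", round(100 * probs[k]))
      row[[nm]] <- q[k]
    }
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  # conventional column order
  qcols <- setdiff(names(out), c("group", "total_weight"))
  out[, c("group", qcols, "total_weight")]
}

demo_design <- function(pop, shares) {
  shares <- as.data.frame(shares)[, SHARE_COLS]
  X <- cbind(Pop = pop, as.matrix(shares))
  storage.mode(X) <- "double"
  X
}

#' Model A: localized difference from demographics alone
#'
#' BART fit of LD on total population and the five racial/ethnic shares of
#' the block groups overlapping each cell, with partial dependence curves
#' for every predictor.  A positive share PDP means the national model
#' systematically underpredicts where that group's share is higher.
#'
#' @param pop per-cell allocated population.
#' @param shares per-cell share columns (`share_asian` ... `share_hispanic`).
#' @param ld per-cell localized difference (one pollutant).
#' @param config a [bart_config()].
#' @param pdp_features predictors to compute PDPs for (default all six).
#' @return list of class `ld_equity_model`: `fit` (the `ld_bart`) and
#'   `pdps` (named list of `ld_pdp`).
#' @export
fit_model_a <- function(pop, shares, ld, config = bart_config(),
                        pdp_features = NULL) {
  X <- demo_design(pop, shares)
  fit <- bart_fit(X, ld, config)
  if (is.null(pdp_features)) pdp_features <- colnames(X)
  pdps <- lapply(pdp_features, function(f) partial_dependence(fit, f))
  names(pdps) <- pdp_features
  structure(list(fit = fit, pdps = pdps, model = "A"),
            class = "ld_equity_model")
}

#' Model B: demographics plus known local sources
#'
#' Adds the 21 KLS densities to Model A's predictors.  Demographic PDPs
#' are evaluated on Model A's evaluation grid when one is supplied, making
#' the A-to-B attenuation a numeric (not visual) comparison.
#'
#' @param pop,shares,ld,config as in [fit_model_a()].
#' @param kls_matrix cells x 21 feature matrix from
#'   [build_feature_matrix()].
#' @param model_a optional Model A result whose PDP grids are frozen into
#'   the Model B demographic PDPs.
#' @param pdp_features demographic predictors to compute PDPs for.
#' @return list of class `ld_equity_model` (`fit`, `pdps`).
#' @export
fit_model_b <- function(pop, shares, kls_matrix, ld, config = bart_config(),
                        model_a = NULL, pdp_features = NULL) {
  X <- cbind(demo_design(pop, shares), as.matrix(kls_matrix))
  fit <- bart_fit(X, ld, config)
  if (is.null(pdp_features)) {
    pdp_features <- if (!is.null(model_a)) names(model_a$pdps) else
      colnames(demo_design(pop, shares))
  }
  pdps <- lapply(pdp_features, function(f) {
    ev <- if (!is.null(model_a) && f %in% names(model_a$pdps)) {
      model_a$pdps[[f]]$value
    } else NULL
    partial_dependence(fit, f, eval_values = ev)
  })
  names(pdps) <- pdp_features
  structure(list(fit = fit, pdps = pdps, model = "B"),
            class = "ld_equity_model")
}

#' @export
print.ld_equity_model <- function(x, ...) {
  cat("<ld_equity_model> Model", x$model, "\n")
  cat("  predictors:", length(x$fit$feature_names),
      " pseudo-R2:", signif(pseudo_r2(x$fit), 3), "\n")
  cat("  PDPs:", paste(names(x$pdps), collapse = ", "), "\n")
  invisible(x)
}

#' Attenuation of a partial-dependence relationship from Model A to Model B
#'
#' The amplitude of each mean PDP curve (max minus min over the shared
#' evaluation grid, which spans the 5th to 95th percentile of the
#' predictor) is compared between the demographics-only model and the
#' demographics-plus-sources model.  A ratio below one means adding source
#' densities explains away part of the demographic relationship.
#'
#' @param pdp_a,pdp_b `ld_pdp` objects for the same predictor on identical
#'   evaluation grids.
#' @return one-row tibble: `predictor`, `range_a`, `range_b`, `diff`
#'   (range_b - range_a), `ratio` (range_b / range_a; 1 when both are
#'   flat).
#' @export
pdp_attenuation <- function(pdp_a, pdp_b) {
  fa <- attr(pdp_a, "feature"); fb <- attr(pdp_b, "feature")
  if (!identical(fa, fb)) stop("PDPs are for different predictors: ",
                               fa, " vs ", fb)
  if (length(pdp_a$value) != length(pdp_b$value) ||
      max(abs(pdp_a$value - pdp_b$value)) > 1e-9) {
    stop("PDP evaluation grids differ; refit Model B with model_a= to freeze the grid")
  }
  range_a <- max(pdp_a$mean) - min(pdp_a$mean)
  range_b <- max(pdp_b$mean) - min(pdp_b$mean)
  ratio <- if (range_a == 0 && range_b == 0) 1 else
    if (range_a == 0) Inf else range_b / range_a
  tibble::tibble(predictor = fa, range_a = range_a, range_b = range_b,
                 diff = range_b - range_a, ratio = ratio)
}

#' @rdname pdp_attenuation
#' @param model_a,model_b `ld_equity_model` results sharing PDP predictors.
#' @return `attenuation_report`: one row per shared predictor.
#' @export
attenuation_report <- function(model_a, model_b) {
  shared <- intersect(names(model_a$pdps), names(model_b$pdps))
  do.call(rbind, lapply(shared, function(f) {
    pdp_attenuation(model_a$pdps[[f]], model_b$pdps[[f]])
  }))
}
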