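# User-facing interface to the sum-of-trees sampler: fitting, prediction,
# partial dependence with posterior credible bands, variable-inclusion
# proportions, and the pseudo-R^2 / NRMSE fit summaries.

#' BART sampler configuration
#'
#' Defaults are the standard sum-of-trees prior: `m = 50` trees, leaf prior
#' scale `k = 2` (so leaf means have prior sd `0.5 / (k * sqrt(m))` on the
#' internally rescaled response), error-variance prior `nu = 3`, `q = 0.9`
#' (the prior puts probability `q` below the least-squares residual
#' variance), tree-depth prior `alpha = 0.95`, `beta = 2`, and
#' grow/prune/change proposal probabilities 0.28/0.28/0.44.
#'
#' @param n_trees number of trees `m` in the sum.
#' @param n_burn burn-in iterations discarded.
#' @param n_post retained posterior draws.
#' @param k leaf-prior scale; larger values shrink leaf effects harder.
#' @param nu,q error-variance prior: sigma^2 ~ nu*lambda/chi^2_nu with
#'   lambda set so P(sigma^2 < sigma_hat^2) = q.
#' @param alpha,beta depth prior: a node at depth d splits with prior
#'   probability `alpha * (1 + d)^(-beta)`.
#' @param p_grow,p_prune,p_change structural proposal probabilities
#'   (must sum to 1).
#' @param seed optional RNG seed applied at fit time.
#' @return a validated list of class `ld_bart_config`.
#' @export
bart_config <- function(n_trees = 50L, n_burn = 250L, n_post = 1000L,
                        k = 2, nu = 3, q = 0.9, alpha = 0.95, beta = 2,
                        p_grow = 0.28, p_prune = 0.28, p_change = 0.44,
                        seed = NULL) {
  cfg <- list(n_trees = as.integer(n_trees), n_burn = as.integer(n_burn),
              n_post = as.integer(n_post), k = k, nu = nu, q = q,
              alpha = alpha, beta = beta, p_grow = p_grow, p_prune = p_prune,
              p_change = p_change, seed = seed)
  stopifnot(cfg$n_trees >= 1, cfg$n_post >= 1, cfg$n_burn >= 0,
            cfg$alpha > 0, cfg$alpha < 1, cfg$beta >= 0,
            cfg$nu > 0, cfg$q > 0, cfg$q < 1, cfg$k > 0)
  if (abs(p_grow + p_prune + p_change - 1) > 1e-9) {
    stop("proposal probabilities must sum to 1")
  }
  class(cfg) <- "ld_bart_config"
  cfg
}

#' Fit a BART model
#'
#' Bayesian backfitting MCMC over a sum of `m` regression trees: per
#' iteration each tree receives a grow, prune or change proposal evaluated
#' against the residual of the other trees by Metropolis-Hastings under the
#' conjugate normal leaf prior, leaf means are drawn from their conjugate
#' posterior, and the error variance from its scaled inverse-chi-square
#' conditional.  The response is internally centered and scaled to
#' `[-0.5, 0.5]`; outputs are returned on the original scale.
#'
#' A constant response cannot inform any split: the fit degenerates to an
#' intercept-only posterior, flagged via `$degenerate`.
#'
#' @param X numeric matrix (observations x features) with column names; no
#'   missing values.
#' @param y numeric response (the localized difference, in the analyses
#'   this package targets).
#' @param config a [bart_config()].
#' @return object of class `ld_bart` holding the serialized tree draws,
#'   sigma^2 draws (original scale), per-draw in-sample fits, the response
#'   transform, and the training data.
#' @export
bart_fit <- function(X, y, config = bart_config()) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed; filter or impute first")
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (nrow(X) < 10) stop("at least 10 observations are required")
  if (!is.null(config$seed)) set.seed(config$seed)

  ymin <- min(y); ymax <- max(y)
  if (ymax == ymin) {
    fit <- structure(list(degenerate = TRUE, constant = ymin,
                          feature_names = colnames(X), X = X, y = y,
                          config = config,
                          transform = list(ymin = ymin, ymax = ymax,
                                           range = 0)),
                     class = "ld_bart")
    return(fit)
  }
  rng <- ymax - ymin
  z <- (y - ymin) / rng - 0.5
  sigma_mu <- 0.5 / (config$k * sqrt(config$n_trees))

  # data-informed scale of the error-variance prior
  sigma_hat <- if (nrow(X) > ncol(X) + 2) {
    s <- tryCatch(summary(stats::lm(z ~ X))$sigma, error = function(e) stats::sd(z))
    if (!is.finite(s) || s <= 0) stats::sd(z) else s
  } else {
    stats::sd(z)
  }
  lambda <- sigma_hat^2 * stats::qchisq(1 - config$q, config$nu) / config$nu

  res <- .bart_mcmc(X, z, config$n_trees, config$n_burn, config$n_post,
                    sigma_mu, config$nu, lambda, config$alpha, config$beta,
                    config$p_grow, config$p_prune, sigma_hat^2)
  structure(list(degenerate = FALSE,
                 draws = res$trees,
                 sigma2 = res$sigma2 * rng^2,
                 train_fit_z = res$train_fit,
                 transform = list(ymin = ymin, ymax = ymax, range = rng),
                 feature_names = colnames(X),
                 X = X, y = y, config = config),
            class = "ld_bart")
}

#' @export
print.ld_bart <- function(x, ...) {
  cat("<ld_bart> sum-of-trees posterior\n")
  if (x$degenerate) {
    cat("  degenerate: constant response", x$constant, "\n")
    return(invisible(x))
  }
  cat("  n =", nrow(x$X), " features =", length(x$feature_names),
      " trees =", x$config$n_trees, "\n")
  cat("  retained draws =", x$config$n_post,
      " (after", x$config$n_burn, "burn-in)\n")
  cat("  posterior mean sigma =", signif(mean(sqrt(x$sigma2)), 4), "\n")
  cat("  in-sample pseudo-R2 =", signif(pseudo_r2(x), 3), "\n")
  invisible(x)
}

z_to_y <- function(fit, z) (z + 0.5) * fit$transform$range + fit$transform$ymin

#' Posterior predictions
#'
#' Sums every retained draw's trees over the rows of `newdata` and maps the
#' result back to the response scale.
#'
#' @param object an `ld_bart` fit.
#' @param newdata matrix or data frame containing (at least) the training
#'   feature columns; unknown training features are an error.
#' @param ... unused.
#' @return list with `mean` (posterior-mean prediction per row) and `draws`
#'   (retained-draws x rows matrix).
#' @export
predict.ld_bart <- function(object, newdata = object$X, ...) {
  if (object$degenerate) {
    n <- nrow(as.matrix(newdata))
    return(list(mean = rep(object$constant, n),
                draws = matrix(object$constant, 1, n)))
  }
  newdata <- as.matrix(newdata)
  missing_cols <- setdiff(object$feature_names, colnames(newdata))
  if (length(missing_cols) > 0) {
    stop("newdata lacks training feature(s): ",
         paste(missing_cols, collapse = ", "))
  }
  Xn <- newdata[, object$feature_names, drop = FALSE]
  dz <- .bart_predict(object$draws, Xn, object$config$n_trees)
  dy <- z_to_y(object, dz)
  list(mean = colMeans(dy), draws = dy)
}

# evaluation grid for one feature: its quantiles, plus the exact value 0 for
# zero-inflated features where the presence/absence step is the quantity of
# interest.
pdp_eval_values <- function(x, eval_quantiles, zero_inflated_min = 0.1) {
  v <- unname(stats::quantile(x, eval_quantiles, type = 7))
  if (min(x) == 0 && mean(x == 0) >= zero_inflated_min) v <- c(0, v)
  sort(unique(v))
}

#' Partial dependence with posterior credible bands
#'
#' Friedman's partial dependence under the posterior: for each evaluation
#' value v, every training row has feature `j` replaced by v, the draw's
#' predictions are averaged over rows, and the across-draw mean and
#' credible band are reported.  The x-axis is also reported as quantiles of
#' the observed feature distribution, and for zero-inflated features the
#' exact value 0 is always included so the presence/absence contrast is
#' directly readable.
#'
#' @param fit an `ld_bart` fit.
#' @param j feature name or index.
#' @param eval_quantiles probabilities at which to evaluate (default 5% to
#'   95% in steps of 5%).
#' @param eval_values optional explicit evaluation values overriding the
#'   quantile grid (used to compare models on a frozen grid).
#' @param level credible level of the band (default 0.95).
#' @param X rows over which the other features vary (default training X).
#' @return object of class `ld_pdp`: a tibble with `value`, `quantile`
#'   (empirical CDF at the value), `mean`, `lower`, `upper`; the per-draw
#'   curves are in attribute `draws` (draws x values), the feature name in
#'   attribute `feature`.
#' @export
partial_dependence <- function(fit, j, eval_quantiles = seq(0.05, 0.95, 0.05),
                               eval_values = NULL, level = 0.95,
                               X = fit$X) {
  if (is.character(j)) {
    jn <- match(j, fit$feature_names)
    if (is.na(jn)) stop("unknown feature: ", j)
  } else {
    jn <- as.integer(j)
    if (jn < 1 || jn > length(fit$feature_names)) stop("feature index out of range")
  }
  feature <- fit$feature_names[jn]
  X <- as.matrix(X)
  if (!is.null(colnames(X))) X <- X[, fit$feature_names, drop = FALSE]
  x <- X[, jn]
  if (is.null(eval_values)) {
    if (max(x) == min(x)) {
      warning("feature `", feature, "` is constant; single-point PDP")
      eval_values <- x[1]
    } else {
      eval_values <- pdp_eval_values(x, eval_quantiles)
    }
  }
  if (fit$degenerate) {
    dy <- matrix(fit$constant, 1, length(eval_values))
  } else {
    dz <- .bart_pdp(fit$draws, X, jn - 1L, eval_values,
                    fit$config$n_trees)
    dy <- z_to_y(fit, dz)
  }
  a <- (1 - level) / 2
  out <- tibble::tibble(
    value = eval_values,
    quantile = vapply(eval_values, function(v) mean(x <= v), numeric(1)),
    mean = colMeans(dy),
    lower = apply(dy, 2, stats::quantile, probs = a),
    upper = apply(dy, 2, stats::quantile, probs = 1 - a)
  )
  attr(out, "draws") <- dy
  attr(out, "feature") <- feature
  attr(out, "level") <- level
  class(out) <- c("ld_pdp", class(out))
  out
}

#' Presence/absence contrast of a partial-dependence curve
#'
#' For sparse source features the scientifically meaningful quantity is the
#' step between absence (value 0) and presence.  The contrast is computed
#' per posterior draw, so its credible interval accounts for the full joint
#' uncertainty.
#'
#' @param pdp an `ld_pdp`.
#' @param from,to evaluation values to contrast (defaults: smallest and
#'   largest evaluated values).
#' @param level credible level.
#' @return one-row tibble: `from`, `to`, `step` (posterior mean of
#'   PDP(to) - PDP(from)), `lower`, `upper`.
#' @export
pdp_step <- function(pdp, from = min(pdp$value), to = max(pdp$value),
                     level = 0.95) {
  draws <- attr(pdp, "draws")
  i_from <- which.min(abs(pdp$value - from))
  i_to <- which.min(abs(pdp$value - to))
  delta <- draws[, i_to] - draws[, i_from]
  a <- (1 - level) / 2
  tibble::tibble(from = pdp$value[i_from], to = pdp$value[i_to],
                 step = mean(delta),
                 lower = unname(stats::quantile(delta, a)),
                 upper = unname(stats::quantile(delta, 1 - a)))
}

#' Variable-inclusion proportions
#'
#' For each retained draw, the fraction of all split rules that use each
#' feature (a draw whose trees hold no splits contributes the uniform
#' 1/p), averaged over draws.  Proportions sum to one.
#'
#' @param fit an `ld_bart` fit.
#' @return named numeric vector over the training features.
#' @export
variable_inclusion_proportions <- function(fit) {
  p <- length(fit$feature_names)
  if (fit$degenerate) {
    return(stats::setNames(rep(1 / p, p), fit$feature_names))
  }
  acc <- numeric(p)
  for (d in fit$draws) {
    vars <- d[, "var"]
    vars <- vars[vars >= 0]
    if (length(vars) == 0) {
      acc <- acc + 1 / p
    } else {
      acc <- acc + tabulate(vars + 1L, nbins = p) / length(vars)
    }
  }
  stats::setNames(acc / length(fit$draws), fit$feature_names)
}

#' @rdname variable_inclusion_proportions
#' @param k number of top-ranked features to return (default 8, the number
#'   the downstream source analysis focuses on).
#' @return `top_vip`: tibble `feature`, `vip`, sorted decreasing.
#' @export
top_vip <- function(fit, k = 8) {
  vip <- sort(variable_inclusion_proportions(fit), decreasing = TRUE)
  k <- min(k, length(vip))
  tibble::tibble(feature = names(vip)[seq_len(k)],
                 vip = unname(vip[seq_len(k)]))
}

posterior_mean_fit <- function(fit, X, y) {
  if (fit$degenerate) return(rep(fit$constant, length(y)))
  if (!is.null(fit$train_fit_z) &&
      identical(dim(X), dim(fit$X)) && isTRUE(all.equal(X, fit$X))) {
    colMeans(z_to_y(fit, fit$train_fit_z))
  } else {
    predict(fit, X)$mean
  }
}

#' Model-fit summaries
#'
#' `pseudo_r2` is `1 - SSE/SST` with SSE from the posterior-mean in-sample
#' predictions and SST about the observed mean; a zero-variance response
#' gives 0 (flagged via attribute `degenerate`).  `nrmse` is the RMSE of
#' the posterior-mean predictions normalized by the absolute value of the
#' observed mean (the mean of a localized difference can be negative); a
#' zero observed mean yields `Inf` with a warning.
#'
#' @param fit an `ld_bart` fit.
#' @param X,y evaluation data (default: training data).
#' @return a single numeric value.
#' @export
pseudo_r2 <- function(fit, X = fit$X, y = fit$y) {
  pred <- posterior_mean_fit(fit, X, y)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(structure(0, degenerate = TRUE))
  1 - sum((y - pred)^2) / sst
}

#' @rdname pseudo_r2
#' @export
nrmse <- function(fit, X = fit$X, y = fit$y) {
  pred <- posterior_mean_fit(fit, X, y)
  rmse <- sqrt(mean((y - pred)^2))
  if (mean(y) == 0) {
    warning("observed mean is zero; NRMSE undefined")
    return(structure(Inf, degenerate = TRUE))
  }
  rmse / abs(mean(y))
}
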