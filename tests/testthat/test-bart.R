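# Sum-of-trees sampler: recovery, prediction, partial dependence, VIP,
# fit summaries, invariances.

fast_cfg <- function(seed = 1, ...) {
  bart_config(n_burn = 100, n_post = 200, seed = seed, ...)
}

sim_X <- function(n, p, seed = 1) {
  set.seed(seed)
  X <- matrix(runif(n * p), n, p)
  colnames(X) <- paste0("x", seq_len(p))
  X
}

test_that("a constant response degenerates to an intercept-only posterior", {
  X <- sim_X(30, 3)
  fit <- bart_fit(X, rep(4.2, 30))
  expect_true(fit$degenerate)
  pr <- predict(fit, X)
  expect_equal(pr$mean, rep(4.2, 30))
  r2 <- pseudo_r2(fit)
  expect_equal(as.numeric(r2), 0)
  expect_true(attr(r2, "degenerate"))
})

test_that("input validation rejects NAs, short data, unknown columns", {
  X <- sim_X(20, 2)
  expect_error(bart_fit(X, c(NA, rnorm(19))), "missing values")
  expect_error(bart_fit(X[1:5, ], rnorm(5)), "at least 10")
  fit <- bart_fit(X, rnorm(20), fast_cfg())
  expect_error(predict(fit, matrix(1, 2, 1, dimnames = list(NULL, "x9"))),
               "lacks training feature")
})

test_that("a step function is recovered at plateau centers", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 500
    X <- matrix(runif(n * 3), n, 3, dimnames = list(NULL, c("x1", "x2", "x3")))
    y <- 10 * (X[, 1] > 0.5) + rnorm(n, 0, 1)
    fit <- bart_fit(X, y, fast_cfg(seed = seed))
    pred <- predict(fit)$mean
    lo <- X[, 1] < 0.25; hi <- X[, 1] > 0.75
    expect_lt(abs(mean(pred[lo]) - 0), 1)
    expect_lt(abs(mean(pred[hi]) - 10), 1)
  }
})

test_that("hand-crafted posteriors predict by exact tree walks", {
  X <- cbind(x1 = c(0.1, 0.4, 0.6, 0.9), x2 = 1:4)
  post <- make_posterior(list(one_split_draw(1, 0.5, left = 0, right = 10)), X)
  pr <- predict(post, X)
  expect_equal(pr$mean, c(0, 0, 10, 10))
  # two trees sum
  two <- rbind(one_split_draw(1, 0.5, 0, 10, tree = 0),
               leaf_only_draw(1, tree = 1))
  post2 <- make_posterior(list(two), X)
  expect_equal(predict(post2, X)$mean, c(1, 1, 11, 11))
  # prediction mean equals the mean of per-draw predictions
  post3 <- make_posterior(list(leaf_only_draw(2), leaf_only_draw(4)), X)
  pr3 <- predict(post3, X)
  expect_equal(pr3$mean, colMeans(pr3$draws))
  expect_equal(pr3$mean, rep(3, 4))
})

test_that("fitted posteriors agree with an independent tree-walk oracle", {
  X <- sim_X(40, 3, seed = 7)
  set.seed(7)
  y <- 5 * X[, 2] + rnorm(40, 0, 0.5)
  fit <- bart_fit(X, y, bart_config(n_trees = 5, n_burn = 30, n_post = 20,
                                    seed = 7))
  pr <- predict(fit, X)
  expect_equal(pr$draws, oracle_predict(fit, X), tolerance = 1e-12)
})

test_that("PDP is flat for features the trees never split on", {
  X <- cbind(x1 = runif(20), x2 = runif(20))
  post <- make_posterior(list(one_split_draw(1, 0.5, 0, 10)), X)
  pdp <- partial_dependence(post, "x2")
  expect_true(all(abs(pdp$mean - pdp$mean[1]) < 1e-12))
})

test_that("a one-split tree on x_j yields the two-level PDP", {
  set.seed(2)
  X <- cbind(x1 = runif(50), x2 = runif(50))
  th <- median(X[, 1])
  post <- make_posterior(list(one_split_draw(1, th, 0, 10)), X)
  pdp <- partial_dependence(post, "x1", eval_values = c(min(X[, 1]), max(X[, 1])))
  expect_equal(pdp$mean, c(0, 10))
  expect_equal(oracle_pdp(post, 1, pdp$value)[1, ], c(0, 10))
})

test_that("partial dependence equals the brute-force estimator", {
  X <- sim_X(60, 3, seed = 9)
  set.seed(9)
  y <- 3 * X[, 1] - 2 * X[, 3] + rnorm(60, 0, 0.3)
  fit <- bart_fit(X, y, bart_config(n_trees = 5, n_burn = 30, n_post = 15,
                                    seed = 9))
  pdp <- partial_dependence(fit, "x1", eval_quantiles = c(0.1, 0.5, 0.9))
  expect_equal(attr(pdp, "draws"), oracle_pdp(fit, 1, pdp$value),
               tolerance = 1e-11)
})

test_that("credible bands bracket the mean and widen with the level", {
  X <- sim_X(100, 2, seed = 4)
  set.seed(4)
  y <- 4 * X[, 1] + rnorm(100, 0, 0.5)
  fit <- bart_fit(X, y, fast_cfg(seed = 4))
  p95 <- partial_dependence(fit, "x1", level = 0.95)
  p80 <- partial_dependence(fit, "x1", level = 0.8)
  expect_true(all(p95$lower <= p95$mean & p95$mean <= p95$upper))
  expect_true(all(p80$lower >= p95$lower - 1e-12))
  expect_true(all(p80$upper <= p95$upper + 1e-12))
})

test_that("variable-inclusion proportions normalize and rank signal", {
  X <- cbind(x1 = runif(20), x2 = runif(20))
  post <- make_posterior(list(one_split_draw(1, 0.5, 0, 1)), X)
  vip <- variable_inclusion_proportions(post)
  expect_equal(unname(vip), c(1, 0))
  # zero-split draws contribute the uniform
  post0 <- make_posterior(list(leaf_only_draw(0)), X)
  expect_equal(unname(variable_inclusion_proportions(post0)), c(0.5, 0.5))

  X2 <- sim_X(300, 8, seed = 6)
  set.seed(6)
  y <- 8 * X2[, 4] + rnorm(300, 0, 0.5)
  fit <- bart_fit(X2, y, fast_cfg(seed = 6))
  vip2 <- variable_inclusion_proportions(fit)
  expect_equal(sum(vip2), 1, tolerance = 1e-9)
  expect_equal(names(which.max(vip2)), "x4")
  expect_equal(top_vip(fit, 3)$feature[1], "x4")
})

test_that("pseudo-R2 and NRMSE match hand arithmetic", {
  X <- cbind(x1 = c(0, 1))
  post <- make_posterior(list(leaf_only_draw(2)), X, y = c(1, 3))
  expect_equal(as.numeric(pseudo_r2(post)), 0)   # predictions at the mean
  expect_equal(as.numeric(nrmse(post)), 0.5)     # rmse 1 over |mean| 2
  # perfect predictions
  Xp <- cbind(x1 = c(0.2, 0.8))
  perfect <- make_posterior(list(one_split_draw(1, 0.5, 1, 3)), Xp,
                            y = c(1, 3))
  expect_equal(as.numeric(pseudo_r2(perfect)), 1)
  expect_equal(as.numeric(nrmse(perfect)), 0)
  # zero observed mean flags NRMSE
  z <- make_posterior(list(leaf_only_draw(0)), Xp, y = c(-1, 1))
  expect_warning(v <- nrmse(z), "undefined")
  expect_true(is.infinite(v))
})

test_that("fits are seed-reproducible and shift-equivariant", {
  X <- sim_X(80, 3, seed = 10)
  set.seed(10)
  y <- 2 * X[, 1] + rnorm(80, 0, 0.4)
  cfg <- bart_config(n_trees = 10, n_burn = 40, n_post = 30, seed = 123)
  f1 <- bart_fit(X, y, cfg)
  f2 <- bart_fit(X, y, cfg)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$sigma2, f2$sigma2)

  # adding a constant shifts every prediction and PDP by that constant
  f3 <- bart_fit(X, y + 7, cfg)
  expect_equal(predict(f3, X)$mean, predict(f1, X)$mean + 7,
               tolerance = 1e-12)
  p1 <- partial_dependence(f1, "x1")
  p3 <- partial_dependence(f3, "x1", eval_values = p1$value)
  expect_equal(p3$mean, p1$mean + 7, tolerance = 1e-12)
})

test_that("split values always lie within the training range", {
  X <- sim_X(50, 4, seed = 11)
  set.seed(11)
  y <- X[, 1] + rnorm(50, 0, 0.2)
  fit <- bart_fit(X, y, bart_config(n_trees = 8, n_burn = 30, n_post = 20,
                                    seed = 11))
  for (d in fit$draws) {
    internal <- d[, "var"] >= 0
    if (!any(internal)) next
    vars <- d[internal, "var"] + 1
    splits <- d[internal, "split"]
    expect_true(all(splits >= apply(X, 2, min)[vars] &
                      splits <= apply(X, 2, max)[vars]))
  }
  expect_true(all(fit$sigma2 > 0))
})
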