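# small synthetic regression problem with a known structure
fx_ml_data <- function(n = 120, seed = 1, noise = 0.05) {
  set.seed(seed)
  cov <- gen_covariates(n, seed)
  cov$y <- 2 * (cov$sand / 100) + 0.5 * (cov$mbc / 300) + rnorm(n, 0, noise)
  cov
}

test_that("stratified partition is disjoint, exhaustive and reproducible", {
  d <- fx_ml_data(100)
  p <- partition(d, "y", 0.75, seed = 42)
  expect_equal(length(p$train), 75)
  expect_equal(length(p$test), 25)
  expect_equal(sort(c(p$train, p$test)), 1:100)
  expect_identical(partition(d, "y", 0.75, seed = 42), p)
  expect_false(identical(partition(d, "y", 0.75, seed = 43)$train, p$train))
})

test_that("stratification represents both modes of a bimodal response", {
  set.seed(1)
  d <- data.frame(y = c(rnorm(40, 0, 0.1), rnorm(40, 10, 0.1)))
  for (s in 1:25) {
    p <- partition(d, "y", 0.75, seed = s)
    expect_true(any(d$y[p$test] < 5) && any(d$y[p$test] > 5))
    expect_true(any(d$y[p$train] < 5) && any(d$y[p$train] > 5))
  }
})

test_that("tiny data fall back to a simple random split with a warning", {
  d <- data.frame(y = rnorm(6))
  expect_warning(p <- partition(d, "y", 0.5, seed = 1), "stratify")
  expect_equal(sort(c(p$train, p$test)), 1:6)
})

test_that("MLR reproduces a nearly linear response", {
  d <- fx_ml_data(150, noise = 0.001)
  m <- train_model(d, "y", method = "mlr", transform = "identity",
                   cv = list(folds = 5, repeats = 1), seed = 1)
  expect_gt(m$metrics_train$r2, 0.999)
  expect_equal(predict(m, d[1:5, ]), unname(d$y[1:5]), tolerance = 0.05)
})

test_that("the GBM grid enumerates the full tree/depth/shrinkage lattice", {
  g <- default_grid("gbm")
  expect_equal(nrow(g), 5 * 7 * 2)
  expect_true(all(g$n_minobsinnode == 10))
  expect_setequal(unique(g$n_trees), c(10, 50, 100, 150, 200))
  expect_setequal(unique(g$interaction_depth), 1:7)
  expect_setequal(unique(g$shrinkage), c(0.01, 0.1))
})

test_that("grid search scores every candidate and picks the CV-best", {
  d <- fx_ml_data(120, noise = 0.1)
  grid <- expand.grid(n_trees = c(20L, 60L), interaction_depth = c(2L, 4L),
                      shrinkage = 0.1, n_minobsinnode = 10L)
  m <- train_model(d, "y", method = "gbm", transform = "identity",
                   grid = grid, cv = list(folds = 3, repeats = 1), seed = 2)
  expect_equal(nrow(m$grid_results), nrow(grid))
  expect_true(all(is.finite(m$grid_results$cv_r2)))
  expect_equal(m$cv_r2, max(m$grid_results$cv_r2))
  expect_error(train_model(transform = "identity", d, "y", method = "rf",
                           grid = data.frame(ntree = 100L, mtry = 2L),
                           cv = list(folds = 3, repeats = 1), seed = 1),
               NA)
})

test_that("degenerate constant targets are rejected", {
  d <- fx_ml_data(60)
  d$y <- 1
  expect_error(train_model(d, "y", method = "mlr", transform = "identity",
                           cv = list(folds = 3, repeats = 1)),
               "constant")
})

test_that("rate targets are modeled on log10 scale and inverted on predict", {
  tab <- gen_kinetics_table(260, seed = 5)
  m3 <- tab[tab$model_type == "M3", ]
  m <- train_model(m3, "k3", method = "rf",
                   grid = data.frame(ntree = 50L, mtry = 3L),
                   cv = list(folds = 3, repeats = 1), seed = 5)
  expect_equal(m$transform, "log10")
  expect_true(all(predict(m, m3[1:20, ]) > 0))
})

test_that("RFE recovers the informative features and profiles all sizes", {
  d <- fx_ml_data(250, seed = 8, noise = 0.02)
  sel <- rfe_select(d, "y", method = "rf", folds = 5, seed = 8,
                    transform = "identity")
  expect_equal(nrow(sel$profile), 11)
  expect_true(all(c("sand", "mbc") %in% sel$features))
  expect_lt(length(sel$features), 11)
})

test_that("repeat_and_select keeps the best of the runs", {
  d <- fx_ml_data(120, seed = 3, noise = 0.2)
  res <- repeat_and_select(d, "y", method = "mlr", n_repeats = 5, seed = 10,
                           transform = "identity",
                           cv = list(folds = 3, repeats = 1))
  expect_equal(nrow(res$runs), 5)
  expect_equal(res$model$metrics_test$r2, max(res$runs$r2_test))
  one <- repeat_and_select(d, "y", method = "mlr", n_repeats = 1, seed = 10,
                           transform = "identity",
                           cv = list(folds = 3, repeats = 1))
  expect_equal(one$runs$r2_test, res$runs$r2_test[1])
})

test_that("AIC ranking prefers parsimony at equal error and is order-invariant", {
  d <- fx_ml_data(100, seed = 4, noise = 0.05)
  part <- partition(d, "y", 0.75, seed = 4)
  train <- d[part$train, ]
  m_small <- train_model(train, "y", features = c("sand", "mbc", "ph"),
                         method = "mlr", transform = "identity",
                         cv = list(folds = 3, repeats = 1), seed = 4)
  m_big <- train_model(train, "y", method = "mlr", transform = "identity",
                       cv = list(folds = 3, repeats = 1), seed = 4)
  rank <- compare_by_aic(list(small = m_small, big = m_big), d[part$test, ])
  expect_equal(rank$model[rank$winner], "small")
  rank_rev <- compare_by_aic(list(big = m_big, small = m_small),
                             d[part$test, ])
  expect_equal(sort(rank$aic), sort(rank_rev$aic))
  expect_equal(rank_rev$model[rank_rev$winner], "small")
})

test_that("AIC hand case orders p = 1 before p = 2 at equal SSE", {
  a1 <- evaluate(c(0, 0), c(1, 1), p = 1, metrics = "aic")$aic
  a2 <- evaluate(c(0, 0), c(1, 1), p = 2, metrics = "aic")$aic
  expect_equal(a1, 2.0)
  expect_equal(a2, 4.0)
  expect_lt(a1, a2)
})

test_that("importance is a percentage vector honouring known structure", {
  d <- fx_ml_data(200, seed = 6, noise = 0.02)
  m <- train_model(d, "y", method = "rf", transform = "identity",
                   grid = data.frame(ntree = 100L, mtry = 3L),
                   cv = list(folds = 3, repeats = 1), seed = 6)
  vi <- variable_importance(m)
  expect_equal(sum(vi), 100, tolerance = 1e-6)
  expect_true(all(vi >= 0))
  expect_equal(names(which.max(vi)), "sand")

  single <- train_model(d, "y", features = "sand", method = "mlr",
                        transform = "identity",
                        cv = list(folds = 3, repeats = 1), seed = 6)
  expect_equal(unname(variable_importance(single)), 100)
})

test_that("partial dependence spans [0,1] and tracks an additive component", {
  d <- fx_ml_data(200, seed = 9, noise = 0.01)
  m <- train_model(d, "y", method = "mlr", transform = "identity",
                   cv = list(folds = 3, repeats = 1), seed = 9)
  pd <- partial_dependence(m, "sand", grid_size = 15)
  expect_equal(nrow(pd), 15)
  expect_equal(range(pd$x_norm), c(0, 1))
  # the generating map is additive with slope 2/100 in sand: the PD curve
  # must match that component up to an additive constant
  comp <- 2 * pd$x / 100
  resid <- pd$yhat - comp
  expect_lt(diff(range(resid)) / diff(range(comp)), 0.05)

  d0 <- d
  d0$sand <- 50
  m0 <- train_model(d0, "y", features = c("sand", "mbc"), method = "mlr",
                    transform = "identity",
                    cv = list(folds = 3, repeats = 1), seed = 9)
  expect_error(partial_dependence(m0, "sand"), "constant")
  expect_error(partial_dependence(m, "not_a_feature"), "subset")
})
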