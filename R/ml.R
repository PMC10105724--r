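# Predictive modelling of kinetics parameters from edaphic-climatic
# covariates: MLR / random forest / gradient boosting with repeated k-fold
# cross-validation, grid search, recursive feature elimination and AIC-based
# model selection. All metrics flow through evaluate() so that a single
# implementation of the evaluation formulas is used everywhere.

.default_transform <- function(target) {
  if (grepl("k", target, fixed = TRUE)) "log10" else "identity"
}

.apply_transform <- function(y, transform) {
  switch(transform,
         identity = y,
         log10 = {
           if (any(y <= 0)) stop("log10 transform requires positive targets")
           log10(y)
         },
         stop("unknown transform: ", transform))
}

.invert_transform <- function(y, transform) {
  switch(transform, identity = y, log10 = 10^y)
}

#' Stratified train/test partition
#'
#' Random split into a training and a testing set, stratified on the target
#' by quantile bins so that the full response range is represented on both
#' sides. Falls back to a simple random split (with a warning) when the data
#' are too few to stratify.
#'
#' @param data data.frame.
#' @param target name of the response column used for stratification.
#' @param train_fraction fraction of rows in the training set (default 0.75).
#' @param seed integer seed.
#' @param bins number of quantile strata (default 5).
#' @return list with integer index vectors \code{train} and \code{test}
#'   (disjoint, exhaustive).
#' @export
partition <- function(data, target, train_fraction = 0.75, seed = 1L,
                      bins = 5L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  y <- data[[target]]
  n <- nrow(data)
  set.seed(seed)
  breaks <- unique(stats::quantile(y, seq(0, 1, length.out = bins + 1),
                                   type = 7, names = FALSE))
  strata <- if (length(breaks) > 2 && n >= 2 * bins) {
    cut(y, breaks, include.lowest = TRUE)
  } else {
    warning("too few rows (or too little spread) to stratify; simple split")
    factor(rep(1, n))
  }
  train <- integer(0)
  for (lev in levels(strata)) {
    idx <- which(strata == lev)
    if (!length(idx)) next
    k <- round(length(idx) * train_fraction)
    k <- min(max(k, if (length(idx) > 1) 1L else 0L), length(idx))
    train <- c(train, if (k > 0) sample(idx, k) else integer(0))
  }
  train <- sort(train)
  if (!length(train) || length(train) == n) {
    # degenerate rounding: force a nontrivial split
    train <- sort(sample.int(n, max(1L, min(n - 1L, round(n * train_fraction)))))
  }
  list(train = train, test = setdiff(seq_len(n), train))
}

.make_folds <- function(n, k, repeats, seed) {
  set.seed(seed)
  out <- list()
  for (r in seq_len(repeats)) {
    fold <- sample(rep(seq_len(k), length.out = n))
    for (j in seq_len(k)) {
      out[[length(out) + 1L]] <- which(fold == j)
    }
  }
  out
}

# Fit one learner on (x, y) and return a predict closure (modeling scale).
.fit_learner <- function(x, y, method, pars, seed) {
  if (method == "mlr") {
    df <- data.frame(x, .y = y, check.names = FALSE)
    fit <- stats::lm(.y ~ ., data = df)
    list(fit = fit,
         predict = function(nd) unname(stats::predict(fit, newdata = nd)))
  } else if (method == "rf") {
    set.seed(seed)
    fit <- randomForest::randomForest(
      x = x, y = y, ntree = pars$ntree, mtry = pars$mtry, importance = TRUE)
    list(fit = fit,
         predict = function(nd) unname(stats::predict(fit, newdata = nd)))
  } else if (method == "gbm") {
    dm <- xgboost::xgb.DMatrix(as.matrix(x), label = y)
    fit <- xgboost::xgb.train(
      params = list(max_depth = pars$interaction_depth, eta = pars$shrinkage,
                    min_child_weight = pars$n_minobsinnode,
                    objective = "reg:squarederror", nthread = 1,
                    seed = seed),
      data = dm, nrounds = pars$n_trees, verbose = 0)
    list(fit = fit,
         predict = function(nd) {
           unname(stats::predict(fit, as.matrix(nd)))
         })
  } else {
    stop("unknown method: ", method)
  }
}

#' Hyperparameter grids
#'
#' Default search grids: GBM varies the number of trees over
#' \{10, 50, 100, 150, 200\}, interaction depth 1-7 and shrinkage
#' \{0.01, 0.1\} with the minimum node size fixed at 10; the random forest
#' grows 100 trees and varies mtry from 2 to the number of features minus
#' one. MLR has no tuning grid.
#'
#' @param method \code{"mlr"}, \code{"rf"} or \code{"gbm"}.
#' @param n_features number of candidate features (for the RF mtry range).
#' @return data.frame of candidate hyperparameter combinations.
#' @export
default_grid <- function(method, n_features = 11L) {
  switch(method,
    mlr = data.frame(dummy = 0),
    rf = data.frame(ntree = 100L,
                    mtry = seq.int(min(2L, max(1L, n_features - 1L)),
                                   max(1L, n_features - 1L))),
    gbm = expand.grid(n_trees = c(10L, 50L, 100L, 150L, 200L),
                      interaction_depth = 1:7,
                      shrinkage = c(0.01, 0.1),
                      n_minobsinnode = 10L),
    stop("unknown method: ", method))
}

# Mean CV R2 for every grid row. For GBM the tree-count dimension is
# evaluated by training once per (depth, shrinkage) per fold at the largest
# tree count and scoring the nested prediction at each smaller count.
.cv_grid <- function(x, y, method, grid, folds, seed) {
  score <- function(pred_list) {
    mean(vapply(pred_list, function(pr) {
      evaluate(pr$obs, pr$sim, metrics = "r2")$r2
    }, numeric(1)))
  }
  if (method == "gbm") {
    combos <- unique(grid[c("interaction_depth", "shrinkage",
                            "n_minobsinnode")])
    res <- grid
    res$cv_r2 <- NA_real_
    for (ci in seq_len(nrow(combos))) {
      sel <- grid$interaction_depth == combos$interaction_depth[ci] &
        grid$shrinkage == combos$shrinkage[ci] &
        grid$n_minobsinnode == combos$n_minobsinnode[ci]
      ntrees <- sort(unique(grid$n_trees[sel]))
      per_nt <- lapply(ntrees, function(i) list())
      for (f in seq_along(folds)) {
        hold <- folds[[f]]
        pars <- list(interaction_depth = combos$interaction_depth[ci],
                     shrinkage = combos$shrinkage[ci],
                     n_minobsinnode = combos$n_minobsinnode[ci],
                     n_trees = max(ntrees))
        lrn <- .fit_learner(x[-hold, , drop = FALSE], y[-hold], "gbm", pars,
                            seed + f)
        for (ti in seq_along(ntrees)) {
          pr <- stats::predict(lrn$fit, as.matrix(x[hold, , drop = FALSE]),
                               iterationrange = c(1, ntrees[ti]))
          per_nt[[ti]][[f]] <- list(obs = y[hold], sim = pr)
        }
      }
      for (ti in seq_along(ntrees)) {
        res$cv_r2[sel & grid$n_trees == ntrees[ti]] <- score(per_nt[[ti]])
      }
    }
    return(res)
  }
  res <- grid
  res$cv_r2 <- vapply(seq_len(nrow(grid)), function(gi) {
    pars <- as.list(grid[gi, , drop = FALSE])
    preds <- lapply(seq_along(folds), function(f) {
      hold <- folds[[f]]
      lrn <- .fit_learner(x[-hold, , drop = FALSE], y[-hold], method, pars,
                          seed + f)
      list(obs = y[hold], sim = lrn$predict(x[hold, , drop = FALSE]))
    })
    score(preds)
  }, numeric(1))
  res
}

#' Train a predictive model for one kinetics parameter
#'
#' Grid-searches the method's hyperparameters by repeated k-fold
#' cross-validation (10-fold, 3 repeats by default), selects the candidate
#' with the highest mean CV R-squared, and refits it on all supplied rows.
#' Rate targets are modeled as log10(k) by default (they span several orders
#' of magnitude); the transform is recorded and inverted on prediction.
#'
#' @param data data.frame containing the features and the target.
#' @param target name of the response column.
#' @param features character vector of feature columns (default the eleven
#'   covariates, intersected with \code{names(data)}).
#' @param method \code{"mlr"}, \code{"rf"} or \code{"gbm"}.
#' @param transform \code{"auto"} (log10 for rate-like targets, identity
#'   otherwise), \code{"identity"} or \code{"log10"}.
#' @param grid hyperparameter grid (default \code{\link{default_grid}}).
#' @param cv list with \code{folds} and \code{repeats}.
#' @param seed integer seed (controls folds and learner randomness).
#' @return object of class \code{trained_model}: \code{method},
#'   \code{features}, \code{target}, \code{transform}, \code{best_params},
#'   \code{grid_results}, \code{cv_r2}, \code{fit}, \code{metrics_train}
#'   (modeling scale, via \code{\link{evaluate}}), \code{data}, \code{seed}.
#' @export
train_model <- function(data, target, features = NULL,
                        method = c("rf", "gbm", "mlr"), transform = "auto",
                        grid = NULL, cv = list(folds = 10L, repeats = 3L),
                        seed = 1L) {
  method <- match.arg(method)
  if (is.null(features)) features <- intersect(som_covariates(), names(data))
  miss <- setdiff(c(features, target), names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  x <- data[features]
  if (anyNA(x) || anyNA(data[[target]])) {
    stop("training data must be complete (gap-fill covariates upstream)")
  }
  if (transform == "auto") transform <- .default_transform(target)
  y <- .apply_transform(data[[target]], transform)
  if (stats::var(y) == 0) stop("degenerate target: constant response")
  if (is.null(grid)) grid <- default_grid(method, length(features))

  folds <- .make_folds(nrow(x), cv$folds, cv$repeats, seed)
  gres <- .cv_grid(x, y, method, grid, folds, seed)
  if (all(!is.finite(gres$cv_r2))) {
    stop("grid exhausted without a finite CV score; grid results:\n",
         paste(utils::capture.output(print(gres)), collapse = "\n"))
  }
  best_i <- which.max(gres$cv_r2)
  best <- as.list(gres[best_i, setdiff(names(gres), "cv_r2"), drop = FALSE])

  lrn <- .fit_learner(x, y, method, best, seed)
  sim <- lrn$predict(x)
  metrics_train <- evaluate(y, sim, p = length(features), warn_sse0 = FALSE)

  structure(
    list(method = method, features = features, target = target,
         transform = transform, best_params = best, grid_results = gres,
         cv_r2 = gres$cv_r2[best_i], cv = cv, fit = lrn$fit,
         metrics_train = metrics_train, data = data[c(features, target)],
         seed = seed),
    class = "trained_model")
}

# prediction on the modeling (possibly log10) scale
.predict_t <- function(model, newdata) {
  nd <- as.data.frame(newdata)[model$features]
  if (model$method == "gbm") {
    unname(stats::predict(model$fit, as.matrix(nd)))
  } else {
    unname(stats::predict(model$fit, newdata = nd))
  }
}

#' @export
predict.trained_model <- function(object, newdata, ...) {
  .invert_transform(.predict_t(object, newdata), object$transform)
}

#' Per-tree predictions of a trained random forest
#'
#' @param model a trained \code{"rf"} model.
#' @param newdata data.frame of feature values.
#' @return matrix (rows x trees) of predictions on the natural parameter
#'   scale.
#' @export
predict_trees <- function(model, newdata) {
  stopifnot(inherits(model, "trained_model"))
  if (model$method != "rf") stop("per-tree predictions require an RF model")
  nd <- as.data.frame(newdata)[model$features]
  pa <- stats::predict(model$fit, newdata = nd, predict.all = TRUE)
  .invert_transform(pa$individual, model$transform)
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("trained_model: %s -> %s [%s], %d features, CV R2 = %.3f\n",
              paste(x$features, collapse = "+"), x$target, x$method,
              length(x$features), x$cv_r2))
  invisible(x)
}

#' Recursive feature elimination
#'
#' Backward selection guided by the model's importance ranking: features are
#' ranked once on the full data, nested subsets of every size 1..p are
#' scored by k-fold cross-validation, and the best subset is returned under
#' a parsimony tie rule (among subsets within \code{tie} of the best CV
#' R-squared, the smallest wins).
#'
#' @inheritParams train_model
#' @param folds number of CV folds (default 10).
#' @param tie tie threshold on CV R-squared (default 0.01).
#' @param grid hyperparameter grid used while scoring subsets; defaults to a
#'   single mid-grid configuration for speed.
#' @return list with \code{features} (selected subset), \code{profile}
#'   (data.frame: size, cv_r2, features) and \code{ranking}.
#' @export
rfe_select <- function(data, target, features = NULL,
                       method = c("rf", "gbm", "mlr"), folds = 10L,
                       seed = 1L, transform = "auto", tie = 0.01,
                       grid = NULL) {
  method <- match.arg(method)
  if (is.null(features)) features <- intersect(som_covariates(), names(data))
  if (transform == "auto") transform <- .default_transform(target)
  y <- .apply_transform(data[[target]], transform)
  if (stats::var(y) == 0) stop("degenerate target: constant response")
  if (is.null(grid)) {
    grid <- switch(method,
      rf = data.frame(ntree = 100L, mtry = 2L),
      gbm = data.frame(n_trees = 100L, interaction_depth = 3L,
                       shrinkage = 0.1, n_minobsinnode = 10L),
      mlr = data.frame(dummy = 0))
  }
  full <- train_model(data, target, features, method, transform,
                      grid = grid, cv = list(folds = folds, repeats = 1L),
                      seed = seed)
  ranking <- names(sort(variable_importance(full), decreasing = TRUE))

  fold_idx <- .make_folds(nrow(data), folds, 1L, seed)
  x_all <- data[features]
  prof <- lapply(seq_along(ranking), function(s) {
    sub <- ranking[seq_len(s)]
    pars <- as.list(grid[1, , drop = FALSE])
    if (method == "rf") pars$mtry <- min(pars$mtry, max(1L, s - 1L), s)
    r2 <- mean(vapply(fold_idx, function(hold) {
      lrn <- .fit_learner(x_all[-hold, sub, drop = FALSE], y[-hold], method,
                          pars, seed)
      evaluate(y[hold], lrn$predict(x_all[hold, sub, drop = FALSE]),
               metrics = "r2")$r2
    }, numeric(1)))
    data.frame(size = s, cv_r2 = r2,
               features = paste(sub, collapse = "+"))
  })
  profile <- do.call(rbind, prof)
  best_r2 <- max(profile$cv_r2)
  size <- min(profile$size[profile$cv_r2 >= best_r2 - tie])
  list(features = ranking[seq_len(size)], profile = profile,
       ranking = ranking)
}

#' Repeat training over fresh partitions and keep the best run
#'
#' Runs \code{n_repeats} independent train/test cycles (a fresh stratified
#' 75/25 partition per run), trains on the training side, scores both sides,
#' and returns the run with the highest test R-squared (modeling scale).
#'
#' @inheritParams train_model
#' @param n_repeats number of repeats (the reference protocol uses 100).
#' @param train_fraction training fraction per run (default 0.75).
#' @return list with \code{model} (best run's model, carrying
#'   \code{metrics_test}), \code{runs} (per-run data.frame: run, seed,
#'   r2_train, r2_test) and \code{best_run}.
#' @export
repeat_and_select <- function(data, target, features = NULL,
                              method = c("rf", "gbm", "mlr"),
                              n_repeats = 1L, seed = 1L,
                              train_fraction = 0.75, transform = "auto",
                              grid = NULL,
                              cv = list(folds = 10L, repeats = 3L)) {
  method <- match.arg(method)
  stopifnot(n_repeats >= 1)
  best <- NULL
  runs <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    s <- seed + r - 1L
    part <- partition(data, target, train_fraction, seed = s)
    m <- train_model(data[part$train, , drop = FALSE], target, features,
                     method, transform, grid = grid, cv = cv, seed = s)
    yt <- .apply_transform(data[[target]][part$test], m$transform)
    sim <- .predict_t(m, data[part$test, , drop = FALSE])
    mt <- evaluate(yt, sim, p = length(m$features),
                   metrics = c("r2", "ccc", "rmse", "aic"), warn_sse0 = FALSE)
    m$metrics_test <- mt
    m$partition <- part
    runs[[r]] <- data.frame(run = r, seed = s,
                            r2_train = m$metrics_train$r2, r2_test = mt$r2)
    if (is.null(best) || mt$r2 > best$metrics_test$r2) best <- m
  }
  runs <- do.call(rbind, runs)
  list(model = best, runs = runs,
       best_run = runs$run[which.max(runs$r2_test)])
}

#' Rank trained models by AIC on a common evaluation set
#'
#' Computes \eqn{AIC = n \ln(SSE/n) + 2p} for each model on the same rows
#' (p = number of selected features, residuals on the shared modeling
#' scale) and returns the models ranked ascending; the lowest-AIC model
#' wins.
#'
#' @param models list of \code{trained_model}s with a common target and
#'   transform.
#' @param data evaluation data.frame (features + target).
#' @return data.frame: model label, method, n_features, r2, aic, rank,
#'   winner flag; attribute \code{"order"} gives the ranking permutation.
#' @export
compare_by_aic <- function(models, data) {
  stopifnot(length(models) >= 2)
  tgt <- unique(vapply(models, `[[`, character(1), "target"))
  trf <- unique(vapply(models, `[[`, character(1), "transform"))
  if (length(tgt) != 1 || length(trf) != 1) {
    stop("models must share one target and transform for AIC comparison")
  }
  y <- .apply_transform(data[[tgt]], trf)
  rows <- lapply(seq_along(models), function(i) {
    m <- models[[i]]
    sim <- .predict_t(m, data)
    met <- evaluate(y, sim, p = length(m$features),
                    metrics = c("r2", "aic"), warn_sse0 = FALSE)
    lbl <- if (!is.null(names(models)) && nzchar(names(models)[i])) {
      names(models)[i]
    } else {
      m$method
    }
    data.frame(model = lbl, method = m$method,
               n_features = length(m$features), r2 = met$r2, aic = met$aic)
  })
  out <- do.call(rbind, rows)
  ord <- order(out$aic)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$winner <- out$rank == 1L
  rownames(out) <- NULL
  attr(out, "order") <- ord
  out
}

#' Relative importance of the model's features (percent)
#'
#' Permutation importance for random forests (out-of-bag %IncMSE), gain for
#' gradient boosting, absolute standardized coefficients for MLR; negative
#' contributions are floored at zero and the vector is normalized to sum to
#' 100.
#'
#' @param model a \code{trained_model}.
#' @return named numeric vector over the model's features, summing to 100.
#' @export
variable_importance <- function(model) {
  stopifnot(inherits(model, "trained_model"))
  fts <- model$features
  if (length(fts) == 1L) {
    return(stats::setNames(100, fts))
  }
  raw <- switch(model$method,
    rf = {
      im <- randomForest::importance(model$fit, type = 1)[, 1]
      if (sum(pmax(im, 0)) == 0) {
        im <- randomForest::importance(model$fit, type = 2)[, 1]
      }
      im[fts]
    },
    gbm = {
      tab <- xgboost::xgb.importance(model = model$fit)
      stats::setNames(tab$Gain[match(fts, tab$Feature)], fts)
    },
    mlr = {
      cf <- stats::coef(model$fit)[-1]
      nm <- gsub("`", "", names(cf))
      sds <- vapply(model$data[fts], stats::sd, numeric(1))
      abs(stats::setNames(cf[match(fts, nm)], fts)) * sds
    })
  raw[is.na(raw)] <- 0
  raw <- pmax(raw, 0)
  if (sum(raw) == 0) raw[] <- 1
  100 * raw / sum(raw)
}

#' Partial dependence of the prediction on one feature
#'
#' The standard clamp-and-average marginal response: the feature is set to
#' each of \code{grid_size} values spanning its observed range while all
#' other features keep their observed values, and predictions are averaged.
#' The feature axis is also reported normalized to 0-1.
#'
#' @param model a \code{trained_model}.
#' @param feature a feature in the model's subset.
#' @param grid_size number of evaluation points (default 20).
#' @param data data over which to marginalize (default the training data).
#' @param scale \code{"natural"} (transform inverted, default) or
#'   \code{"model"} (modeling scale, additive for additive responses).
#' @return data.frame: \code{x}, \code{x_norm} in \[0, 1\], \code{yhat}.
#' @export
partial_dependence <- function(model, feature, grid_size = 20L,
                               data = model$data,
                               scale = c("natural", "model")) {
  stopifnot(inherits(model, "trained_model"))
  scale <- match.arg(scale)
  if (!feature %in% model$features) {
    stop("feature '", feature, "' is not in the model's subset")
  }
  v <- data[[feature]]
  rng <- range(v)
  if (diff(rng) == 0) stop("feature '", feature, "' is constant")
  gx <- seq(rng[1], rng[2], length.out = grid_size)
  yhat <- vapply(gx, function(g) {
    nd <- data[model$features]
    nd[[feature]] <- g
    p <- .predict_t(model, nd)
    if (scale == "natural") p <- .invert_transform(p, model$transform)
    mean(p)
  }, numeric(1))
  data.frame(x = gx, x_norm = (gx - rng[1]) / diff(rng), yhat = yhat)
}
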