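#' Agreement and error metrics for simulated vs observed values
#'
#' Computes the evaluation metrics used throughout the package, directly from
#' their defining sums: the coefficient of determination
#' \eqn{R^2 = 1 - SSE / \sum (y_{obs} - \bar y_{obs})^2}; Lin-type concordance
#' correlation in its population form
#' \eqn{\rho_c = 2 \sum (y_{sim}-\bar y_{sim})(y_{obs}-\bar y_{obs}) /
#' [n(\bar y_{sim}-\bar y_{obs})^2 + \sum(y_{sim}-\bar y_{sim})^2 +
#' \sum(y_{obs}-\bar y_{obs})^2]} (note: raw sums, no n-1 correction);
#' \eqn{RMSE = \sqrt{SSE/n}}; RMSEn = RMSE divided by the interquartile range
#' of the observations; and \eqn{AIC = n \ln(SSE/n) + 2p}. Quartiles use
#' linear interpolation of order statistics (quantile type 7).
#'
#' @param y_obs numeric vector of observations.
#' @param y_sim numeric vector of simulated/predicted values, same length.
#' @param p number of explanatory variables (required for \code{"aic"}).
#' @param metrics character vector choosing which metrics to compute; any of
#'   \code{"r2"}, \code{"ccc"}, \code{"rmse"}, \code{"rmsen"}, \code{"aic"}.
#'   \code{"aic"} is included by default only when \code{p} is given.
#' @param warn_sse0 warn when SSE = 0 makes AIC degenerate (-Inf sentinel).
#' @return named list with the requested metrics.
#' @examples
#' evaluate(c(1, 2, 3, 4), c(2, 3, 4, 5))$ccc  # 10/14
#' @export
evaluate <- function(y_obs, y_sim, p = NULL,
                     metrics = c("r2", "ccc", "rmse", "rmsen",
                                 if (!is.null(p)) "aic"),
                     warn_sse0 = TRUE) {
  y_obs <- as.numeric(y_obs)
  y_sim <- as.numeric(y_sim)
  if (length(y_obs) != length(y_sim)) stop("`y_obs`/`y_sim` length mismatch")
  n <- length(y_obs)
  if (n < 2) stop("need at least 2 paired observations")
  if (any(!is.finite(y_obs)) || any(!is.finite(y_sim))) {
    stop("metrics require finite values")
  }
  metrics <- match.arg(metrics, c("r2", "ccc", "rmse", "rmsen", "aic"),
                       several.ok = TRUE)
  sse <- sum((y_sim - y_obs)^2)
  out <- list()
  if ("r2" %in% metrics) {
    sst <- sum((y_obs - mean(y_obs))^2)
    out$r2 <- if (sst == 0) {
      if (sse == 0) 1 else -Inf
    } else 1 - sse / sst
  }
  if ("ccc" %in% metrics) {
    mo <- mean(y_obs); ms <- mean(y_sim)
    num <- 2 * sum((y_sim - ms) * (y_obs - mo))
    den <- n * (ms - mo)^2 + sum((y_sim - ms)^2) + sum((y_obs - mo)^2)
    out$ccc <- if (den == 0) 1 else num / den
  }
  if (any(c("rmse", "rmsen") %in% metrics)) {
    rmse <- sqrt(sse / n)
    if ("rmse" %in% metrics) out$rmse <- rmse
    if ("rmsen" %in% metrics) {
      q <- stats::quantile(y_obs, c(0.25, 0.75), type = 7, names = FALSE)
      iqr <- q[2] - q[1]
      if (iqr <= 0) stop("RMSEn undefined: interquartile range of y_obs is 0")
      out$rmsen <- rmse / iqr
    }
  }
  if ("aic" %in% metrics) {
    if (is.null(p)) stop("AIC requires `p`, the number of explanatory variables")
    if (p < 1) stop("`p` must be >= 1")
    if (sse == 0) {
      if (warn_sse0) warning("SSE = 0: AIC reported as -Inf")
      out$aic <- -Inf
    } else {
      out$aic <- n * log(sse / n) + 2 * p
    }
  }
  out
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square p-value (df = number of
#' groups - 1), as used for comparing kinetics parameters between the two- and
#' three-pool model classes. Identical values across all groups return H = 0,
#' p = 1.
#'
#' @param groups a list of numeric vectors, one per group (>= 2 non-empty
#'   groups).
#' @return list with \code{H}, \code{p_value} and \code{df}.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) stop("need >= 2 groups")
  groups <- lapply(groups, function(g) as.numeric(g[is.finite(g)]))
  if (any(vapply(groups, length, integer(1)) == 0)) {
    stop("all groups must be non-empty")
  }
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  if (length(unique(x)) == 1L) {
    return(list(H = 0, p_value = 1, df = length(groups) - 1L))
  }
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), p_value = unname(kt$p.value),
       df = unname(kt$parameter))
}

#' Pairwise Spearman rank correlation matrix
#'
#' Rank correlations between all numeric columns of a table, with
#' pairwise-complete handling of missing values. Entries that are undefined
#' (a constant column within the complete pairs) are returned as \code{NA}
#' and listed in the \code{"undefined"} attribute rather than silently set
#' to 0.
#'
#' @param table a data.frame or matrix; non-numeric columns are dropped.
#' @return symmetric correlation matrix with unit diagonal and an
#'   \code{"undefined"} attribute naming undefined pairs (possibly empty).
#' @export
spearman_matrix <- function(table) {
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1))
  df <- df[num]
  if (ncol(df) < 2) stop("need at least two numeric columns")
  m <- suppressWarnings(
    stats::cor(df, method = "spearman", use = "pairwise.complete.obs")
  )
  diag(m) <- 1
  und <- which(is.na(m) & upper.tri(m), arr.ind = TRUE)
  undefined <- if (nrow(und)) {
    paste(rownames(m)[und[, 1]], colnames(m)[und[, 2]], sep = ":")
  } else character(0)
  attr(m, "undefined") <- undefined
  m
}

#' Median and central confidence intervals of a sample
#'
#' Median plus symmetric central intervals: the 50\% interval spans the
#' 25th-75th percentiles and the 90\% interval the 5th-95th, with quantile
#' type 7 (linear interpolation of order statistics).
#'
#' @param values numeric vector with at least one finite value.
#' @param levels central interval levels, default \code{c(0.5, 0.9)}.
#' @return named list: \code{median}, \code{n}, and per level a length-2
#'   vector named \code{ci50}, \code{ci90}, ...
#' @export
quantile_summary <- function(values, levels = c(0.5, 0.9)) {
  values <- as.numeric(values[is.finite(values)])
  if (length(values) == 0) stop("no finite values")
  if (any(levels <= 0 | levels >= 1)) stop("levels must be in (0, 1)")
  out <- list(median = stats::median(values), n = length(values))
  for (L in levels) {
    ci <- stats::quantile(values, c((1 - L) / 2, 1 - (1 - L) / 2),
                          type = 7, names = FALSE)
    out[[paste0("ci", round(100 * L))]] <- ci
  }
  out
}
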