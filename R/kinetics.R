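#' Multi-pool first-order decomposition parameters
#'
#' Constructs the parameter set of a parallel multi-pool first-order
#' decomposition model: pool fractions \code{f}, reference decomposition
#' rates \code{k} (d^-1) and the initial substrate stock \code{S0}
#' (mg C g^-1 soil). Pools are stored in canonical fast-to-slow order
#' (strictly descending \code{k}); \code{f} is permuted alongside.
#'
#' @param f numeric vector of pool fractions; must lie in \[0, 1\] and sum
#'   to 1 (tolerance 1e-9).
#' @param k numeric vector of decomposition rates (d^-1), same length as
#'   \code{f}; non-negative (a zero rate encodes an inert pool).
#' @param S0 initial substrate stock, > 0. Defaults to 1 so that fractions
#'   and releases are expressed per unit initial SOM.
#' @return an object of class \code{pool_kinetics} with elements
#'   \code{n_pools}, \code{f}, \code{k}, \code{S0}.
#' @examples
#' p <- pool_kinetics(f = c(0.2, 0.8), k = c(0.05, 0.005))
#' remaining_substrate(p, c(0, 30, 365))
#' @export
pool_kinetics <- function(f, k, S0 = 1) {
  f <- as.numeric(f)
  k <- as.numeric(k)
  if (length(f) != length(k)) {
    stop("`f` and `k` must have the same length")
  }
  if (!length(f) %in% 1:3) {
    stop("supported models have 1, 2 or 3 pools")
  }
  if (any(!is.finite(f)) || any(!is.finite(k))) {
    stop("`f` and `k` must be finite")
  }
  if (any(f < -1e-12) || any(f > 1 + 1e-12)) {
    stop("pool fractions must lie in [0, 1]")
  }
  if (abs(sum(f) - 1) > 1e-9) {
    stop("pool fractions must sum to 1 (got ", format(sum(f)), ")")
  }
  if (any(k < 0)) {
    stop("decomposition rates must be non-negative")
  }
  if (!is.numeric(S0) || length(S0) != 1L || !is.finite(S0) || S0 <= 0) {
    stop("`S0` must be a single positive number")
  }
  ord <- order(k, decreasing = TRUE)
  structure(
    list(n_pools = length(f), f = pmin(pmax(f[ord], 0), 1), k = k[ord],
         S0 = as.numeric(S0)),
    class = "pool_kinetics"
  )
}

#' @export
print.pool_kinetics <- function(x, ...) {
  cat(sprintf("%d-pool first-order kinetics (S0 = %g mg C g^-1)\n",
              x$n_pools, x$S0))
  print(data.frame(pool = seq_len(x$n_pools), f = x$f, k_d = x$k))
  invisible(x)
}

.check_times <- function(t) {
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("time must be finite and non-negative (days since incubation start)")
  }
  t
}

#' Remaining substrate S(t)
#'
#' Evaluates \eqn{S(t) = S(0) \sum_i f_i e^{-k_i t}}, the substrate mass left
#' across all pools at time \code{t} days.
#'
#' @param params a \code{\link{pool_kinetics}} object.
#' @param t numeric vector of times (days, >= 0).
#' @return numeric vector of substrate mass (mg C g^-1 soil).
#' @export
remaining_substrate <- function(params, t) {
  stopifnot(inherits(params, "pool_kinetics"))
  t <- .check_times(t)
  vapply(t, function(ti) params$S0 * sum(params$f * exp(-params$k * ti)),
         numeric(1))
}

#' Cumulative carbon release R_cum(t)
#'
#' Evaluates \eqn{R_{cum}(t) = S(0) (1 - \sum_i f_i e^{-k_i t})}, the
#' cumulative CO2-C released by time \code{t}. Complements
#' \code{\link{remaining_substrate}} so that remaining + cumulative = S0.
#'
#' @inheritParams remaining_substrate
#' @return numeric vector of cumulative release (mg C g^-1 soil).
#' @export
cumulative_release <- function(params, t) {
  stopifnot(inherits(params, "pool_kinetics"))
  t <- .check_times(t)
  vapply(t, function(ti) params$S0 * (1 - sum(params$f * exp(-params$k * ti))),
         numeric(1))
}

#' Instantaneous mineralization rate R(t)
#'
#' Evaluates \eqn{R(t) = S(0) \sum_i k_i f_i e^{-k_i t}}, the derivative of
#' the cumulative release.
#'
#' @inheritParams remaining_substrate
#' @return numeric vector of flux (mg C g^-1 soil d^-1).
#' @export
flux_rate <- function(params, t) {
  stopifnot(inherits(params, "pool_kinetics"))
  t <- .check_times(t)
  vapply(t, function(ti) params$S0 * sum(params$k * params$f * exp(-params$k * ti)),
         numeric(1))
}

#' Incubation respiration time series
#'
#' Container for an observed (or simulated) laboratory incubation series:
#' cumulative CO2-C release over time, with an optional instantaneous flux
#' track and experiment metadata.
#'
#' @param times days since incubation start, strictly increasing, >= 0.
#' @param cumulative cumulative C release (mg C g^-1 soil), same length as
#'   \code{times}, non-negative.
#' @param flux optional instantaneous rate track (mg C g^-1 soil d^-1).
#' @param meta named list of metadata (e.g. \code{measured_var}, \code{inc_t},
#'   \code{moisture}, \code{duration}).
#' @return object of class \code{incubation_series}.
#' @export
incubation_series <- function(times, cumulative, flux = NULL, meta = list()) {
  times <- as.numeric(times)
  cumulative <- as.numeric(cumulative)
  if (length(times) != length(cumulative)) {
    stop("`times` and `cumulative` must have equal length")
  }
  if (any(!is.finite(times)) || any(times < 0)) {
    stop("`times` must be finite and non-negative")
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("`times` must be strictly increasing")
  }
  if (any(!is.finite(cumulative)) || any(cumulative < 0)) {
    stop("`cumulative` must be finite and non-negative")
  }
  if (!is.null(flux)) {
    flux <- as.numeric(flux)
    if (length(flux) != length(times)) stop("`flux` length must match `times`")
  }
  structure(list(times = times, cumulative = cumulative, flux = flux,
                 meta = meta),
            class = "incubation_series")
}

#' Read an incubation series from CSV
#'
#' Expects a header with columns \code{time_d} and \code{cum_co2_mgC_per_g},
#' and optionally \code{flux_mgC_per_g_d}.
#'
#' @param path CSV file path.
#' @return an \code{\link{incubation_series}}.
#' @export
read_incubation_series <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  req <- c("time_d", "cum_co2_mgC_per_g")
  if (!all(req %in% names(df))) {
    stop("series CSV must contain columns: ", paste(req, collapse = ", "))
  }
  flux <- if ("flux_mgC_per_g_d" %in% names(df)) df$flux_mgC_per_g_d else NULL
  incubation_series(df$time_d, df$cum_co2_mgC_per_g, flux = flux)
}

#' Write an incubation series to CSV
#'
#' @param series an \code{\link{incubation_series}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_incubation_series <- function(series, path) {
  stopifnot(inherits(series, "incubation_series"))
  df <- data.frame(time_d = series$times, cum_co2_mgC_per_g = series$cumulative)
  if (!is.null(series$flux)) df$flux_mgC_per_g_d <- series$flux
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# ---- constrained reparameterisation -----------------------------------------
# Rates: log k_1 = a_1, log k_i = log k_{i-1} - softplus(a_i)  (i > 1), which
# guarantees k_1 > k_2 > k_3 for any unconstrained a. Fractions: stick-breaking
# with logistic sticks, which keeps f on the simplex. The optimizer therefore
# runs fully unconstrained.

.softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
.inv_softplus <- function(y) {
  y <- pmax(y, 1e-8)
  ifelse(y > 30, y, log(expm1(y)))
}

.theta_to_params <- function(theta, n_pools, S0_fixed = NULL) {
  a <- theta[seq_len(n_pools)]
  logk <- cumsum(c(a[1], if (n_pools > 1) -.softplus(a[-1])))
  k <- exp(logk)
  if (n_pools == 1L) {
    f <- 1
  } else {
    b <- theta[n_pools + seq_len(n_pools - 1)]
    stick <- stats::plogis(b)
    f <- numeric(n_pools)
    rem <- 1
    for (i in seq_len(n_pools - 1)) {
      f[i] <- rem * stick[i]
      rem <- rem - f[i]
    }
    f[n_pools] <- rem
  }
  S0 <- if (is.null(S0_fixed)) exp(theta[length(theta)]) else S0_fixed
  list(f = f, k = k, S0 = S0)
}

.params_to_theta <- function(f, k, S0 = NULL) {
  n <- length(k)
  logk <- log(pmax(k, 1e-12))
  a <- c(logk[1], if (n > 1) .inv_softplus(-diff(logk)))
  theta <- a
  if (n > 1) {
    f <- pmin(pmax(f, 1e-6), 1 - 1e-6)
    b <- numeric(n - 1)
    rem <- 1
    for (i in seq_len(n - 1)) {
      b[i] <- stats::qlogis(min(max(f[i] / rem, 1e-6), 1 - 1e-6))
      rem <- rem - f[i]
      rem <- max(rem, 1e-9)
    }
    theta <- c(theta, b)
  }
  if (!is.null(S0)) theta <- c(theta, log(S0))
  theta
}

# Exponential peeling: a data-driven start. The remaining substrate is a sum
# of decaying exponentials, so the slowest component is log-linear in the
# tail; fit it there, subtract, and repeat toward the fastest pool.
.peel_start <- function(t, rem, n_pools) {
  amps <- ks <- rep(NA_real_, n_pools)
  r <- rem
  floor_r <- max(rem) * 1e-10 + 1e-300
  for (j in rev(seq_len(n_pools))) {
    pos <- which(r > floor_r)
    if (length(pos) < 3) return(NULL)
    n_use <- if (j == 1) length(pos) else max(3, ceiling(length(pos) * 0.35))
    idx <- utils::tail(pos, n_use)
    cf <- stats::coef(stats::lm(log(r[idx]) ~ t[idx]))
    k <- max(-cf[2], 1e-8)
    a <- exp(cf[1])
    ks[j] <- k
    amps[j] <- a
    r <- pmax(r - a * exp(-k * t), 0)
  }
  if (any(!is.finite(ks)) || any(!is.finite(amps)) || sum(amps) <= 0) {
    return(NULL)
  }
  ord <- order(ks, decreasing = TRUE)
  ks <- ks[ord]
  amps <- pmax(amps[ord], 1e-8)
  # enforce strictly descending rates for the transform
  for (j in seq_len(n_pools - 1)) {
    ks[j + 1] <- min(ks[j + 1], ks[j] / 1.01)
  }
  list(k = ks, f = amps / sum(amps))
}

# Deterministic multi-start grid: descending rate combinations drawn from a
# half-decade log grid on [1e-6, 1] d^-1, paired with fraction starts cycling
# through simplex corners and the centroid.
.make_starts <- function(n_pools, n_starts, seed) {
  grid <- 10^seq(0, -6, by = -0.5)
  if (n_pools == 1L) {
    ks <- matrix(grid, ncol = 1)
  } else {
    idx <- utils::combn(seq_along(grid), n_pools)
    ks <- t(apply(idx, 2, function(i) grid[i]))  # already descending
  }
  fr <- switch(as.character(n_pools),
    "1" = list(1),
    "2" = list(c(0.5, 0.5), c(0.8, 0.2), c(0.2, 0.8)),
    "3" = list(c(1, 1, 1) / 3, c(0.7, 0.2, 0.1), c(0.1, 0.2, 0.7),
               c(0.2, 0.6, 0.2))
  )
  set.seed(seed)
  ord <- sample(nrow(ks))
  take <- ord[round(seq(1, nrow(ks), length.out = min(n_starts, nrow(ks))))]
  take <- unique(take)
  lapply(seq_along(take), function(j) {
    list(k = ks[take[j], ], f = fr[[(j - 1) %% length(fr) + 1]])
  })
}

#' Fit a constrained multi-pool first-order model to an incubation series
#'
#' Nonlinear least squares on cumulative CO2-C release (default) or the
#' instantaneous flux. The model is reparameterised so that the
#' Levenberg-Marquardt iterations run unconstrained while the returned
#' parameters always satisfy the simplex constraint on fractions and a strict
#' descending ordering of rates. A deterministic multi-start protocol over a
#' log-spaced rate grid guards against local minima.
#'
#' @param series an \code{\link{incubation_series}}.
#' @param n_pools number of pools, 1, 2 or 3.
#' @param target fit the \code{"cumulative"} release curve (default) or the
#'   \code{"flux"} track.
#' @param S0 initial substrate stock. If supplied it is held fixed (the usual
#'   case when SOC-derived stocks are measured); if \code{NULL} it is fitted.
#' @param n_starts number of multi-start initialisations (default 24).
#' @param seed integer seed controlling the multi-start ordering.
#' @param max_iter maximum Levenberg-Marquardt iterations per start.
#' @param flag_threshold identifiability threshold: a flag is raised when
#'   duration * k_slowest falls below it (slowest pool barely expressed).
#' @return object of class \code{somkin_fit}: \code{params}
#'   (\code{pool_kinetics}), \code{rss}, \code{r2}, \code{rmse}, \code{aic},
#'   \code{bic}, \code{n_obs}, \code{converged}, \code{n_starts_used},
#'   \code{flags} (character vector), \code{fitted}, \code{target}.
#' @export
fit_first_order <- function(series, n_pools, target = c("cumulative", "flux"),
                            S0 = NULL, n_starts = 24, seed = 1L,
                            max_iter = 500, flag_threshold = 0.05) {
  stopifnot(inherits(series, "incubation_series"))
  target <- match.arg(target)
  if (!n_pools %in% 1:3) stop("`n_pools` must be 1, 2 or 3")
  y <- if (target == "flux") {
    if (is.null(series$flux)) stop("series has no flux track")
    series$flux
  } else {
    series$cumulative
  }
  t <- series$times
  n <- length(y)
  if (n < 2 * n_pools + 1) {
    stop("need at least ", 2 * n_pools + 1, " observations for ", n_pools,
         " pools (have ", n, ")")
  }

  flags <- character(0)
  if (target == "cumulative" &&
      (max(y) <= 0 || any(diff(y) < -1e-9 * max(abs(y), 1)))) {
    flags <- c(flags, "degenerate_input")
  }

  fit_S0 <- is.null(S0)
  # scale guess for a fitted S0: the asymptote is at or above the last point
  S0_guess <- if (fit_S0) max(max(y) * 1.5, 1e-6) else S0

  model_fun <- function(pk_list, tt) {
    p <- pool_kinetics(pk_list$f, pk_list$k, pk_list$S0)
    if (target == "flux") flux_rate(p, tt) else cumulative_release(p, tt)
  }
  resid_fun <- function(theta) {
    pl <- .theta_to_params(theta, n_pools, if (fit_S0) NULL else S0)
    pred <- if (target == "flux") {
      pl$S0 * vapply(t, function(ti) sum(pl$k * pl$f * exp(-pl$k * ti)),
                     numeric(1))
    } else {
      pl$S0 * vapply(t, function(ti) 1 - sum(pl$f * exp(-pl$k * ti)),
                     numeric(1))
    }
    pred - y
  }

  starts <- .make_starts(n_pools, n_starts, seed)
  if (target == "cumulative" && !"degenerate_input" %in% flags) {
    asym <- if (fit_S0) max(y) * 1.05 else S0
    peel <- .peel_start(t, pmax(asym - y, 0), n_pools)
    if (!is.null(peel)) starts <- c(list(peel), starts)
  }
  best <- NULL
  n_used <- 0L
  ctrl <- minpack.lm::nls.lm.control(maxiter = max_iter, ftol = 1e-13,
                                     ptol = 1e-13, maxfev = 10000)
  for (st in starts) {
    theta0 <- .params_to_theta(st$f, st$k, if (fit_S0) S0_guess else NULL)
    res <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = theta0, fn = resid_fun, control = ctrl)
      ),
      error = function(e) NULL
    )
    n_used <- n_used + 1L
    if (is.null(res)) next
    rss <- sum(res$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-15 * max(best$rss, 1)) {
      best <- list(theta = res$par, rss = rss, info = res$info)
    }
    # early exit on an essentially perfect fit
    if (!is.null(best) && best$rss < 1e-20 * max(sum(y^2), 1)) break
  }
  if (is.null(best)) {
    stop("fit_first_order: no start converged (", n_used, " starts tried, ",
         n_pools, " pools, n = ", n, ")")
  }
  # polish: restarting Levenberg-Marquardt from the incumbent resets the
  # damping and often escapes shallow plateaus
  for (rep in 1:2) {
    pol <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = best$theta, fn = resid_fun, control = ctrl)
      ),
      error = function(e) NULL
    )
    if (is.null(pol)) break
    rss_p <- sum(pol$fvec^2)
    if (rss_p >= best$rss) break
    best <- list(theta = pol$par, rss = rss_p, info = pol$info)
  }

  pl <- .theta_to_params(best$theta, n_pools, if (fit_S0) NULL else S0)
  params <- pool_kinetics(pl$f, pl$k, pl$S0)
  fitted <- model_fun(pl, t)
  p_free <- n_pools + (n_pools - 1) + as.integer(fit_S0)
  met <- evaluate(y, fitted, p = p_free,
                  metrics = c("r2", "rmse", "aic"), warn_sse0 = FALSE)
  bic <- if (best$rss > 0) n * log(best$rss / n) + p_free * log(n) else -Inf

  duration <- max(t)
  if (duration * min(params$k) < flag_threshold) {
    flags <- c(flags, "slow_pool_unidentifiable")
  }
  converged <- best$info %in% 1:4

  structure(
    list(params = params, rss = best$rss, r2 = met$r2, rmse = met$rmse,
         aic = met$aic, bic = bic, n_obs = n, converged = converged,
         n_starts_used = n_used, flags = flags, fitted = fitted,
         target = target, S0_fitted = fit_S0),
    class = "somkin_fit"
  )
}

#' @export
print.somkin_fit <- function(x, ...) {
  cat(sprintf("first-order fit (%d pools, target = %s): RSS = %.4g, R2 = %.4f\n",
              x$params$n_pools, x$target, x$rss, x$r2))
  print(x$params)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
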