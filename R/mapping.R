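#' Lat/lon gridded covariate layer
#'
#' A lightweight geographic grid: a value matrix whose rows run north to
#' south and columns west to east, with a lon/lat extent in WGS84 decimal
#' degrees. Cell values are referenced to cell centers; missing cells are
#' \code{NA}.
#'
#' @param values numeric matrix (rows = latitude bands, north first).
#' @param xmin,xmax,ymin,ymax extent in decimal degrees.
#' @param var optional variable tag.
#' @return object of class \code{grid_raster}.
#' @export
grid_raster <- function(values, xmin = -180, xmax = 180, ymin = -60,
                        ymax = 90, var = NULL) {
  values <- as.matrix(values)
  if (xmax <= xmin || ymax <= ymin) stop("invalid extent")
  structure(list(values = values, xmin = xmin, xmax = xmax, ymin = ymin,
                 ymax = ymax, var = var),
            class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  r <- grid_res(x)
  cat(sprintf("grid_raster%s: %d x %d cells, extent [%g, %g] x [%g, %g], res %g x %g deg\n",
              if (is.null(x$var)) "" else paste0(" <", x$var, ">"),
              nrow(x$values), ncol(x$values), x$xmin, x$xmax, x$ymin, x$ymax,
              r[1], r[2]))
  invisible(x)
}

#' Cell resolution of a grid (degrees)
#' @param r a \code{\link{grid_raster}}.
#' @return length-2 numeric: c(x_res, y_res).
#' @export
grid_res <- function(r) {
  c((r$xmax - r$xmin) / ncol(r$values), (r$ymax - r$ymin) / nrow(r$values))
}

#' Cell-center coordinates of a grid
#' @param r a \code{\link{grid_raster}}.
#' @return list with \code{lon} (west to east) and \code{lat} (north to
#'   south) center vectors.
#' @export
grid_centers <- function(r) {
  res <- grid_res(r)
  list(lon = r$xmin + (seq_len(ncol(r$values)) - 0.5) * res[1],
       lat = r$ymax - (seq_len(nrow(r$values)) - 0.5) * res[2])
}

.same_geometry <- function(a, b, tol = 1e-9) {
  all(dim(a$values) == dim(b$values)) &&
    abs(a$xmin - b$xmin) < tol && abs(a$xmax - b$xmax) < tol &&
    abs(a$ymin - b$ymin) < tol && abs(a$ymax - b$ymax) < tol
}

#' Sample a grid at point coordinates
#'
#' Nearest-cell-center lookup; points outside the extent return \code{NA}.
#'
#' @param r a \code{\link{grid_raster}}.
#' @param lon,lat coordinate vectors (decimal degrees).
#' @return numeric vector of cell values.
#' @export
sample_grid <- function(r, lon, lat) {
  stopifnot(inherits(r, "grid_raster"))
  res <- grid_res(r)
  col <- floor((lon - r$xmin) / res[1]) + 1
  row <- floor((r$ymax - lat) / res[2]) + 1
  # points exactly on the max edge belong to the last cell
  col[lon == r$xmax] <- ncol(r$values)
  row[lat == r$ymin] <- nrow(r$values)
  ok <- !is.na(lon) & !is.na(lat) & col >= 1 & col <= ncol(r$values) &
    row >= 1 & row <= nrow(r$values)
  out <- rep(NA_real_, length(lon))
  out[ok] <- r$values[cbind(row[ok], col[ok])]
  out
}

#' Resample a grid to a new resolution
#'
#' Bilinear interpolation (default) or nearest-neighbour on cell centers over
#' the same extent. Under bilinear interpolation any contributing missing
#' cell makes the output cell missing; at the grid margin, where a target
#' center falls outside the hull of source centers, the source coordinate is
#' clamped to the border row/column.
#'
#' @param r a \code{\link{grid_raster}}.
#' @param res target resolution in degrees (single value applied to both
#'   axes).
#' @param method \code{"bilinear"} or \code{"nearest"}.
#' @return resampled \code{grid_raster}.
#' @export
resample_grid <- function(r, res, method = c("bilinear", "nearest")) {
  stopifnot(inherits(r, "grid_raster"), res > 0)
  method <- match.arg(method)
  src_res <- grid_res(r)
  if (res < min(src_res) / 100) {
    warning("resampling refines the grid by more than 100x")
  }
  ncol_new <- max(1L, round((r$xmax - r$xmin) / res))
  nrow_new <- max(1L, round((r$ymax - r$ymin) / res))
  out <- grid_raster(matrix(NA_real_, nrow_new, ncol_new), r$xmin, r$xmax,
                     r$ymin, r$ymax, var = r$var)
  tgt <- grid_centers(out)
  src <- grid_centers(r)
  if (method == "nearest") {
    out$values <- outer(tgt$lat, tgt$lon, function(la, lo) {
      sample_grid(r, lo, la)
    })
    return(out)
  }
  nr <- nrow(r$values); nc <- ncol(r$values)
  v <- matrix(NA_real_, nrow_new, ncol_new)
  # fractional source indices of the target centers (clamped to the hull)
  fi <- (r$ymax - tgt$lat) / src_res[2] - 0.5
  fj <- (tgt$lon - r$xmin) / src_res[1] - 0.5
  fi <- pmin(pmax(fi, 0), nr - 1)
  fj <- pmin(pmax(fj, 0), nc - 1)
  i0 <- pmin(floor(fi) + 1, nr); i1 <- pmin(i0 + 1, nr)
  j0 <- pmin(floor(fj) + 1, nc); j1 <- pmin(j0 + 1, nc)
  wi <- fi - (i0 - 1)
  wj <- fj - (j0 - 1)
  for (a in seq_len(nrow_new)) {
    q00 <- r$values[i0[a], j0]; q01 <- r$values[i0[a], j1]
    q10 <- r$values[i1[a], j0]; q11 <- r$values[i1[a], j1]
    v[a, ] <- (1 - wi[a]) * ((1 - wj) * q00 + wj * q01) +
      wi[a] * ((1 - wj) * q10 + wj * q11)
  }
  out$values <- v
  out
}

#' Crop a grid to an extent
#'
#' Keeps cells whose centers fall inside the extent. The default extent is
#' the analysis window of 60 degrees south to 90 degrees north.
#'
#' @param r a \code{\link{grid_raster}}.
#' @param xmin,xmax,ymin,ymax crop extent (degrees).
#' @return cropped \code{grid_raster} (cell values untouched).
#' @export
crop_grid <- function(r, xmin = r$xmin, xmax = r$xmax, ymin = -60, ymax = 90) {
  stopifnot(inherits(r, "grid_raster"))
  ctr <- grid_centers(r)
  keep_c <- which(ctr$lon >= xmin & ctr$lon <= xmax)
  keep_r <- which(ctr$lat >= ymin & ctr$lat <= ymax)
  if (!length(keep_c) || !length(keep_r)) {
    stop("crop extent does not intersect the grid")
  }
  res <- grid_res(r)
  grid_raster(r$values[keep_r, keep_c, drop = FALSE],
              xmin = r$xmin + (min(keep_c) - 1) * res[1],
              xmax = r$xmin + max(keep_c) * res[1],
              ymin = r$ymax - max(keep_r) * res[2],
              ymax = r$ymax - (min(keep_r) - 1) * res[2],
              var = r$var)
}

#' Write / read the plain-text grid exchange format
#'
#' A small self-describing text format for gridded layers: a header with the
#' extent, dimensions and variable tag, followed by the value matrix row by
#' row (north first), missing cells as \code{NA}.
#'
#' @param r a \code{\link{grid_raster}}.
#' @param path file path.
#' @return \code{path} (write) or a \code{grid_raster} (read).
#' @export
write_grid_txt <- function(r, path) {
  stopifnot(inherits(r, "grid_raster"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("somkin_grid 1",
               sprintf("extent %.10g %.10g %.10g %.10g", r$xmin, r$xmax,
                       r$ymin, r$ymax),
               sprintf("dim %d %d", nrow(r$values), ncol(r$values)),
               sprintf("var %s", if (is.null(r$var)) "-" else r$var)), con)
  utils::write.table(r$values, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_grid_txt
#' @export
read_grid_txt <- function(path) {
  hdr <- readLines(path, n = 4)
  if (!startsWith(hdr[1], "somkin_grid")) stop("not a somkin grid file")
  ext <- as.numeric(strsplit(hdr[2], " ")[[1]][-1])
  dm <- as.integer(strsplit(hdr[3], " ")[[1]][-1])
  var <- strsplit(hdr[4], " ")[[1]][2]
  vals <- as.matrix(utils::read.table(path, skip = 4))
  dimnames(vals) <- NULL
  stopifnot(nrow(vals) == dm[1], ncol(vals) == dm[2])
  grid_raster(vals, ext[1], ext[2], ext[3], ext[4],
              var = if (var == "-") NULL else var)
}

.stack_rasters <- function(rasters, features) {
  miss <- setdiff(features, names(rasters))
  if (length(miss)) {
    stop("missing feature raster(s): ", paste(miss, collapse = ", "))
  }
  ref <- rasters[[features[1]]]
  for (f in features[-1]) {
    if (!.same_geometry(ref, rasters[[f]])) {
      stop("raster '", f, "' is not co-registered with '", features[1], "'")
    }
  }
  X <- sapply(features, function(f) as.vector(rasters[[f]]$values))
  X <- matrix(X, ncol = length(features),
              dimnames = list(NULL, features))
  list(ref = ref, X = X, ok = stats::complete.cases(X))
}

.vec_to_grid <- function(v, ref, var = NULL) {
  m <- matrix(v, nrow(ref$values), ncol(ref$values))
  grid_raster(m, ref$xmin, ref$xmax, ref$ymin, ref$ymax, var = var)
}

#' Predict a kinetics parameter over covariate grids
#'
#' Applies a trained model cellwise to co-registered covariate layers (one
#' per selected feature). Predictions are returned on the natural parameter
#' scale (any log10 target transform inverted); a missing value in any input
#' layer propagates to the output.
#'
#' @param model a \code{\link{train_model}} result.
#' @param rasters named list of \code{\link{grid_raster}} layers covering the
#'   model's selected features.
#' @return object of class \code{parameter_grid}: \code{mean}
#'   (\code{grid_raster}), \code{parameter}, \code{method}, \code{seed}.
#' @export
predict_grid <- function(model, rasters) {
  stopifnot(inherits(model, "trained_model"))
  st <- .stack_rasters(rasters, model$features)
  pred <- rep(NA_real_, nrow(st$X))
  if (any(st$ok)) {
    nd <- as.data.frame(st$X[st$ok, , drop = FALSE])
    pred[st$ok] <- predict(model, nd)
  }
  structure(list(mean = .vec_to_grid(pred, st$ref, model$target),
                 lower = NULL, upper = NULL, reun = NULL,
                 parameter = model$target, method = model$method,
                 seed = model$seed),
            class = "parameter_grid")
}

#' @export
print.parameter_grid <- function(x, ...) {
  cat(sprintf("parameter_grid <%s> (%s model)\n", x$parameter, x$method))
  print(x$mean)
  if (!is.null(x$reun)) {
    cat(sprintf("ReUn: mean %.3g over %d defined cells\n",
                mean(x$reun$values, na.rm = TRUE),
                sum(is.finite(x$reun$values))))
  }
  invisible(x)
}

.reun_from_bounds <- function(lo, hi, mn) {
  reun <- abs(hi - lo) / mn
  reun[!is.finite(mn) | mn <= 0] <- NA_real_
  reun
}

#' Input-driven relative uncertainty from pH percentile layers
#'
#' Propagates the 5th/95th-percentile pH layers through the model: the 90%
#' interval width at each cell is the absolute difference between the
#' predictions under the two percentile layers, and the relative uncertainty
#' is ReUn = width / mean prediction. Cells with a non-positive mean
#' prediction are masked (counted in \code{n_masked}).
#'
#' @param model a trained model whose feature set includes \code{"ph"} (a
#'   model without pH yields ReUn = 0 everywhere).
#' @param rasters co-registered covariate layers (mean pH among them).
#' @param ph5,ph95 \code{\link{grid_raster}} percentile layers.
#' @return \code{parameter_grid} with \code{lower}, \code{upper}, \code{reun}
#'   and \code{n_masked}.
#' @export
input_uncertainty_ph <- function(model, rasters, ph5, ph95) {
  base <- predict_grid(model, rasters)
  if (!"ph" %in% model$features) {
    z <- base$mean; z$values[] <- ifelse(is.na(base$mean$values), NA, 0)
    base$lower <- base$upper <- base$mean
    base$reun <- z
    base$n_masked <- 0L
    return(base)
  }
  if (!.same_geometry(rasters[["ph"]], ph5) ||
      !.same_geometry(rasters[["ph"]], ph95)) {
    stop("pH percentile layers are not co-registered")
  }
  r5 <- rasters; r5[["ph"]] <- ph5
  r95 <- rasters; r95[["ph"]] <- ph95
  p5 <- predict_grid(model, r5)$mean$values
  p95 <- predict_grid(model, r95)$mean$values
  mn <- base$mean$values
  base$lower <- .vec_to_grid(pmin(p5, p95), base$mean, model$target)
  base$upper <- .vec_to_grid(pmax(p5, p95), base$mean, model$target)
  reun <- .reun_from_bounds(p5, p95, mn)
  base$n_masked <- sum(is.na(reun) & !is.na(p5) & !is.na(p95))
  base$reun <- .vec_to_grid(reun, base$mean, "ReUn")
  base
}

#' Model-structure relative uncertainty from the random-forest ensemble
#'
#' Uses the per-tree predictions of a random forest at each cell: the 90%
#' interval is the empirical 5th-95th quantile range over trees (on the
#' natural parameter scale) and the mean is the tree-ensemble average;
#' ReUn = width / mean.
#'
#' @param model a trained \code{"rf"} model.
#' @param rasters co-registered covariate layers.
#' @return \code{parameter_grid} with per-cell ensemble mean, \code{lower},
#'   \code{upper}, \code{reun} and \code{n_masked}.
#' @export
structure_uncertainty <- function(model, rasters) {
  stopifnot(inherits(model, "trained_model"))
  if (model$method != "rf") stop("structure uncertainty requires an RF model")
  st <- .stack_rasters(rasters, model$features)
  n_cell <- nrow(st$X)
  mn <- lo <- hi <- rep(NA_real_, n_cell)
  if (any(st$ok)) {
    nd <- as.data.frame(st$X[st$ok, , drop = FALSE])
    trees <- predict_trees(model, nd)  # cells x trees, natural scale
    if (ncol(trees) < 10) warning("fewer than 10 trees: quantiles unstable")
    mn[st$ok] <- rowMeans(trees)
    q <- t(apply(trees, 1, stats::quantile, probs = c(0.05, 0.95), type = 7,
                 names = FALSE))
    lo[st$ok] <- q[, 1]
    hi[st$ok] <- q[, 2]
  }
  reun <- .reun_from_bounds(lo, hi, mn)
  structure(list(mean = .vec_to_grid(mn, st$ref, model$target),
                 lower = .vec_to_grid(lo, st$ref, model$target),
                 upper = .vec_to_grid(hi, st$ref, model$target),
                 reun = .vec_to_grid(reun, st$ref, "ReUn"),
                 n_masked = sum(is.na(reun) & !is.na(mn)),
                 parameter = model$target, method = model$method,
                 seed = model$seed),
            class = "parameter_grid")
}

#' Latitudinal profile of a gridded field
#'
#' Aggregates a grid (or the mean layer of a \code{parameter_grid}) into
#' latitude bands: per band the mean and the empirical 5-95% quantile range
#' over all defined cells, optionally area-weighted by cos(latitude).
#'
#' @param grid a \code{grid_raster} or \code{parameter_grid}.
#' @param band band width in degrees (default 0.5).
#' @param area_weighted weight cells by cos(latitude) in the band mean.
#' @return data.frame: \code{lat_lo}, \code{lat_hi}, \code{lat_center},
#'   \code{n}, \code{mean}, \code{lo90}, \code{hi90}; empty bands have
#'   \code{n = 0} and \code{NA} statistics.
#' @export
latitudinal_profile <- function(grid, band = 0.5, area_weighted = FALSE) {
  if (inherits(grid, "parameter_grid")) grid <- grid$mean
  stopifnot(inherits(grid, "grid_raster"), band > 0)
  if (all(is.na(grid$values))) stop("grid has no defined cells")
  ctr <- grid_centers(grid)
  n_bands <- ceiling((grid$ymax - grid$ymin) / band - 1e-12)
  out <- lapply(seq_len(n_bands), function(b) {
    hi <- grid$ymax - (b - 1) * band
    lo <- max(hi - band, grid$ymin)
    rows <- which(ctr$lat <= hi & ctr$lat > lo |
                    (lo == grid$ymin & ctr$lat == lo))
    v <- as.vector(grid$values[rows, , drop = FALSE])
    w <- rep(cos(ctr$lat[rows] * pi / 180), times = ncol(grid$values))
    keep <- is.finite(v)
    v <- v[keep]; w <- w[keep]
    if (!length(v)) {
      return(data.frame(lat_lo = lo, lat_hi = hi, lat_center = (lo + hi) / 2,
                        n = 0L, mean = NA_real_, lo90 = NA_real_,
                        hi90 = NA_real_))
    }
    m <- if (area_weighted) sum(w * v) / sum(w) else mean(v)
    q <- stats::quantile(v, c(0.05, 0.95), type = 7, names = FALSE)
    data.frame(lat_lo = lo, lat_hi = hi, lat_center = (lo + hi) / 2,
               n = length(v), mean = m, lo90 = q[1], hi90 = q[2])
  })
  do.call(rbind, out)
}
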