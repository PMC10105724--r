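#' Column names of the compiled kinetics table
#'
#' The fixed schema of one compiled incubation record: identification, site
#' coordinates, edaphic-climatic covariates, incubation conditions, the fitted
#' model class (M1/M2/M3) with its pool fractions and rates (d^-1), and fit
#' diagnostics. Missing values are empty cells (never 0 or -999).
#'
#' @return character vector of column names, required columns first.
#' @export
kinetics_schema <- function() {
  c("record_id", "source_id", "latitude", "longitude", "elev", "map", "mat",
    "ecosystem", "sand", "silt", "clay", "ph", "moisture", "inc_t",
    "duration", "measured_var", "model_type", "f1", "f2", "f3",
    "k1", "k2", "k3", "r2", "rmse", "aic", "bic", "mbc", "soc", "ndvi",
    "slope")
}

#' The eleven edaphic-climatic explanatory variables
#'
#' @return character vector: MAP, MAT, Sand, Clay, pH, SOC, MBC, Elev, Slope,
#'   NDVI and incubation temperature, as table column names.
#' @export
som_covariates <- function() {
  c("map", "mat", "sand", "clay", "ph", "soc", "mbc", "elev", "slope",
    "ndvi", "inc_t")
}

.mandatory_cols <- function() {
  c("record_id", "latitude", "longitude", "model_type", "f1", "k1")
}

#' Validate an in-memory compiled kinetics table
#'
#' Applies the row-level validity rules: coordinates in range, fractions on
#' the simplex (with the derivable fraction recomputed when absent: f2 = 1-f1
#' for M2, f3 = 1-f1-f2 for M3), rates positive and ordered k1 > k2 > k3
#' where present, and texture fractions summing to 100 within a tolerance of
#' 2 (source rounding). Invalid rows are collected in a reject report, not
#' silently dropped.
#'
#' @param df data.frame with (at least) the mandatory schema columns.
#' @return a \code{kinetics_table}: the valid rows, with attribute
#'   \code{"rejects"} (data.frame of \code{row}, \code{record_id},
#'   \code{reason}).
#' @export
validate_kinetics_table <- function(df) {
  miss <- setdiff(.mandatory_cols(), names(df))
  if (length(miss)) {
    stop("missing mandatory columns: ", paste(miss, collapse = ", "))
  }
  for (col in setdiff(kinetics_schema(), names(df))) df[[col]] <- NA
  df <- df[kinetics_schema()]

  # derivable fractions
  m2 <- !is.na(df$model_type) & df$model_type == "M2"
  df$f2[m2 & is.na(df$f2)] <- 1 - df$f1[m2 & is.na(df$f2)]
  m3 <- !is.na(df$model_type) & df$model_type == "M3"
  fill3 <- m3 & is.na(df$f3) & !is.na(df$f2)
  df$f3[fill3] <- 1 - df$f1[fill3] - df$f2[fill3]

  reasons <- vector("list", nrow(df))
  add <- function(i, r) reasons[[i]] <<- c(reasons[[i]], r)
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (!is.na(r$latitude) && (r$latitude < -90 || r$latitude > 90)) {
      add(i, "latitude out of [-90, 90]")
    }
    if (!is.na(r$longitude) && (r$longitude < -180 || r$longitude > 180)) {
      add(i, "longitude out of [-180, 180]")
    }
    if (is.na(r$model_type) || !r$model_type %in% c("M1", "M2", "M3")) {
      add(i, "model_type not in {M1, M2, M3}")
      next
    }
    np <- as.integer(substr(r$model_type, 2, 2))
    f <- c(r$f1, r$f2, r$f3)[seq_len(np)]
    k <- c(r$k1, r$k2, r$k3)[seq_len(np)]
    if (any(is.na(f))) {
      add(i, "missing pool fraction")
    } else {
      if (any(f < -1e-6 | f > 1 + 1e-6)) add(i, "fraction outside [0, 1]")
      if (abs(sum(f) - 1) > 1e-6) add(i, "fractions do not sum to 1")
    }
    if (any(is.na(k))) {
      add(i, "missing decomposition rate")
    } else {
      if (any(k <= 0)) add(i, "non-positive decomposition rate")
      if (np > 1 && any(diff(k) >= 0)) add(i, "rates not strictly descending")
    }
    tex <- c(r$sand, r$silt, r$clay)
    if (all(!is.na(tex)) && abs(sum(tex) - 100) > 2) {
      add(i, "sand + silt + clay not ~100")
    }
  }
  bad <- which(vapply(reasons, length, integer(1)) > 0)
  rejects <- if (length(bad)) {
    data.frame(row = bad, record_id = df$record_id[bad],
               reason = vapply(reasons[bad], paste, character(1),
                               collapse = "; "))
  } else {
    data.frame(row = integer(0), record_id = character(0),
               reason = character(0))
  }
  out <- if (length(bad)) df[-bad, , drop = FALSE] else df
  rownames(out) <- NULL
  attr(out, "rejects") <- rejects
  class(out) <- c("kinetics_table", "data.frame")
  out
}

#' Read a compiled kinetics table from CSV
#'
#' Reads, optionally renames columns via a mapping, harmonizes rate units to
#' d^-1, and validates. Rates reported per year are divided by 365. The unit
#' is taken from a \code{rate_unit} column (values \code{"d-1"} or
#' \code{"yr-1"}) when present, otherwise from the \code{rate_unit} argument.
#'
#' @param path CSV path (header required; empty cells are missing values).
#' @param col_map optional named character vector mapping source column names
#'   to schema names, e.g. \code{c(Lat = "latitude")}.
#' @param rate_unit default unit of k columns when no \code{rate_unit} column
#'   exists: \code{"d-1"} (default) or \code{"yr-1"}.
#' @return a validated \code{kinetics_table} (see
#'   \code{\link{validate_kinetics_table}}); rejected rows are in
#'   \code{attr(x, "rejects")}.
#' @export
read_kinetics_table <- function(path, col_map = NULL, rate_unit = "d-1") {
  df <- utils::read.csv(path, na.strings = c("", "NA"), check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    hit <- names(df) %in% names(col_map)
    names(df)[hit] <- unname(col_map[names(df)[hit]])
  }
  units <- if ("rate_unit" %in% names(df)) df$rate_unit else
    rep(rate_unit, nrow(df))
  units[is.na(units)] <- rate_unit
  known <- units %in% c("d-1", "yr-1")
  if (!all(known)) {
    stop("unknown rate units: ", paste(unique(units[!known]), collapse = ", "))
  }
  fac <- ifelse(units == "yr-1", 1 / 365, 1)
  for (col in c("k1", "k2", "k3")) {
    if (col %in% names(df)) df[[col]] <- df[[col]] * fac
  }
  df$rate_unit <- NULL
  validate_kinetics_table(df)
}

#' Write a compiled kinetics table to CSV
#'
#' Rates are written in d^-1; missing values as empty cells. Round-trips with
#' \code{\link{read_kinetics_table}}.
#'
#' @param table a \code{kinetics_table} or compatible data.frame.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_kinetics_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Reference decomposition rates of four classical SOM models
#'
#' Fixed pool-wise reference rate constants (d^-1) of the ANIMO and DAISY
#' two-pool models and the CLMcn and DAYCENT three-pool models, used as a
#' reality check against the compiled-data distributions.
#'
#' @return data.frame with columns \code{model}, \code{model_type} (matching
#'   pool class M2/M3), \code{pool} (1 = fast) and \code{k_ref} (d^-1).
#' @export
reference_models <- function() {
  data.frame(
    model = c("ANIMO", "ANIMO", "DAISY", "DAISY",
              "CLMcn", "CLMcn", "CLMcn", "DAYCENT", "DAYCENT", "DAYCENT"),
    model_type = c("M2", "M2", "M2", "M2", "M3", "M3", "M3", "M3", "M3", "M3"),
    pool = c(1L, 2L, 1L, 2L, 1L, 2L, 3L, 1L, 2L, 3L),
    k_ref = c(5.5e-3, 6.0e-4, 5.0e-2, 5.0e-3,
              7.1e-2, 1.4e-3, 1.0e-4, 3.0e-2, 1.1e-3, 9.0e-6)
  )
}

#' Fill missing covariates from gridded layers
#'
#' Samples each covariate raster at the site coordinate (nearest cell
#' center) for records whose covariate cell is empty. Filled entries are
#' flagged in companion \code{<var>_filled} logical columns; present values
#' are never overwritten; sites outside a raster's extent stay missing (and
#' unflagged).
#'
#' @param records a \code{kinetics_table} (or data.frame with coordinates).
#' @param rasters named list of \code{\link{grid_raster}} layers; names must
#'   be covariate column names (see \code{\link{som_covariates}}).
#' @return the records with gaps filled and provenance flag columns added.
#' @export
fill_missing_covariates <- function(records, rasters) {
  stopifnot(is.list(rasters), !is.null(names(rasters)))
  for (var in names(rasters)) {
    if (!var %in% names(records)) records[[var]] <- NA_real_
    flag <- paste0(var, "_filled")
    records[[flag]] <- FALSE
    gap <- is.na(records[[var]]) & !is.na(records$latitude) &
      !is.na(records$longitude)
    if (!any(gap)) next
    vals <- sample_grid(rasters[[var]], records$longitude[gap],
                        records$latitude[gap])
    got <- !is.na(vals)
    records[[var]][which(gap)[got]] <- vals[got]
    records[[flag]][which(gap)[got]] <- TRUE
  }
  records
}

#' Summarize kinetics parameters by model class and compare pools
#'
#' Per model class (M2/M3) and parameter, the median with 50% and 90%
#' central intervals; Kruskal-Wallis tests of each shared parameter between
#' the M2 and M3 classes; and a check of the classical reference-model rate
#' constants against the corresponding 50% interval of the compiled data.
#'
#' @param records a \code{kinetics_table}.
#' @return list with \code{summary} (data.frame: model_type, parameter, n,
#'   median, ci50_lo/hi, ci90_lo/hi), \code{kw} (parameter, H, p_value) and
#'   \code{reference} (reference constants with \code{within_ci50} flags).
#' @export
pool_comparison <- function(records) {
  pars <- c("k1", "k2", "k3", "f1", "f2", "f3")
  classes <- intersect(c("M1", "M2", "M3"), unique(records$model_type))
  rows <- list()
  for (mt in classes) {
    sub <- records[records$model_type == mt, , drop = FALSE]
    for (p in pars) {
      v <- sub[[p]]
      v <- v[is.finite(v)]
      if (length(v) < 2) next
      q <- quantile_summary(v)
      rows[[length(rows) + 1L]] <- data.frame(
        model_type = mt, parameter = p, n = q$n, median = q$median,
        ci50_lo = q$ci50[1], ci50_hi = q$ci50[2],
        ci90_lo = q$ci90[1], ci90_hi = q$ci90[2]
      )
    }
  }
  summary <- do.call(rbind, rows)

  kw <- data.frame(parameter = character(0), H = numeric(0),
                   p_value = numeric(0))
  if (all(c("M2", "M3") %in% classes)) {
    for (p in c("k1", "k2", "f1")) {
      g2 <- records[[p]][records$model_type == "M2"]
      g3 <- records[[p]][records$model_type == "M3"]
      g2 <- g2[is.finite(g2)]; g3 <- g3[is.finite(g3)]
      if (length(g2) < 2 || length(g3) < 2) next
      res <- kruskal_wallis(list(M2 = g2, M3 = g3))
      kw <- rbind(kw, data.frame(parameter = p, H = res$H,
                                 p_value = res$p_value))
    }
  } else {
    message("pool_comparison: both M2 and M3 required for KW comparison; ",
            "skipped")
  }

  ref <- reference_models()
  ref$within_ci50 <- NA
  if (!is.null(summary)) {
    for (i in seq_len(nrow(ref))) {
      par <- paste0("k", ref$pool[i])
      hit <- summary$model_type == ref$model_type[i] & summary$parameter == par
      if (any(hit)) {
        ref$within_ci50[i] <- ref$k_ref[i] >= summary$ci50_lo[hit][1] &
          ref$k_ref[i] <= summary$ci50_hi[hit][1]
      }
    }
  }
  list(summary = summary, kw = kw, reference = ref)
}
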