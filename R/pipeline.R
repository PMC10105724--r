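#' Validate a pipeline run configuration
#'
#' A run configuration is a named list (or a YAML file) with the keys:
#' \describe{
#'   \item{out_dir}{output directory (created if absent); required.}
#'   \item{seed}{root integer seed; every stage derives its randomness from
#'     it (default 1).}
#'   \item{stages}{ordered subset of \code{"simulate"}, \code{"summarize"},
#'     \code{"train"}, \code{"map"}, \code{"profile"}.}
#'   \item{table}{path to an existing compiled-table CSV (alternative to the
#'     simulate stage).}
#'   \item{n_sites}{synthetic table size (default 800).}
#'   \item{targets}{kinetics parameters to model, as \code{"<class>_<par>"}
#'     strings, e.g. \code{"M3_k3"}.}
#'   \item{methods}{any of \code{"mlr"}, \code{"rf"}, \code{"gbm"}.}
#'   \item{repeats}{train/test repetitions per target and method (default 1).}
#'   \item{rfe}{logical: run recursive feature elimination first.}
#'   \item{cv}{list with \code{folds} and \code{repeats}.}
#'   \item{raster}{list with \code{nrow} and \code{ncol} of the synthetic
#'     covariate grids used by the map stage.}
#'   \item{band}{latitude band width (degrees) for profiles (default 0.5).}
#' }
#' Unknown keys are a hard error (no silent typos); stage dependencies are
#' checked before execution.
#'
#' @param config named list or path to a YAML file.
#' @return the validated, default-completed configuration list.
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  known <- c("out_dir", "seed", "stages", "table", "n_sites", "targets",
             "methods", "repeats", "rfe", "cv", "raster", "band")
  bad <- setdiff(names(config), known)
  if (length(bad)) {
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  }
  defaults <- list(seed = 1L, stages = c("simulate", "summarize", "train"),
                   n_sites = 800L, targets = "M3_k3", methods = "rf",
                   repeats = 1L, rfe = FALSE,
                   cv = list(folds = 10L, repeats = 3L),
                   raster = list(nrow = 30L, ncol = 60L), band = 0.5)
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  }
  if (is.null(config$out_dir)) stop("config requires `out_dir`")
  ok_stage <- c("simulate", "summarize", "train", "map", "profile")
  if (!all(config$stages %in% ok_stage)) {
    stop("unknown stage(s): ",
         paste(setdiff(config$stages, ok_stage), collapse = ", "))
  }
  if (!all(config$methods %in% c("mlr", "rf", "gbm"))) {
    stop("methods must be among mlr, rf, gbm")
  }
  if (!all(grepl("^M[23]_(k[123]|f[12])$", config$targets))) {
    stop("targets must look like M3_k3, M2_f1, ...")
  }
  need_table <- any(c("summarize", "train") %in% config$stages)
  if (need_table && !"simulate" %in% config$stages && is.null(config$table)) {
    stop("stages ", paste(intersect(config$stages, c("summarize", "train")),
                          collapse = "/"),
         " need either the simulate stage or a `table` path")
  }
  if ("map" %in% config$stages && !"train" %in% config$stages) {
    stop("stage 'map' requires stage 'train' (no trained model otherwise)")
  }
  if ("profile" %in% config$stages && !"map" %in% config$stages) {
    stop("stage 'profile' requires stage 'map'")
  }
  if (!is.null(config$table) && !file.exists(config$table)) {
    stop("config `table` path does not exist: ", config$table)
  }
  config
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the configured stages in order: simulate (or load) the compiled
#' kinetics table; summarize it (model-class comparison, Kruskal-Wallis
#' tests, reference-model check, covariate Spearman matrix); train
#' predictive models per target and method (optionally with feature
#' selection) and rank methods by AIC; apply the best random-forest model
#' over synthetic covariate rasters with pH-input and tree-structure
#' uncertainty; and compute latitudinal profiles. Every artifact is written
#' under \code{out_dir} and listed in the returned manifest together with
#' the seeds and metrics; rerunning with the same config and seed reproduces
#' the numbers.
#'
#' @param config a configuration list or YAML path
#'   (see \code{\link{validate_run_config}}).
#' @param quiet suppress stage messages.
#' @return the run manifest (list: config, seed, package version, outputs,
#'   metrics), invisibly also written to \code{out_dir/manifest.json}.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  cfg <- validate_run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list(
    package = as.character(utils::packageVersion("somkin")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "out_dir")],
    outputs = list(), metrics = list()
  )
  stage_wrap <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      manifest$failed_stage <<- name
      .write_manifest(manifest, cfg$out_dir)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    say("stage %-9s done in %.1fs", name, proc.time()[["elapsed"]] - t0)
    res
  }

  table <- NULL
  if ("simulate" %in% cfg$stages) {
    table <- stage_wrap("simulate", {
      tab <- gen_kinetics_table(cfg$n_sites, seed = cfg$seed)
      p <- file.path(cfg$out_dir, "kinetics_table_synthetic.csv")
      write_kinetics_table(tab, p)
      manifest$outputs$table <- p
      tab
    })
  } else if (!is.null(cfg$table)) {
    table <- read_kinetics_table(cfg$table)
    manifest$outputs$table <- cfg$table
  }

  if ("summarize" %in% cfg$stages) {
    stage_wrap("summarize", {
      cmp <- pool_comparison(table)
      ps <- file.path(cfg$out_dir, "parameter_summary.csv")
      pk <- file.path(cfg$out_dir, "kw_tests.csv")
      pr <- file.path(cfg$out_dir, "reference_models.csv")
      utils::write.csv(cmp$summary, ps, row.names = FALSE)
      utils::write.csv(cmp$kw, pk, row.names = FALSE)
      utils::write.csv(cmp$reference, pr, row.names = FALSE)
      rho <- spearman_matrix(table[intersect(som_covariates(),
                                             names(table))])
      pc <- file.path(cfg$out_dir, "covariate_spearman.csv")
      utils::write.csv(as.data.frame(rho), pc, row.names = TRUE)
      manifest$outputs[c("summary", "kw", "reference", "spearman")] <-
        list(ps, pk, pr, pc)
      manifest$metrics$kw <- cmp$kw
      NULL
    })
  }

  models <- list()
  if ("train" %in% cfg$stages) {
    models <- stage_wrap("train", {
      out <- list()
      for (tg in cfg$targets) {
        mt <- sub("_.*$", "", tg)
        par <- sub("^.*_", "", tg)
        sub_tab <- table[table$model_type == mt, , drop = FALSE]
        fts <- intersect(som_covariates(), names(sub_tab))
        if (isTRUE(cfg$rfe)) {
          fts <- rfe_select(sub_tab, par, fts, method = cfg$methods[1],
                            folds = cfg$cv$folds, seed = cfg$seed)$features
        }
        fit_one <- function(m) {
          repeat_and_select(sub_tab, par, fts, method = m,
                            n_repeats = cfg$repeats, seed = cfg$seed,
                            cv = cfg$cv)$model
        }
        ms <- lapply(cfg$methods, fit_one)
        names(ms) <- cfg$methods
        if (length(ms) > 1) {
          test_rows <- sub_tab[ms[[1]]$partition$test, , drop = FALSE]
          rank <- compare_by_aic(ms, test_rows)
          manifest$metrics[[paste0("aic_", tg)]] <- rank
        }
        out[[tg]] <- ms
        manifest$metrics[[paste0("r2_test_", tg)]] <-
          lapply(ms, function(m) m$metrics_test$r2)
      }
      pm <- file.path(cfg$out_dir, "models.rds")
      saveRDS(out, pm)
      manifest$outputs$models <- pm
      out
    })
  }

  grids <- list()
  if ("map" %in% cfg$stages) {
    grids <- stage_wrap("map", {
      rasters <- gen_rasters(cfg$raster$nrow, cfg$raster$ncol,
                             seed = cfg$seed)
      out <- list()
      for (tg in names(models)) {
        m <- if ("rf" %in% names(models[[tg]])) {
          models[[tg]][["rf"]]
        } else {
          models[[tg]][[1]]
        }
        pg <- predict_grid(m, rasters)
        pph <- file.path(cfg$out_dir, paste0("map_", tg, ".txt"))
        write_grid_txt(pg$mean, pph)
        manifest$outputs[[paste0("map_", tg)]] <- pph
        un <- input_uncertainty_ph(m, rasters, rasters$ph5, rasters$ph95)
        pun <- file.path(cfg$out_dir, paste0("reun_ph_", tg, ".txt"))
        write_grid_txt(un$reun, pun)
        manifest$outputs[[paste0("reun_ph_", tg)]] <- pun
        manifest$metrics[[paste0("reun_ph_mean_", tg)]] <-
          mean(un$reun$values, na.rm = TRUE)
        if (m$method == "rf") {
          st <- structure_uncertainty(m, rasters)
          pst <- file.path(cfg$out_dir, paste0("reun_trees_", tg, ".txt"))
          write_grid_txt(st$reun, pst)
          manifest$outputs[[paste0("reun_trees_", tg)]] <- pst
          manifest$metrics[[paste0("reun_trees_mean_", tg)]] <-
            mean(st$reun$values, na.rm = TRUE)
        }
        out[[tg]] <- pg
      }
      out
    })
  }

  if ("profile" %in% cfg$stages) {
    stage_wrap("profile", {
      for (tg in names(grids)) {
        prof <- latitudinal_profile(grids[[tg]], band = cfg$band)
        pp <- file.path(cfg$out_dir, paste0("latitude_", tg, ".csv"))
        utils::write.csv(prof, pp, row.names = FALSE)
        manifest$outputs[[paste0("profile_", tg)]] <- pp
      }
      NULL
    })
  }

  .write_manifest(manifest, cfg$out_dir)
  manifest
}

.write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
  invisible(manifest)
}
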