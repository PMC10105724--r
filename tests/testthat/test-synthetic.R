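test_that("generators are pure functions of (config, seed)", {
  expect_identical(gen_covariates(50, seed = 3), gen_covariates(50, seed = 3))
  expect_false(identical(gen_covariates(50, seed = 3),
                         gen_covariates(50, seed = 4)))
  expect_identical(gen_kinetics_table(40, seed = 9),
                   gen_kinetics_table(40, seed = 9))
  r1 <- gen_rasters(12, 20, seed = 5)
  r2 <- gen_rasters(12, 20, seed = 5)
  expect_identical(lapply(r1, `[[`, "values"), lapply(r2, `[[`, "values"))
})

test_that("copula covariates reproduce the target rank correlations", {
  cov <- gen_covariates(10000, seed = 1)
  expect_lt(abs(cor(cov$map, cov$mat, method = "spearman") - 0.822), 0.03)
  expect_lt(abs(cor(cov$elev, cov$slope, method = "spearman") + 0.775), 0.03)
  # an uncorrelated pair stays near zero
  expect_lt(abs(cor(cov$ph, cov$ndvi, method = "spearman")), 0.05)
  # marginals respect their configured ranges
  cfg <- synthetic_config()
  for (v in names(cfg$marginals)) {
    expect_gte(min(cov[[v]]), cfg$marginals[[v]][1])
    expect_lte(max(cov[[v]]), cfg$marginals[[v]][2])
  }
})

test_that("texture triplets live on the 100% simplex", {
  cov <- gen_covariates(500, seed = 2)
  expect_true(all(abs(cov$sand + cov$silt + cov$clay - 100) < 1e-9))
  expect_true(all(cov$sand > 0 & cov$silt > 0 & cov$clay > 0))
})

test_that("unknown config fields are rejected", {
  expect_error(synthetic_config(nsites = 10), "unknown config")
})

test_that("the noiseless parameter map is deterministic in its covariates", {
  cov <- gen_covariates(300, seed = 7)
  pars <- true_parameter_map(cov, "M3", seed = 1, noise_sd = 0)
  # k3 is a smooth function of pH alone up to the secondary MAP trend;
  # with both frozen the map is deterministic
  pars2 <- true_parameter_map(cov, "M3", seed = 99, noise_sd = 0)
  expect_equal(pars$k3, pars2$k3)
  spec <- attr(pars, "map_spec")
  expect_equal(spec$k3$dom, "ph")
  # reconstruct log10 k3 from the published spec components
  u_ph <- (cov$ph - 3.5) / 6
  u_map <- cov$map / 4000
  rec <- spec$k3$intercept + spec$k3$w_dom * spec$k3$g_dom(u_ph) +
    spec$k3$w_sec * spec$k3$g_sec(u_map)
  expect_equal(log10(pars$k3), rec, tolerance = 1e-12)
  # fractions are a simplex
  expect_true(all(abs(pars$f1 + pars$f2 + pars$f3 - 1) < 1e-12))
  # rates keep the fast-to-slow ordering row-wise
  expect_true(all(pars$k1 > pars$k2 & pars$k2 > pars$k3))
})

test_that("generated rate medians sit inside the compiled 90% intervals", {
  tab <- gen_kinetics_table(1000, seed = 13)
  med <- function(mt, p) median(tab[[p]][tab$model_type == mt], na.rm = TRUE)
  expect_gt(med("M2", "k1"), 3.7e-3); expect_lt(med("M2", "k1"), 0.59)
  expect_gt(med("M2", "k2"), 5.02e-5); expect_lt(med("M2", "k2"), 2.00e-2)
  expect_gt(med("M3", "k1"), 4.2e-3); expect_lt(med("M3", "k1"), 0.50)
  expect_gt(med("M3", "k2"), 1.21e-4); expect_lt(med("M3", "k2"), 3.80e-2)
  expect_gt(med("M3", "k3"), 5.30e-7); expect_lt(med("M3", "k3"), 7.00e-4)
})

test_that("incubation curves are exact at zero noise and monotone with noise", {
  p <- fx_params3()
  ser0 <- gen_incubation_series(p, times = fx_times60(), noise_frac = 0)
  expect_equal(ser0$cumulative, cumulative_release(p, fx_times60()))
  expect_equal(ser0$flux, flux_rate(p, fx_times60()))

  ser1 <- gen_incubation_series(p, noise_frac = 0.05, seed = 1)
  ser2 <- gen_incubation_series(p, noise_frac = 0.05, seed = 2)
  expect_false(identical(ser1$cumulative, ser2$cumulative))
  expect_true(all(diff(ser1$cumulative) >= 0))
  expect_equal(ser1$times, ser2$times)
  expect_error(gen_incubation_series(p, noise_frac = -0.1), "non-negative")
})

test_that("generator and fitter round-trip at zero noise", {
  p <- pool_kinetics(c(0.25, 0.75), c(0.08, 0.004))
  ser <- gen_incubation_series(p, noise_frac = 0)
  fit <- fit_first_order(ser, 2, S0 = 1)
  expect_lt(max(abs(fit$params$k - p$k) / p$k), 1e-4)
  expect_lt(max(abs(fit$params$f - p$f) / p$f), 1e-4)
})

test_that("raster fields honour marginals, pH percentile order and shape", {
  expect_error(gen_rasters(5, 20), "10 x 10")
  ras <- gen_rasters(14, 28, seed = 3)
  expect_setequal(names(ras), c(som_covariates(), "silt", "ph5", "ph95"))
  expect_true(all(ras$ph5$values <= ras$ph$values))
  expect_true(all(ras$ph$values <= ras$ph95$values))
  cfg <- synthetic_config()
  expect_gte(min(ras$mat$values), cfg$marginals$mat[1])
  expect_lte(max(ras$mat$values), cfg$marginals$mat[2])
  expect_true(all(abs(ras$sand$values + ras$silt$values + ras$clay$values -
                        100) < 1e-9))
})

test_that("sites sampled from rasters carry the raster cell values", {
  ras <- gen_rasters(12, 24, seed = 8)
  sites <- sites_from_rasters(ras, 40, seed = 9)
  for (v in c("ph", "map", "sand", "ndvi")) {
    expect_equal(sites[[v]],
                 sample_grid(ras[[v]], sites$longitude, sites$latitude))
  }
})

test_that("full synthetic chain recovers dominant drivers end to end", {
  # covariates -> true parameters -> RF on a fresh seed: pH must dominate
  # the passive-pool rate in most seeds (dominance is built into the map)
  hits <- 0L
  for (s in 1:5) {
    tab <- gen_kinetics_table(350, seed = 100 + s)
    m3 <- tab[tab$model_type == "M3", ]
    m <- train_model(m3, "k3", method = "rf",
                     grid = data.frame(ntree = 60L, mtry = 3L),
                     cv = list(folds = 2, repeats = 1), seed = s)
    vi <- variable_importance(m)
    if (names(which.max(vi)) == "ph") hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})
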