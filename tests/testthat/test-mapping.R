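fx_rf_model <- function(seed = 5) {
  tab <- gen_kinetics_table(260, seed = seed)
  m3 <- tab[tab$model_type == "M3", ]
  train_model(m3, "k3", method = "rf",
              grid = data.frame(ntree = 60L, mtry = 3L),
              cv = list(folds = 3, repeats = 1), seed = seed)
}

test_that("grid geometry, sampling and the text format are consistent", {
  g <- grid_raster(matrix(1:12, 3, 4), 0, 40, 0, 30)
  expect_equal(grid_res(g), c(10, 10))
  ctr <- grid_centers(g)
  expect_equal(ctr$lon, c(5, 15, 25, 35))
  expect_equal(ctr$lat, c(25, 15, 5))
  # nearest-cell-center sampling, including the max edges
  expect_equal(sample_grid(g, 5, 25), 1)
  expect_equal(sample_grid(g, 39.9, 0.1), 12)
  expect_equal(sample_grid(g, 40, 0), 12)
  expect_true(is.na(sample_grid(g, 41, 5)))

  path <- withr::local_tempfile(fileext = ".txt")
  g$var <- "ph"
  write_grid_txt(g, path)
  back <- read_grid_txt(path)
  expect_equal(back$values, g$values)
  expect_equal(back$xmin, 0)
  expect_equal(back$var, "ph")
})

test_that("bilinear resampling is exact for constants and linear fields", {
  cst <- grid_raster(matrix(3.3, 10, 10), 0, 10, 0, 10)
  for (res in c(2, 0.5)) {
    out <- resample_grid(cst, res)
    expect_true(all(abs(out$values - 3.3) < 1e-12))
  }
  # 2x2 grid (1,2;3,4) sampled at its exact center -> mean of the four
  q <- grid_raster(matrix(c(1, 3, 2, 4), 2, 2), 0, 2, 0, 2)
  mid <- resample_grid(q, 2)  # single output cell centered at (1,1)
  expect_equal(as.vector(mid$values), 2.5)
  # linear-in-longitude gradient is reproduced exactly at interior centers
  lon <- 0.5 + 0:19
  lin <- grid_raster(matrix(rep(2 * lon, each = 10), 10, 20), 0, 20, 0, 10)
  out <- resample_grid(lin, 0.5)
  ctr <- grid_centers(out)
  interior <- ctr$lon > 1 & ctr$lon < 19
  expect_equal(out$values[5, interior], 2 * ctr$lon[interior],
               tolerance = 1e-9)
  # nodata propagates through interpolation
  h <- grid_raster(matrix(c(1, NA, 2, 4), 2, 2), 0, 2, 0, 2)
  expect_true(is.na(resample_grid(h, 2)$values[1, 1]))
  expect_warning(resample_grid(cst, 1 / 150), "100x")
})

test_that("cropping keeps cell values and implied geometry", {
  g <- grid_raster(matrix(seq_len(60 * 30), 30, 60), -180, 180, -90, 90)
  same <- crop_grid(g, ymin = -90, ymax = 90)
  expect_equal(same$values, g$values)
  crp <- crop_grid(g)  # default 60S-90N window
  expect_equal(crp$ymin, -60)
  expect_equal(nrow(crp$values), ceiling((90 - (-60)) / grid_res(g)[2]))
  expect_equal(crp$values, g$values[1:25, ])
  expect_error(crop_grid(g, ymin = 91, ymax = 95), "intersect")
})

test_that("gridded predictions equal tabular predictions cell by cell", {
  m <- fx_rf_model()
  ras <- gen_rasters(15, 30, seed = 2)
  pg <- predict_grid(m, ras)
  ctr <- grid_centers(pg$mean)
  set.seed(3)
  cells <- cbind(sample(15, 100, TRUE), sample(30, 100, TRUE))
  nd <- as.data.frame(lapply(ras[m$features], function(r) r$values[cells]))
  expect_equal(pg$mean$values[cells], unname(predict(m, nd)))

  const <- lapply(ras, function(r) {
    r$values[] <- mean(r$values)
    r
  })
  pgc <- predict_grid(m, const)
  point <- predict(m, as.data.frame(lapply(const[m$features],
                                           function(r) r$values[1, 1])))
  expect_true(all(abs(pgc$mean$values - point) < 1e-12))
  expect_error(predict_grid(m, ras[setdiff(names(ras), m$features[1])]),
               m$features[1])
})

test_that("pH-input uncertainty follows the width/mean definition", {
  m <- fx_rf_model()
  expect_true("ph" %in% m$features)
  ras <- gen_rasters(12, 24, seed = 4)
  # collapsed percentile layers -> zero relative uncertainty
  un0 <- input_uncertainty_ph(m, ras, ras$ph, ras$ph)
  expect_true(all(abs(un0$reun$values) < 1e-12, na.rm = TRUE))
  un <- input_uncertainty_ph(m, ras, ras$ph5, ras$ph95)
  expect_true(all(un$reun$values >= 0, na.rm = TRUE))
  expect_true(all(un$lower$values <= un$upper$values, na.rm = TRUE))
  # hand arithmetic: width 1 over mean 2
  expect_equal(somkin:::.reun_from_bounds(1, 2, 2), 0.5)
  expect_true(is.na(somkin:::.reun_from_bounds(1, 2, 0)))
})

test_that("a model without pH in its subset has zero pH-driven uncertainty", {
  tab <- gen_kinetics_table(200, seed = 6)
  m3 <- tab[tab$model_type == "M3", ]
  m <- train_model(m3, "k1", features = c("sand", "mbc"), method = "rf",
                   grid = data.frame(ntree = 40L, mtry = 1L),
                   cv = list(folds = 3, repeats = 1), seed = 6)
  ras <- gen_rasters(10, 20, seed = 6)
  un <- input_uncertainty_ph(m, ras, ras$ph5, ras$ph95)
  expect_true(all(un$reun$values == 0, na.rm = TRUE))
})

test_that("relative uncertainty is invariant to rescaling predictions", {
  lo <- matrix(runif(50, 1, 2), 5, 10)
  hi <- lo + runif(50, 0, 1)
  mn <- (lo + hi) / 2
  r1 <- somkin:::.reun_from_bounds(lo, hi, mn)
  r2 <- somkin:::.reun_from_bounds(3 * lo, 3 * hi, 3 * mn)
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("tree-ensemble uncertainty matches sorted order statistics", {
  m <- fx_rf_model()
  ras <- gen_rasters(10, 20, seed = 7)
  st <- structure_uncertainty(m, ras)
  expect_true(all(st$lower$values <= st$mean$values + 1e-12, na.rm = TRUE))
  expect_true(all(st$mean$values <= st$upper$values + 1e-12, na.rm = TRUE))
  # brute-force check on a handful of cells
  nd <- as.data.frame(lapply(ras[m$features], function(r) r$values[1:5, 1]))
  trees <- predict_trees(m, nd)
  for (i in 1:5) {
    srt <- sort(trees[i, ])
    q <- stats::quantile(srt, c(0.05, 0.95), type = 7, names = FALSE)
    expect_equal(st$lower$values[i, 1], q[1], tolerance = 1e-12)
    expect_equal(st$upper$values[i, 1], q[2], tolerance = 1e-12)
    expect_equal(st$mean$values[i, 1], mean(srt), tolerance = 1e-12)
  }
  # widening one tail value can only widen (or keep) the 90% width
  v <- trees[1, ]
  w0 <- diff(stats::quantile(v, c(0.05, 0.95), type = 7, names = FALSE))
  v[which.max(v)] <- max(v) * 10
  w1 <- diff(stats::quantile(v, c(0.05, 0.95), type = 7, names = FALSE))
  expect_gte(w1, w0)
})

test_that("latitudinal profiles aggregate bands correctly", {
  cst <- grid_raster(matrix(4.2, 20, 30), -180, 180, -60, 90)
  prof <- latitudinal_profile(cst, band = 7.5)
  expect_equal(nrow(prof), ceiling(150 / 7.5))
  expect_true(all(prof$mean == 4.2))
  expect_true(all(prof$hi90 - prof$lo90 == 0))

  # field linear in latitude: band means are linear in the band center
  nr <- 30
  lat_c <- 90 - (seq_len(nr) - 0.5) * 150 / nr
  lin <- grid_raster(matrix(rep(2 * lat_c, 10), nr, 10), -180, 180, -60, 90)
  prof2 <- latitudinal_profile(lin, band = 10)
  expect_equal(prof2$mean, 2 * prof2$lat_center, tolerance = 1e-9)

  # band aggregation ignores longitude: shuffling within rows changes nothing
  shuf <- lin
  set.seed(1)
  for (i in seq_len(nr)) shuf$values[i, ] <- sample(shuf$values[i, ])
  expect_equal(latitudinal_profile(shuf, band = 10), prof2)

  expect_error(latitudinal_profile(grid_raster(matrix(NA_real_, 10, 10))),
               "no defined")
})
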