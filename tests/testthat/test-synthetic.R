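test_that("bundle counts follow the configuration", {
  cfg <- fieldConfig(n_rows = 2L, n_cols = 2L,
                     timepoints_dat = c(12L, 56L, 101L), seed = 7L)
  b <- generateField(cfg)
  expect_equal(nrow(bundleTruth(b)), 4L)
  expect_length(b@layers, 3L)
  expect_length(b@detections, 3L)
  # all rasters of one flight share shape and geotransform
  shp <- dim(rasterValues(bundleLayers(b, 1)[[1]]))
  for (L in bundleLayers(b, 2)) {
    expect_equal(dim(rasterValues(L)), shp)
    expect_equal(rasterGeoTransform(L)@gsd_x, 0.01)
  }
  expect_true(all(bundleTruth(b)$weight_g > 0))
  expect_false(anyDuplicated(bundleTruth(b)$plant_id) > 0)
})

test_that("identical seeds give bit-identical bundles", {
  cfg <- fieldConfig(n_rows = 2L, n_cols = 2L,
                     timepoints_dat = c(12L, 56L, 101L), seed = 7L)
  b1 <- generateField(cfg)
  b2 <- generateField(cfg)
  expect_identical(bundleTruth(b1), bundleTruth(b2))
  for (t in 1:3) {
    expect_identical(bundleDetections(b1, t), bundleDetections(b2, t))
    for (nm in names(b1@layers[[t]]))
      expect_identical(rasterValues(bundleLayers(b1, t)[[nm]]),
                       rasterValues(bundleLayers(b2, t)[[nm]]))
  }
})

test_that("rendered growth is monotone non-decreasing in DAT", {
  b <- small_bundle()
  expect_true(all(apply(b@radii, 1, function(r) all(diff(r) >= 0))))
  expect_true(all(apply(b@heights, 1, function(h) all(diff(h) >= 0))))
  # rendered max height per flight tracks the growth curve (the peak pixel
  # sits up to half a pixel off the plant centre, so slightly below)
  for (t in c(2, 5)) {
    hmax <- max(rasterValues(bundleLayers(b, t)[["height"]]))
    expect_lte(hmax, max(b@heights[, t]) + 1e-9)
    expect_gte(hmax, 0.95 * max(b@heights[, t]))
  }
})

test_that("oversized plants are rejected with a sizing error", {
  expect_error(fieldConfig(max_radius_m = 0.30), "sizing")
  expect_error(fieldConfig(miss_rate = 1.5), "miss_rate")
  expect_error(fieldConfig(timepoints_dat = c(12L, 12L)), "increasing")
})

test_that("the weight model is recoverable from the emitted rasters", {
  b <- small_noiseless_bundle()
  cfg <- b@config
  tr <- bundleTruth(b)
  # independently recompute volume and mid-season NDVI from the rasters
  gsd <- cfg@gsd_m
  gt <- b@gt
  tp_fin <- length(b@tp_dat)
  tp_mid <- which.min(abs(b@tp_dat - cfg@spectral$bump_mid_dat))
  h_fin <- rasterValues(bundleLayers(b, tp_fin)[["height"]])
  h_ref <- rasterValues(bundleLayers(b, 1)[["height"]])
  nir <- rasterValues(bundleLayers(b, tp_mid)[["NIR"]])
  red <- rasterValues(bundleLayers(b, tp_mid)[["red"]])
  xc <- gt@origin_x + (seq_len(ncol(h_fin)) - 0.5) * gsd
  yc <- gt@origin_y - (seq_len(nrow(h_fin)) - 0.5) * gsd
  vol <- ndvi <- numeric(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    r <- tr$radius_final_m[i]
    ci <- which(abs(xc - tr$x[i]) <= r); ri <- which(abs(yc - tr$y[i]) <= r)
    d <- sqrt(outer((yc[ri] - tr$y[i])^2, (xc[ci] - tr$x[i])^2, "+"))
    disc <- d <= r
    vol[i] <- sum(pmax(h_fin[ri, ci] - h_ref[ri, ci], 0)[disc] * 100) *
      gsd^2 * 1e4
    rm <- b@radii[i, tp_mid]
    cim <- which(abs(xc - tr$x[i]) <= rm)
    rim <- which(abs(yc - tr$y[i]) <= rm)
    dm <- sqrt(outer((yc[rim] - tr$y[i])^2, (xc[cim] - tr$x[i])^2, "+"))
    dscm <- dm <= rm
    ndvi[i] <- mean(((nir - red) / (nir + red))[rim, cim][dscm])
  }
  # with noise_sd = 0 an OLS fit recovers both coefficients exactly
  fit <- lm(tr$weight_g ~ vol + ndvi)
  expect_equal(unname(coef(fit)["vol"]), cfg@weight_model$beta_volume,
               tolerance = 1e-3)
  expect_equal(unname(coef(fit)["ndvi"]), cfg@weight_model$beta_spectral,
               tolerance = 1e-3)
  expect_equal(unname(coef(fit)["(Intercept)"]), 0, tolerance = 1e-6)
})

test_that("simulated detections honor miss rate and jitter settings", {
  b <- small_noiseless_bundle()
  det <- bundleDetections(b, 3)
  # no noise: exactly one box per plant, containing the plant's disc
  expect_equal(nrow(det), nrow(bundleGrid(b)))
  tr <- bundleTruth(b)
  i <- match(det$plant_truth, tr$plant_id)
  r <- b@radii[i, 3]
  expect_true(all(det$xmin <= tr$x[i] - r + 1e-9 &
                  det$xmax >= tr$x[i] + r - 1e-9 &
                  det$ymin <= tr$y[i] - r + 1e-9 &
                  det$ymax >= tr$y[i] + r - 1e-9))
  # miss_rate 1 drops everything
  b2 <- b
  b2@config@detector$miss_rate <- 1
  expect_equal(nrow(simulateDetections(b2, 1)), 0L)
  # determinism under the same seed
  expect_identical(simulateDetections(b, 2), simulateDetections(b, 2))
})

test_that("the retained detection count is binomial in the miss rate", {
  b <- generateField(fieldConfig(n_rows = 10L, n_cols = 10L,
                                 timepoints_dat = c(12L, 56L, 101L),
                                 miss_rate = 0.1, seed = 3L))
  counts <- vapply(1:200, function(s) {
    b@config@seed <- s
    nrow(simulateDetections(b, 2))
  }, numeric(1))
  se <- sqrt(100 * 0.1 * 0.9 / 200)
  expect_lt(abs(mean(counts) - 90), 3 * se)
})
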