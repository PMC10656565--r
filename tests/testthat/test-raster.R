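test_that("point clouds rasterize to per-cell means with nearest fill", {
  gt <- geoTransform(0, 2, 1, 1)
  # two points in one cell average; empty cells take the nearest value
  cloud <- rbind(c(0.5, 1.5, 1), c(0.6, 1.4, 3))
  r <- rasterizeHeight(cloud, gt, c(2, 2))
  expect_equal(rasterValues(r)[1, 1], 2.0)
  expect_true(all(rasterValues(r) == 2.0))  # single filled cell fills all
  # constant cloud covering all cells gives a constant raster
  full <- expand.grid(x = c(0.5, 1.5), y = c(0.5, 1.5))
  r2 <- rasterizeHeight(cbind(full$x, full$y, 7), gt, c(2, 2))
  expect_true(all(rasterValues(r2) == 7))
  expect_error(rasterizeHeight(matrix(numeric(0), 0, 3), gt, c(2, 2)),
               "empty")
})

test_that("surface subtraction clamps negatives to zero", {
  gt <- geoTransform(0, 1, 1)
  h <- rasterLayer(matrix(c(0.30, 0.05, 0.10, 0.10), 2), gt, "height")
  s <- rasterLayer(matrix(0.10, 2, 2), gt, "height")
  out <- rasterValues(subtractSurface(h, s))
  expect_equal(out, matrix(c(0.20, 0, 0, 0), 2))
  expect_error(subtractSurface(h, rasterLayer(matrix(0, 3, 3), gt, "s")),
               "mismatch")
})

test_that("phase correlation recovers integer translations with wrap-around", {
  set.seed(3)
  a <- matrix(rnorm(64 * 64), 64)
  expect_equal(phaseCorrelationShift(a, a), c(dx = 0, dy = 0))
  b <- rollMatrix(a, 3, -2)
  expect_equal(phaseCorrelationShift(a, b), c(dx = -2, dy = 3))
  # a shift of N-1 is reported as -1
  expect_equal(phaseCorrelationShift(a, rollMatrix(a, 63, 0)),
               c(dx = 0, dy = -1))
  expect_error(phaseCorrelationShift(matrix(1, 8, 8), matrix(1, 8, 8)),
               "constant")
})

test_that("MS registration resamples to the RGB grid and closes residual shifts", {
  set.seed(9)
  gt <- geoTransform(0, 0.64, 0.01)
  base <- matrix(runif(64 * 64), 64)
  rgb <- list(R = rasterLayer(base, gt, "R"),
              G = rasterLayer(base, gt, "G"),
              B = rasterLayer(base, gt, "B"))
  # already on the grid with zero offset: values preserved exactly
  ms <- list(NIR = rasterLayer(base, gt, "NIR"))
  reg <- registerMSToRGB(ms, rgb)
  expect_equal(rasterValues(reg$NIR), base)
  expect_equal(attr(reg, "shift"), c(dx = 0, dy = 0))
  # 2x coarser MS: each value replicated over its 2x2 footprint
  coarse <- matrix(runif(32 * 32), 32)
  gt2 <- geoTransform(0, 0.64, 0.02)
  ms2 <- list(NIR = rasterLayer(coarse, gt2, "NIR"))
  reg2 <- registerMSToRGB(ms2, rasterLayer(coarse[rep(1:32, each = 2),
                                                  rep(1:32, each = 2)],
                                           gt, "gray"))
  expect_equal(rasterValues(reg2$NIR),
               coarse[rep(1:32, each = 2), rep(1:32, each = 2)])
  # injected integer offset is corrected; second pass is the identity
  ms3 <- list(NIR = rasterLayer(rollMatrix(base, 3, -2), gt, "NIR"))
  reg3 <- registerMSToRGB(ms3, rasterLayer(base, gt, "gray"))
  expect_equal(attr(reg3, "shift"), c(dx = 2, dy = -3))
  inner <- rasterValues(reg3$NIR)[10:50, 10:50]
  expect_equal(inner, base[10:50, 10:50])
  reg4 <- registerMSToRGB(list(NIR = reg3$NIR),
                          rasterLayer(base, gt, "gray"))
  expect_equal(attr(reg4, "shift"), c(dx = 0, dy = 0))
})

test_that("alignment reports shift and grayscale correlation", {
  set.seed(5)
  gt <- geoTransform(0, 0.32, 0.01)
  mk <- function(m) list(R = rasterLayer(m, gt, "R"),
                         G = rasterLayer(m * 0.8, gt, "G"),
                         B = rasterLayer(m * 0.5, gt, "B"))
  a <- mk(matrix(runif(32 * 32), 32))
  rep0 <- assessAlignment(a, a)
  expect_equal(rep0$shift_px, c(dx = 0, dy = 0))
  expect_equal(rep0$correlation, 1.0)
  b <- mk(matrix(runif(32 * 32), 32))
  b$R@values <- rollMatrix(a$R@values, 1, 1)
  b$G@values <- rollMatrix(a$G@values, 1, 1)
  b$B@values <- rollMatrix(a$B@values, 1, 1)
  rep1 <- assessAlignment(a, b)
  expect_equal(rep1$shift_px, c(dx = 1, dy = 1))
  expect_equal(rep1$shift_mm, c(dx = 10, dy = 10))  # 0.01 m gsd
  inv <- list(R = rasterLayer(1 - a$R@values, gt, "R"),
              G = rasterLayer(1 - a$G@values, gt, "G"),
              B = rasterLayer(1 - a$B@values, gt, "B"))
  # luminance of (1 - channels) is an affine inversion of the luminance
  expect_equal(assessAlignment(a, inv)$correlation, -1.0)
})

test_that("plant stacks cut identical windows across layers and flights", {
  gt <- geoTransform(0, 3, 0.01)
  mk <- function(v) rasterLayer(matrix(v, 300, 300), gt, "x")
  layers <- list(list(R = mk(1), NIR = mk(2)), list(R = mk(3), NIR = mk(4)))
  box <- boundingBoxes(1, 1, 2, 2)
  st <- cutPlantStack(box, layers, c(12L, 34L))
  expect_equal(dim(stackValues(st)), c(2L, 2L, 100L, 100L))
  expect_equal(st@pixel_area_cm2, 1.0)
  expect_equal(stackLayer(st, 2, "NIR")[1, 1], 4)
  # corner coordinates reproduce the box to one pixel
  px <- projectedBoxToPixel(box, gt)
  expect_equal(unname(px["col1"] - px["col0"]), 100)
  expect_error(cutPlantStack(boundingBoxes(-1, 0, 0.5, 0.5), layers,
                             c(12L, 34L)), "outside")
})
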