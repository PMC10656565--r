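test_that("vegetation-index formulas match hand evaluation", {
  L <- list(NIR = matrix(0.8), red = matrix(0.2), red_edge = matrix(0.3),
            green = matrix(0.2), blue = matrix(0.1),
            R = matrix(0.2), G = matrix(0.2), B = matrix(0.1))
  expect_equal(computeVI(L, "NDVI")[1, 1], 0.6)
  expect_equal(computeVI(L, "SAVI")[1, 1], (0.6 / 1.5) * 1.5)
  expect_equal(computeVI(L, "GRVI-MS")[1, 1], 0)   # green == red
  expect_equal(computeVI(L, "GRVI-RGB")[1, 1], 0)  # G == R
  L$NIR <- matrix(0.6)
  expect_equal(computeVI(L, "RECI")[1, 1], 1.0)
  # zero denominator becomes missing
  L0 <- list(NIR = matrix(0.0), red = matrix(0.0))
  expect_true(is.na(computeVI(L0, "NDVI")[1, 1]))
  expect_error(computeVI(L, "NOPE"), "unknown")
})

test_that("index ranges stay in [-1, 1] for non-negative reflectance", {
  set.seed(2)
  L <- list(NIR = matrix(runif(100), 10), red = matrix(runif(100), 10),
            red_edge = matrix(runif(100), 10),
            green = matrix(runif(100), 10), blue = matrix(runif(100), 10),
            R = matrix(runif(100), 10), G = matrix(runif(100), 10),
            B = matrix(runif(100), 10))
  for (nm in c("NDVI", "GRVI-RGB", "GRVI-MS", "MGRVI-RGB", "MGRVI-MS",
               "RGBVI-RGB", "RGBVI-MS", "GNDVI", "NDRE")) {
    v <- computeVI(L, nm)
    expect_true(all(v >= -1 - 1e-12 & v <= 1 + 1e-12, na.rm = TRUE),
                info = nm)
  }
})

test_that("correlated indices are pruned greedily in frozen order", {
  set.seed(4)
  base <- rnorm(40)
  tab <- cbind("GRVI-RGB" = base, "NDVI" = rnorm(40), "SAVI" = rnorm(40))
  expect_equal(as.vector(pruneCorrelatedVIs(tab)),
               c("GRVI-RGB", "NDVI", "SAVI"))
  # an exact duplicate is dropped; three identical columns keep the first
  tab2 <- cbind("GRVI-RGB" = base, "NDVI" = base, "SAVI" = base,
                "NDRE" = rnorm(40))
  kept <- pruneCorrelatedVIs(tab2)
  expect_equal(as.vector(kept), c("GRVI-RGB", "NDRE"))
  # anti-correlated duplicates count too (absolute correlation)
  tab3 <- cbind("GRVI-RGB" = base, "NDVI" = -base)
  expect_equal(as.vector(pruneCorrelatedVIs(tab3)), "GRVI-RGB")
  # constant columns are retained but flagged
  tab4 <- cbind("GRVI-RGB" = base, "NDVI" = rep(1, 40))
  kept4 <- pruneCorrelatedVIs(tab4)
  expect_true("NDVI" %in% kept4)
  expect_equal(attr(kept4, "flagged"), "NDVI")
})

test_that("k-means soil mask separates two pixel populations deterministically", {
  set.seed(11)
  n <- 40 * 40
  veg <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.4, 0.6))
  mk <- function(mu_v, mu_s, sd = 0.02)
    matrix(rnorm(n, ifelse(veg, mu_v, mu_s), sd), 40)
  vis <- list(NDVI = mk(0.8, 0.05), SAVI = mk(0.75, 0.05),
              GNDVI = mk(0.6, 0.1))
  m <- soilMaskKmeans(vis, seed = 3)
  expect_gte(mean(m == matrix(veg, 40)), 0.99)
  expect_identical(m, soilMaskKmeans(vis, seed = 3))
  # the soil label comes from the NDVI rule, not cluster numbering: an
  # inverted seed (different restarts) gives the same decision
  m2 <- soilMaskKmeans(vis, seed = 99)
  expect_gte(mean(m == m2), 0.99)
  expect_error(soilMaskKmeans(list(NDVI = matrix(0.5, 4, 4)), 1),
               "identical")
})

test_that("contour filter removes only sub-threshold components", {
  m <- matrix(FALSE, 60, 60)
  m[2:41, 2:26] <- TRUE            # 1000 px component
  m[50:54, 50] <- TRUE             # 5 px component (0.005 of largest)
  out <- contourFilter(m, 0.05)
  expect_true(all(out[2:41, 2:26]))
  expect_false(any(out[50:54, 50]))
  # single component unchanged; empty mask passes through
  single <- matrix(FALSE, 10, 10); single[3:6, 3:6] <- TRUE
  expect_equal(unclass(contourFilter(single))[1:100],
               as.vector(single))
  empty <- matrix(FALSE, 5, 5)
  expect_false(any(contourFilter(empty)))
  # components above the threshold survive
  m2 <- matrix(FALSE, 30, 30)
  m2[1:10, 1:10] <- TRUE  # 100
  m2[20:24, 20:21] <- TRUE  # 10 px = 0.1 of largest, kept
  expect_true(any(contourFilter(m2, 0.05)[20:24, 20:21]))
})

test_that("the soil-mask / contour cascade is idempotent", {
  set.seed(21)
  n <- 30 * 30
  veg <- rep(FALSE, n)
  veg[sample(n, 200)] <- TRUE
  vis <- list(NDVI = matrix(rnorm(n, ifelse(veg, 0.8, 0.0), 0.03), 30),
              SAVI = matrix(rnorm(n, ifelse(veg, 0.7, 0.05), 0.03), 30))
  once <- contourFilter(soilMaskKmeans(vis, seed = 1), 0.05)
  twice <- contourFilter(once, 0.05)
  expect_equal(unclass(twice)[seq_len(n)], unclass(once)[seq_len(n)])
})

test_that("histogram equalization follows the cdf mapping", {
  # constant layer stays constant
  eq0 <- equalizeRGB(list(R = matrix(0.5, 4, 4)))
  expect_true(length(unique(as.vector(eq0$R))) == 1L)
  # two-level image {0 at 75%, 255 at 25%} maps to {191, 255}
  v <- matrix(c(rep(0, 12), rep(255, 4)), 4)
  eq <- equalizeRGB(list(R = v))
  expect_equal(sort(unique(as.vector(eq$R))), c(191, 255))
  # a smooth gradient equalizes to a near-uniform histogram
  g <- matrix(seq(0, 1, length.out = 64 * 64)^2, 64)
  eqg <- equalizeRGB(list(R = g))$R
  h <- tabulate(findInterval(eqg, seq(0, 255.0001, length.out = 9)), 8)
  expect_lt(max(abs(h - mean(h))) / mean(h), 0.1)
  # NA cells are ignored and preserved
  vna <- v; vna[1, 1] <- NA
  expect_true(is.na(equalizeRGB(list(R = vna))$R[1, 1]))
})

test_that("centering uses the hull-vertex mean and crops the central window", {
  # unit-square hull: vertex mean is the centre
  mask <- matrix(FALSE, 9, 9)
  mask[c(3, 7), c(3, 7)] <- TRUE  # corners of a square
  idx <- which(mask, arr.ind = TRUE)
  hull <- idx[grDevices::chull(idx[, 2], idx[, 1]), ]
  expect_equal(colMeans(hull), c(row = 5, col = 5))
  # symmetric blob already centred: zero shift
  a <- array(0, c(1, 1, 9, 9)); a[1, 1, 4:6, 4:6] <- 1
  st <- new("PlantImageStack", values = a, tp_dat = 12L,
            layer_names = "height", mask = array(TRUE, c(1, 9, 9)),
            pixel_area_cm2 = 1)
  blob <- matrix(FALSE, 9, 9); blob[4:6, 4:6] <- TRUE
  cc <- centerAndCrop(st, blob, crop_fraction = 1)
  expect_equal(attr(cc, "shift"), c(dx = 0, dy = 0))
  expect_equal(stackValues(cc), a)
  # 100 x 100 window at 0.70 retains rows/cols 16..85 (1-based)
  expect_equal(range(uavpheno:::cropIndices(100, 0.70)), c(16, 85))
  expect_equal(length(uavpheno:::cropIndices(100, 0.70)), 70L)
  expect_error(centerAndCrop(st, matrix(FALSE, 9, 9)), "empty")
})

test_that("centering is translation-equivariant", {
  a <- array(0, c(1, 1, 21, 21))
  a[1, 1, 9:13, 9:13] <- matrix(runif(25), 5)
  st <- new("PlantImageStack", values = a, tp_dat = 12L,
            layer_names = "height", mask = array(TRUE, c(1, 21, 21)),
            pixel_area_cm2 = 1)
  m0 <- a[1, 1, , ] > 0
  c0 <- centerAndCrop(st, m0, crop_fraction = 0.6)
  # translate everything by (2, -3) and re-centre
  a2 <- a; a2[1, 1, , ] <- translateMatrix(a[1, 1, , ], 2, -3, fill = 0)
  st2 <- new("PlantImageStack", values = a2, tp_dat = 12L,
             layer_names = "height", mask = array(TRUE, c(1, 21, 21)),
             pixel_area_cm2 = 1)
  c2 <- centerAndCrop(st2, a2[1, 1, , ] > 0, crop_fraction = 0.6)
  expect_equal(attr(c2, "shift"),
               attr(c0, "shift") + c(dx = 3, dy = -2))
  expect_equal(stackValues(c2), stackValues(c0))
})
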