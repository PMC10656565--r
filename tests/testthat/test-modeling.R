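test_that("metrics match hand arithmetic and textbook oracles", {
  y <- c(1, 2, 3); yh <- c(1, 2, 4)
  expect_equal(rSquared(y, yh), 0.5)
  expect_equal(rmse(y, yh), sqrt(1 / 3))
  expect_equal(rSquared(y, y), 1)
  expect_equal(rmse(y, y), 0)
  expect_equal(rSquared(y, rep(mean(y), 3)), 0)
  expect_error(rSquared(c(2, 2, 2), yh), "constant")
  # independent textbook implementations on random vectors
  set.seed(13)
  for (i in 1:5) {
    a <- rnorm(50); b <- a + rnorm(50)
    expect_equal(rSquared(a, b),
                 1 - sum((a - b)^2) / sum((a - mean(a))^2),
                 tolerance = 1e-12)
    expect_equal(rmse(a, b), sqrt(sum((a - b)^2) / 50), tolerance = 1e-12)
  }
})

test_that("splits and folds have the documented sizes and determinism", {
  sp <- splitData(839, seed = 4)
  expect_equal(length(sp$train), 756L)
  expect_equal(length(sp$test), 83L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_identical(sp, splitData(839, seed = 4))
  f <- foldAssignments(756, 5, seed = 2)
  expect_equal(sort(tabulate(f), decreasing = TRUE),
               c(152L, 151L, 151L, 151L, 151L))
  expect_identical(f, foldAssignments(756, 5, seed = 2))
  expect_error(splitData(5), "at least")
})

test_that("cross-validation recovers a noiseless linear signal", {
  set.seed(6)
  X <- matrix(rnorm(120 * 4), 120, dimnames = list(NULL, paste0("x", 1:4)))
  y <- drop(X %*% c(2, -1, 0.5, 0)) + 10
  cv <- crossValidate(modelSpec("lasso"), X, y, seed = 3)
  expect_gte(cv$mean_cv_r2, 0.999)
  expect_equal(nrow(cv$cv), 5L)
  # permuting rows together with the fold labels leaves metrics unchanged
  folds <- foldAssignments(120, 5, seed = 3)
  a <- crossValidate(modelSpec("ridge"), X, y, folds = folds)
  perm <- sample(120)
  b <- crossValidate(modelSpec("ridge"), X[perm, ], y[perm],
                     folds = folds[perm])
  expect_equal(a$mean_cv_r2, b$mean_cv_r2, tolerance = 1e-10)
  expect_error(crossValidate(modelSpec("lasso"), X, rep(1, 120)),
               "degenerate")
})

test_that("every model family fits, predicts and is seed-stable", {
  set.seed(6)
  X <- matrix(rnorm(90 * 5), 90, dimnames = list(NULL, paste0("x", 1:5)))
  y <- drop(X %*% c(3, -2, 1, 0, 0)) + rnorm(90, 0, 0.5)
  sp <- splitData(90, seed = 1)
  for (fam in c("PLS", "lasso", "ridge", "SVM-linear", "RF")) {
    cv <- crossValidate(modelSpec(fam, seed = 5), X[sp$train, ],
                        y[sp$train], seed = 2)
    te <- evaluateOnTest(cv, X[sp$test, ], y[sp$test])
    expect_gte(cv$mean_cv_r2, if (fam == "RF") 0.5 else 0.9)
    expect_gte(te$r2, if (fam == "RF") 0.3 else 0.9)
    cv2 <- crossValidate(modelSpec(fam, seed = 5), X[sp$train, ],
                         y[sp$train], seed = 2)
    expect_equal(cv$mean_cv_r2, cv2$mean_cv_r2)
  }
})

test_that("test-set leakage cannot reach training metrics", {
  set.seed(9)
  X <- matrix(rnorm(100 * 3), 100, dimnames = list(NULL, paste0("x", 1:3)))
  y <- drop(X %*% c(1, 2, 3)) + rnorm(100, 0, 0.3)
  sp <- splitData(100, seed = 2)
  cv <- crossValidate(modelSpec("ridge"), X[sp$train, ], y[sp$train],
                      seed = 7)
  y2 <- y; y2[sp$test] <- sample(y2[sp$test])
  cv2 <- crossValidate(modelSpec("ridge"), X[sp$train, ], y2[sp$train],
                       seed = 7)
  expect_identical(cv$cv, cv2$cv)
})

test_that("exhaustive search scores every subset and finds the generators", {
  set.seed(15)
  X <- matrix(rnorm(100 * 3), 100, dimnames = list(NULL, c("a", "b", "c")))
  y <- drop(X %*% c(2, 1.5, 0)) + rnorm(100, 0, 0.2)
  ex <- exhaustiveSelection(X, y, seed = 1)
  expect_equal(nrow(ex), 3L)          # best subset per cardinality
  expect_equal(sum(choose(3, 1:3)), 7L)  # 2^3 - 1 subsets scored
  expect_equal(sort(strsplit(ex$features[2], ",")[[1]]), c("a", "b"))
  # score is non-decreasing in cardinality within CV noise
  expect_true(all(diff(ex$score) > -0.02))
  big <- matrix(rnorm(20 * 16), 20)
  colnames(big) <- paste0("x", 1:16)
  expect_error(exhaustiveSelection(big, rnorm(20)), "sfsForward")
})

test_that("forward selection is greedy with the prefix property", {
  set.seed(16)
  X <- matrix(rnorm(120 * 5), 120, dimnames = list(NULL, paste0("x", 1:5)))
  y <- 3 * X[, "x4"] + 0.5 * X[, "x2"] + rnorm(120, 0, 0.3)
  s3 <- sfsForward(X, y, n_select = 3, seed = 2)
  expect_equal(s3$feature[1], "x4")  # dominant feature chosen first
  s5 <- sfsForward(X, y, n_select = 5, seed = 2)
  expect_equal(s5$feature[1:3], s3$feature)      # prefix property
  expect_setequal(attr(s5, "path"), colnames(X))  # full path is a permutation
})

test_that("random-forest importance is normalized, ranked and seeded", {
  set.seed(17)
  X <- matrix(rnorm(150 * 6), 150, dimnames = list(NULL, paste0("x", 1:6)))
  y <- 4 * X[, "x1"] + 3 * X[, "x2"] + rnorm(150, 0, 0.3)
  imp <- rfImportance(X, y, seed = 5)
  expect_equal(sum(imp$mdi), 1)
  expect_setequal(imp$feature[1:2], c("x1", "x2"))
  expect_identical(imp, rfImportance(X, y, seed = 5))
})

test_that("temporal schemes select the documented flights", {
  expect_equal(selectTimepoints(c(12L, 19L, 26L, 33L), "interval_7d"),
               c(12L, 19L, 26L, 33L))
  expect_equal(selectTimepoints(c(12L, 16L, 20L, 24L, 28L), "interval_7d"),
               c(12L, 20L, 28L))
  cal <- c(12L, 20L, 34L, 47L, 56L, 70L, 80L, 90L, 101L)
  expect_equal(selectTimepoints(cal, "growth_pattern"),
               c(12L, 34L, 56L, 80L, 101L))
  expect_equal(selectTimepoints(cal, "all_tps"), cal)
  # cutoff truncation and the empty-result error
  sc <- temporalScheme("interval_15d", cutoff_dat = 50L)
  expect_true(all(selectTimepoints(cal, sc) <= 50L))
  expect_error(selectTimepoints(cal,
               temporalScheme("all_tps", cutoff_dat = 5L)), "cutoff")
})

test_that("designs concatenate selected flights cumulatively", {
  feats <- paste0("f", 1:7)
  dats <- c(12L, 20L, 28L, 36L, 44L, 52L, 60L, 68L, 76L, 84L, 92L, 100L,
            108L, 116L)
  cols <- as.vector(outer(feats, dats, function(f, d) paste0(f, "@", d)))
  m <- matrix(rnorm(30 * length(cols)), 30, dimnames = list(1:30, cols))
  ft <- featureTable(m, weights = runif(30, 1000, 4000))
  d_all <- buildDesign(ft, temporalScheme("all_tps"))
  expect_equal(ncol(d_all$X), 7L * 14L)  # 98 columns
  d_one <- buildDesign(ft, temporalScheme("all_tps", "single_tp"))
  expect_equal(ncol(d_one$X), 7L)
  # a cutoff before the second flight makes cumulative and single equal
  sc <- temporalScheme("all_tps", cutoff_dat = 12L)
  d_cut <- buildDesign(ft, sc)
  expect_equal(ncol(d_cut$X), 7L)
  expect_true(all(grepl("@12$", colnames(d_cut$X))))
  # subsetting features
  d_sub <- buildDesign(ft, temporalScheme("all_tps"), features = feats[1:2])
  expect_equal(ncol(d_sub$X), 28L)
})

test_that("the prior-to-harvest sweep reports one row per scheme, cutoff, model", {
  set.seed(19)
  feats <- c("volume", "NDVI")
  dats <- c(12L, 34L, 56L, 80L, 101L)
  cols <- as.vector(outer(feats, dats, function(f, d) paste0(f, "@", d)))
  lat <- matrix(rnorm(60 * length(cols)), 60, dimnames = list(1:60, cols))
  y <- 2000 + 500 * lat[, "volume@101"] + 200 * lat[, "NDVI@56"] +
    rnorm(60, 0, 50)
  ft <- featureTable(lat, weights = pmax(y, 1))
  sw <- priorToHarvestSweep(ft, c("all_tps", "growth_pattern"),
                            harvest_dat = 104L, models = list("ridge"),
                            seed = 3)
  expect_equal(nrow(sw), 2L * 5L * 1L)
  expect_equal(sw$dph, rep(104L - dats, 2))
  # more flights available cannot hurt a noiseless-ish linear response
  final <- sw[sw$scheme == "all_tps" & sw$cutoff_dat == 101L, ]
  first <- sw[sw$scheme == "all_tps" & sw$cutoff_dat == 12L, ]
  expect_gt(final$test_r2, first$test_r2)
})
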