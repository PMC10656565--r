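#' Coefficient of determination
#'
#' R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2).
#'
#' @param y Observed values (length >= 2, non-constant).
#' @param yhat Predicted values.
#' @return Scalar R^2 (<= 1; negative when worse than the mean).
#' @export
rSquared <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) < 2L)
    stop("y and yhat must have equal length >= 2")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("R^2 undefined for constant y")
  1 - sum((y - yhat)^2) / ss_tot
}

#' Root mean square error
#'
#' RMSE = sqrt(mean((y - yhat)^2)), reported in the units of y (g/plant for
#' harvest weights).
#'
#' @inheritParams rSquared
#' @return Scalar RMSE >= 0.
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) < 2L)
    stop("y and yhat must have equal length >= 2")
  sqrt(mean((y - yhat)^2))
}

#' Specify a regression model family and hyperparameter grid
#'
#' Families: "PLS" (partial least squares), "lasso", "ridge", "SVM-linear"
#' (epsilon-regression with a linear kernel) and "RF" (random forest).
#' Default grids: lasso/ridge penalty on a 13-point log grid 1e-3..1e3;
#' PLS components 1..min(20, p); SVM cost on a 7-point log grid 1e-2..1e2
#' with epsilon 0.1; RF with 500 trees, mtry in {ceil(p/3), ceil(sqrt(p))}
#' and min node size in {1, 5}.
#'
#' @param family One of "PLS", "lasso", "ridge", "SVM-linear", "RF".
#' @param grid Optional named list of hyperparameter value vectors.
#' @param seed Integer seed used for any stochastic fit (RF).
#' @return A ModelSpec (list with class "ModelSpec").
#' @export
modelSpec <- function(family = c("PLS", "lasso", "ridge", "SVM-linear", "RF"),
                      grid = NULL, seed = 1L) {
  family <- match.arg(family)
  structure(list(family = family, grid = grid, seed = as.integer(seed)),
            class = "ModelSpec")
}

resolveGrid <- function(spec, p, n) {
  g <- spec$grid
  if (is.null(g)) {
    g <- switch(spec$family,
      lasso = ,
      ridge = list(lambda = 10^seq(-3, 3, length.out = 13)),
      PLS = list(ncomp = seq_len(min(20L, p))),
      "SVM-linear" = list(cost = 10^seq(-2, 2, length.out = 7),
                          epsilon = 0.1),
      RF = list(mtry = unique(c(ceiling(p / 3), ceiling(sqrt(p)))),
                nodesize = c(1L, 5L)))
  }
  if (spec$family == "PLS" && !is.null(g$ncomp))
    g$ncomp <- g$ncomp[g$ncomp <= min(p, n - 1L)]
  if (spec$family == "RF" && !is.null(g$mtry))
    g$mtry <- unique(pmin(g$mtry, p))
  expand.grid(g, KEEP.OUT.ATTRS = FALSE)
}

fitModel <- function(spec, X, y, params) {
  X <- as.matrix(X)
  switch(spec$family,
    lasso = ,
    ridge = {
      alpha <- if (spec$family == "lasso") 1 else 0
      dup <- ncol(X) == 1L
      Xf <- if (dup) cbind(X, X) else X
      fit <- glmnet::glmnet(Xf, y, alpha = alpha,
                            lambda = params$lambda, standardize = FALSE)
      list(kind = spec$family, fit = fit, dup = dup)
    },
    PLS = {
      nc <- min(params$ncomp, ncol(X), nrow(X) - 1L)
      fit <- mixOmics::pls(X, y, ncomp = nc, mode = "regression")
      list(kind = "PLS", fit = fit, ncomp = nc)
    },
    "SVM-linear" = {
      fit <- e1071::svm(x = X, y = y, type = "eps-regression",
                        kernel = "linear", cost = params$cost,
                        epsilon = params$epsilon, scale = FALSE)
      list(kind = "SVM", fit = fit)
    },
    RF = {
      fit <- withr::with_seed(spec$seed,
        randomForest::randomForest(x = X, y = y, ntree = 500L,
                                   mtry = min(params$mtry, ncol(X)),
                                   nodesize = params$nodesize))
      list(kind = "RF", fit = fit)
    })
}

predictModel <- function(model, X) {
  X <- as.matrix(X)
  switch(model$kind,
    lasso = ,
    ridge = {
      Xf <- if (isTRUE(model$dup)) cbind(X, X) else X
      as.vector(stats::predict(model$fit, newx = Xf))
    },
    PLS = {
      pr <- stats::predict(model$fit, newdata = X)
      as.vector(pr$predict[, 1, model$ncomp])
    },
    SVM = as.vector(stats::predict(model$fit, X)),
    RF = as.vector(stats::predict(model$fit, X)))
}

#' Seeded k-fold assignment with near-equal fold sizes
#'
#' Rows are shuffled under the seed and dealt into k folds whose sizes
#' differ by at most one (the remainder goes to the first folds), e.g.
#' n = 756, k = 5 gives sizes 152, 151, 151, 151, 151.
#'
#' @param n Number of rows.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold labels 1..k per row.
#' @export
foldAssignments <- function(n, k = 5L, seed = 1L) {
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  ord <- withr::with_seed(seed, sample.int(n))
  f <- integer(n)
  f[ord] <- rep(seq_len(k), times = sizes)
  f
}

scaleTrainApply <- function(X_tr, X_ap) {
  ctr <- colMeans(X_tr)
  scl <- sqrt(colMeans(sweep(X_tr, 2, ctr)^2))
  keep <- which(scl > 0)  # constant-on-fold columns carry no signal
  if (length(keep) == 0L) stop("all feature columns are constant")
  list(tr = sweep(sweep(X_tr[, keep, drop = FALSE], 2, ctr[keep]), 2,
                  scl[keep], "/"),
       ap = sweep(sweep(X_ap[, keep, drop = FALSE], 2, ctr[keep]), 2,
                  scl[keep], "/"),
       center = ctr[keep], scale = scl[keep], keep = keep)
}

#' Tune and evaluate a model by k-fold cross-validation
#'
#' Per fold, features are standardized on the k-1 training folds and the
#' model is fitted there; R^2 and RMSE are measured on the held-out fold.
#' The grid search selects the hyperparameters maximizing mean CV R^2,
#' after which the model is refitted on all rows (standardized on all
#' rows) with the winning configuration.
#'
#' @param spec A [modelSpec()].
#' @param X Numeric feature matrix.
#' @param y Response (harvest weight, g).
#' @param k Number of folds (default 5).
#' @param seed Seed for the fold shuffle.
#' @param folds Optional precomputed fold labels (overrides k/seed), so one
#'   fold assignment can be shared across feature selection and assessment.
#' @return List of class "cvResult": `family`, `best_params`, `cv`
#'   (per-fold data.frame), `mean_cv_r2`, `mean_cv_rmse`, `fit`, `center`,
#'   `scale`, `n`, `features`.
#' @export
crossValidate <- function(spec, X, y, k = 5L, seed = 1L, folds = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < k) stop("need at least k rows")
  if (stats::var(y) == 0) stop("degenerate response: zero variance")
  if (is.null(folds)) folds <- foldAssignments(nrow(X), k, seed)
  grid <- resolveGrid(spec, ncol(X), min(tabulate(folds) * (k - 1)))
  kf <- sort(unique(folds))
  res <- array(NA_real_, c(nrow(grid), length(kf), 2))
  for (fi in seq_along(kf)) {
    te <- folds == kf[fi]
    sc <- scaleTrainApply(X[!te, , drop = FALSE], X[te, , drop = FALSE])
    for (gi in seq_len(nrow(grid))) {
      # a configuration that cannot be fitted (e.g. more latent components
      # than the design's rank) is scored out rather than aborting the search
      p <- tryCatch({
        m <- fitModel(spec, sc$tr, y[!te], grid[gi, , drop = FALSE])
        predictModel(m, sc$ap)
      }, error = function(e) NULL)
      if (is.null(p)) next
      res[gi, fi, 1] <- rSquared(y[te], p)
      res[gi, fi, 2] <- rmse(y[te], p)
    }
  }
  mean_r2 <- rowMeans(res[, , 1, drop = FALSE][, , 1])
  mean_r2[is.na(mean_r2)] <- -Inf
  if (all(mean_r2 == -Inf)) stop("no hyperparameter configuration could be fitted")
  best <- which.max(mean_r2)
  sc_all <- scaleTrainApply(X, X)
  fit <- fitModel(spec, sc_all$tr, y, grid[best, , drop = FALSE])
  structure(list(
    family = spec$family, best_params = grid[best, , drop = FALSE],
    cv = data.frame(fold = kf, r2 = res[best, , 1], rmse = res[best, , 2]),
    mean_cv_r2 = mean(res[best, , 1]), mean_cv_rmse = mean(res[best, , 2]),
    fit = fit, center = sc_all$center, scale = sc_all$scale,
    n = nrow(X), features = colnames(X)[sc_all$keep]), class = "cvResult")
}

#' Evaluate a cross-validated model on held-out data
#'
#' Held-out features are transformed with the training standardization
#' statistics stored in the result, never their own.
#'
#' @param cvres A "cvResult" from [crossValidate()].
#' @param X_test,y_test Held-out features and response.
#' @return List with `r2`, `rmse`, `predictions`, `n`.
#' @export
evaluateOnTest <- function(cvres, X_test, y_test) {
  X <- sweep(sweep(as.matrix(X_test)[, cvres$features, drop = FALSE], 2,
                   cvres$center), 2, cvres$scale, "/")
  p <- predictModel(cvres$fit, X)
  list(r2 = rSquared(y_test, p), rmse = rmse(y_test, p),
       predictions = p, n = length(y_test))
}

#' Random 90/10 train/test split
#'
#' Uniform draw without replacement; the test set gets
#' `floor(n * test_fraction)` rows (839 plants give 756 train / 83 test at
#' the default 10 percent).
#'
#' @param n Number of rows (or a [FeatureTable-class]).
#' @param test_fraction Fraction held out (default 0.10).
#' @param seed Integer seed.
#' @return List with integer `train` and `test` row indices.
#' @export
splitData <- function(n, test_fraction = 0.10, seed = 1L) {
  if (is(n, "FeatureTable")) n <- nrow(n@values)
  if (n < 10L) stop("need at least 10 rows to split")
  n_test <- floor(n * test_fraction)
  test <- sort(withr::with_seed(seed, sample.int(n, n_test)))
  list(train = setdiff(seq_len(n), test), test = test)
}

cvScore <- function(spec, X, y, folds) {
  X <- as.matrix(X)
  grid <- resolveGrid(spec, ncol(X), nrow(X))
  kf <- sort(unique(folds))
  r2 <- matrix(NA_real_, nrow(grid), length(kf))
  for (fi in seq_along(kf)) {
    te <- folds == kf[fi]
    sc <- scaleTrainApply(X[!te, , drop = FALSE], X[te, , drop = FALSE])
    for (gi in seq_len(nrow(grid))) {
      p <- tryCatch({
        m <- fitModel(spec, sc$tr, y[!te], grid[gi, , drop = FALSE])
        predictModel(m, sc$ap)
      }, error = function(e) NULL)
      if (!is.null(p)) r2[gi, fi] <- rSquared(y[te], p)
    }
  }
  max(rowMeans(r2), na.rm = TRUE)
}

#' Exhaustive (best-subset) feature search
#'
#' Every non-empty feature subset up to `max_set_size` is scored by its
#' mean five-fold cross-validated R^2 under the estimator (lasso by
#' default, with a small penalty grid); the best subset per cardinality is
#' returned. Refuses more than 15 candidate features.
#'
#' @param X Feature matrix with column names.
#' @param y Response.
#' @param estimator A [modelSpec()]; default lasso with lambda {0.01, 0.1}.
#' @param max_set_size Largest subset size scored (default all).
#' @param k,seed Fold count and seed for the shared fold assignment.
#' @return data.frame(size, features, score) with one row per cardinality,
#'   plus attribute `best` (the overall best subset as a character vector).
#' @export
exhaustiveSelection <- function(X, y, estimator = NULL,
                                max_set_size = ncol(X), k = 5L, seed = 1L) {
  p <- ncol(X)
  if (p > 15L)
    stop("too many features for exhaustive search (p > 15); use sfsForward")
  if (is.null(estimator))
    estimator <- modelSpec("lasso", grid = list(lambda = c(0.01, 0.1)))
  folds <- foldAssignments(nrow(X), k, seed)
  nms <- colnames(X)
  best <- vector("list", min(max_set_size, p))
  for (size in seq_len(min(max_set_size, p))) {
    subsets <- utils::combn(p, size, simplify = FALSE)
    scores <- vapply(subsets, function(ii)
      cvScore(estimator, X[, ii, drop = FALSE], y, folds), numeric(1))
    bi <- which.max(scores)
    best[[size]] <- data.frame(size = size,
                               features = paste(nms[subsets[[bi]]],
                                                collapse = ","),
                               score = scores[bi])
  }
  out <- do.call(rbind, best)
  attr(out, "best") <- strsplit(out$features[which.max(out$score)], ",")[[1]]
  out
}

#' Sequential forward feature selection
#'
#' Greedy forward search: at each step the candidate whose addition
#' maximizes mean cross-validated R^2 is appended, so the selection path
#' has the prefix property.
#'
#' @inheritParams exhaustiveSelection
#' @param n_select Number of features to select.
#' @return data.frame(step, feature, score); `path` attribute gives the
#'   selected features in order.
#' @export
sfsForward <- function(X, y, estimator = NULL, n_select = ncol(X),
                       k = 5L, seed = 1L) {
  if (is.null(estimator))
    estimator <- modelSpec("lasso", grid = list(lambda = c(0.01, 0.1)))
  stopifnot(n_select <= ncol(X))
  folds <- foldAssignments(nrow(X), k, seed)
  nms <- colnames(X)
  sel <- integer(0)
  rows <- list()
  for (step in seq_len(n_select)) {
    cand <- setdiff(seq_along(nms), sel)
    scores <- vapply(cand, function(j)
      cvScore(estimator, X[, c(sel, j), drop = FALSE], y, folds),
      numeric(1))
    j <- cand[which.max(scores)]
    sel <- c(sel, j)
    rows[[step]] <- data.frame(step = step, feature = nms[j],
                               score = max(scores))
  }
  out <- do.call(rbind, rows)
  attr(out, "path") <- nms[sel]
  out
}

#' Random-forest feature importance (mean decrease in impurity)
#'
#' A random-forest regressor is fitted on all rows and features are ranked
#' by their total impurity decrease, normalized to sum to one.
#'
#' @param X Feature matrix with column names.
#' @param y Response.
#' @param seed Integer seed.
#' @param ntree Number of trees (default 500).
#' @return data.frame(feature, mdi) sorted by decreasing importance.
#' @export
rfImportance <- function(X, y, seed = 1L, ntree = 500L) {
  fit <- withr::with_seed(seed,
    randomForest::randomForest(x = as.matrix(X), y = y, ntree = ntree))
  imp <- fit$importance[, "IncNodePurity"]
  imp <- imp / sum(imp)
  out <- data.frame(feature = names(imp), mdi = unname(imp))
  out[order(-out$mdi), , drop = FALSE]
}

#' Define a temporal scheme
#'
#' Temporal resolutions: `all_tps` (every flight), `interval_7d` /
#' `interval_15d` / `interval_30d` (greedy fixed-interval walks over the
#' flight calendar) and `growth_pattern` (the growth-stage anchors 12, 34,
#' 56, 80 and 101 DAT). `mode` selects whether a design uses only the time
#' point at the cutoff (`single_tp`) or the whole sequence from the first
#' flight up to the cutoff (`cumulative`).
#'
#' @param name Scheme name.
#' @param mode "cumulative" or "single_tp".
#' @param cutoff_dat Optional last DAT allowed (for prior-to-harvest
#'   sweeps); NULL means no truncation.
#' @return A TemporalScheme (list with class "TemporalScheme").
#' @export
temporalScheme <- function(name = c("all_tps", "interval_7d", "interval_15d",
                                    "interval_30d", "growth_pattern"),
                           mode = c("cumulative", "single_tp"),
                           cutoff_dat = NULL) {
  structure(list(name = match.arg(name), mode = match.arg(mode),
                 cutoff_dat = cutoff_dat), class = "TemporalScheme")
}

growthPatternAnchors <- function() c(12L, 34L, 56L, 80L, 101L)

#' Select the time points of a temporal scheme
#'
#' `all_tps` keeps every DAT; `interval_Nd` walks greedily from the first
#' DAT, at each step taking the earliest flight at least N days after the
#' previously selected one; `growth_pattern` takes, for each growth-stage
#' anchor, the nearest available flight (ties to the earlier one). The
#' result is truncated at the scheme's `cutoff_dat`.
#'
#' @param tp_dat Sorted integer DATs of the available flights.
#' @param scheme A [temporalScheme()] (or scheme name).
#' @return Integer vector of selected DATs.
#' @export
selectTimepoints <- function(tp_dat, scheme) {
  if (is.character(scheme)) scheme <- temporalScheme(scheme)
  stopifnot(!is.unsorted(tp_dat))
  sel <- switch(scheme$name,
    all_tps = tp_dat,
    growth_pattern = sort(unique(vapply(growthPatternAnchors(), function(a)
      tp_dat[which.min(abs(tp_dat - a))], numeric(1)))),
    {
      step <- as.integer(sub("^interval_([0-9]+)d$", "\\1", scheme$name))
      sel <- tp_dat[1]
      repeat {
        nxt <- tp_dat[tp_dat >= sel[length(sel)] + step]
        if (length(nxt) == 0L) break
        sel <- c(sel, nxt[1])
      }
      sel
    })
  if (!is.null(scheme$cutoff_dat)) sel <- sel[sel <= scheme$cutoff_dat]
  if (length(sel) == 0L) stop("no time points remain after the cutoff")
  as.integer(sel)
}

#' Build a design matrix for a temporal scheme
#'
#' Cumulative mode concatenates the feature columns of every selected time
#' point up to the cutoff; single-TP mode uses only the last selected time
#' point. Rows with any missing cell are dropped (with a message).
#'
#' @param table A [FeatureTable-class].
#' @param scheme A [temporalScheme()].
#' @param features Optional subset of base feature names (default all).
#' @return List with `X`, `y`, `tp_used`, `rows` (indices into the table).
#' @export
buildDesign <- function(table, scheme, features = NULL) {
  tps <- selectTimepoints(table@tp_dat, scheme)
  if (scheme$mode == "single_tp") tps <- max(tps)
  if (is.null(features)) features <- table@feature_names
  cols <- as.vector(outer(features, tps, function(f, d) paste0(f, "@", d)))
  cols <- intersect(cols, colnames(table@values))
  if (length(cols) == 0L) stop("selected time points absent from the table")
  X <- table@values[, cols, drop = FALSE]
  allna <- colSums(!is.na(X)) == 0L
  if (any(allna)) {
    message(sum(allna), " all-missing column(s) dropped: ",
            paste(utils::head(colnames(X)[allna], 3L), collapse = ", "),
            if (sum(allna) > 3L) ", ..." else "")
    X <- X[, !allna, drop = FALSE]
  }
  ok <- stats::complete.cases(X) & !is.na(table@weights)
  if (!any(ok)) stop("no rows survive missing-value filtering")
  if (any(!ok)) message(sum(!ok), " row(s) dropped for missing cells")
  list(X = X[ok, , drop = FALSE], y = table@weights[ok], tp_used = tps,
       rows = which(ok))
}

#' Days-prior-to-harvest prediction sweep
#'
#' For each temporal scheme and each available cutoff DAT, builds the
#' cumulative design from the first flight up to the cutoff, tunes every
#' model by k-fold cross-validation on the training rows and evaluates it
#' on the held-out test rows; days prior to harvest = harvest DAT - cutoff.
#'
#' @param table A standardizable [FeatureTable-class] (raw feature values;
#'   standardization happens inside the CV and at refit).
#' @param schemes Character vector of scheme names (or list of
#'   [temporalScheme()]).
#' @param harvest_dat Harvest day (DAT), >= the largest cutoff.
#' @param models List of [modelSpec()] objects (or family names).
#' @param split A [splitData()] result; made from the table when NULL.
#' @param features Optional base-feature subset.
#' @param k,seed Fold count and seed.
#' @return Tidy data.frame(scheme, mode, cutoff_dat, dph, model,
#'   mean_cv_r2, mean_cv_rmse, test_r2, test_rmse, n_train, n_test).
#' @export
priorToHarvestSweep <- function(table, schemes, harvest_dat, models,
                                split = NULL, features = NULL, k = 5L,
                                seed = 1L) {
  if (is.null(split)) split <- splitData(nrow(table@values), seed = seed)
  models <- lapply(models, function(m)
    if (is.character(m)) modelSpec(m, seed = seed) else m)
  rows <- list()
  for (sc in schemes) {
    if (is.character(sc)) sc <- temporalScheme(sc)
    cutoffs <- selectTimepoints(table@tp_dat, temporalScheme(sc$name))
    if (any(cutoffs > harvest_dat)) stop("harvest_dat before a cutoff")
    for (cut in cutoffs) {
      des <- buildDesign(table,
                         temporalScheme(sc$name, "cumulative", cutoff_dat = cut),
                         features = features)
      tr <- des$rows %in% split$train
      if (sum(tr) < k || sum(!tr) < 2L) next
      for (m in models) {
        cvres <- crossValidate(m, des$X[tr, , drop = FALSE], des$y[tr],
                               k = k, seed = seed)
        te <- evaluateOnTest(cvres, des$X[!tr, , drop = FALSE], des$y[!tr])
        rows[[length(rows) + 1L]] <- data.frame(
          scheme = sc$name, mode = "cumulative", cutoff_dat = cut,
          dph = harvest_dat - cut, model = m$family,
          mean_cv_r2 = cvres$mean_cv_r2, mean_cv_rmse = cvres$mean_cv_rmse,
          test_r2 = te$r2, test_rmse = te$rmse,
          n_train = sum(tr), n_test = sum(!tr))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
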