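#' Vegetation-index registry
#'
#' The eleven camera-variant vegetation indices: GRVI, MGRVI and RGBVI exist
#' in both an RGB-camera variant (channels R, G, B) and an MS variant (bands
#' blue, green, red), while GNDVI, NDRE, NDVI, RECI and SAVI require the MS
#' red-edge/NIR bands. Registry order (RGB variant before MS variant, then
#' the MS-only indices) is frozen because the greedy correlation pruning in
#' [pruneCorrelatedVIs()] depends on it.
#'
#' @return data.frame(name, camera, inputs) in frozen order.
#' @export
viRegistry <- function() {
  data.frame(
    name = c("GRVI-RGB", "GRVI-MS", "MGRVI-RGB", "MGRVI-MS",
             "RGBVI-RGB", "RGBVI-MS", "GNDVI", "NDRE", "NDVI", "RECI",
             "SAVI"),
    camera = c("RGB", "MS", "RGB", "MS", "RGB", "MS",
               "MS", "MS", "MS", "MS", "MS"),
    inputs = c("G,R", "green,red", "G,R", "green,red", "B,G,R",
               "blue,green,red", "NIR,green", "NIR,red_edge", "NIR,red",
               "NIR,red_edge", "NIR,red"),
    stringsAsFactors = FALSE)
}

viFormula <- function(name, get) {
  switch(name,
    "GRVI-RGB"  = (get("G") - get("R")) / (get("G") + get("R")),
    "GRVI-MS"   = (get("green") - get("red")) / (get("green") + get("red")),
    "MGRVI-RGB" = (get("G")^2 - get("R")^2) / (get("G")^2 + get("R")^2),
    "MGRVI-MS"  = (get("green")^2 - get("red")^2) /
                  (get("green")^2 + get("red")^2),
    "RGBVI-RGB" = (get("G")^2 - get("B") * get("R")) /
                  (get("G")^2 + get("B") * get("R")),
    "RGBVI-MS"  = (get("green")^2 - get("blue") * get("red")) /
                  (get("green")^2 + get("blue") * get("red")),
    "GNDVI"     = (get("NIR") - get("green")) / (get("NIR") + get("green")),
    "NDRE"      = (get("NIR") - get("red_edge")) /
                  (get("NIR") + get("red_edge")),
    "NDVI"      = (get("NIR") - get("red")) / (get("NIR") + get("red")),
    "RECI"      = get("NIR") / get("red_edge") - 1,
    "SAVI"      = (get("NIR") - get("red")) /
                  (get("NIR") + get("red") + 0.5) * 1.5,
    stop("unknown vegetation index: ", name))
}

#' Compute a vegetation index for every time point of a stack
#'
#' Elementwise evaluation of the registry formula on the stack's layers;
#' cells whose denominator is exactly zero become NA. RGB-variant indices
#' use the RGB-camera channels (R, G, B), MS variants the multispectral
#' bands.
#'
#' @param stack A [PlantImageStack-class] (or a named list of matrices for a
#'   single time point).
#' @param name Registry name, e.g. "NDVI" or "GRVI-RGB".
#' @return A (tp, row, col) array (or a matrix for single-TP list input).
#' @export
computeVI <- function(stack, name) {
  if (!name %in% viRegistry()$name) stop("unknown vegetation index: ", name)
  one <- function(layers) {
    get <- function(nm) {
      if (is.null(layers[[nm]])) stop("missing layer '", nm, "' for ", name)
      layers[[nm]]
    }
    old <- options(warn = -1); on.exit(options(old))
    v <- viFormula(name, get)
    v[!is.finite(v)] <- NA_real_
    v
  }
  if (is.list(stack)) return(one(stack))
  d <- dim(stack@values)
  out <- array(NA_real_, d[c(1, 3, 4)])
  for (t in seq_len(d[1])) {
    layers <- stats::setNames(
      lapply(seq_len(d[2]), function(l) stack@values[t, l, , ]),
      stack@layer_names)
    out[t, , ] <- one(layers)
  }
  out
}

#' Drop highly correlated vegetation indices
#'
#' Greedy pass in the frozen registry order (or the column order given): a
#' VI is dropped when its absolute Pearson correlation with any
#' already-retained VI exceeds `r_threshold`. Constant columns have
#' undefined correlations; they are retained and flagged.
#'
#' @param vi_table Numeric plants x VI matrix with VI column names.
#' @param r_threshold Absolute-correlation threshold (default 0.95).
#' @return Character vector of retained VI names in order, with a
#'   `flagged` attribute naming any constant columns.
#' @export
pruneCorrelatedVIs <- function(vi_table, r_threshold = 0.95) {
  if (nrow(vi_table) < 2L) stop("need at least two plants to correlate")
  ord <- intersect(viRegistry()$name, colnames(vi_table))
  if (length(ord) == 0L) ord <- colnames(vi_table)
  ord <- c(ord, setdiff(colnames(vi_table), ord))
  retained <- character(0)
  flagged <- character(0)
  for (nm in ord) {
    x <- vi_table[, nm]
    if (stats::sd(x, na.rm = TRUE) == 0 || all(is.na(x))) {
      retained <- c(retained, nm)
      flagged <- c(flagged, nm)
      next
    }
    drop <- FALSE
    for (r in setdiff(retained, flagged)) {
      rv <- suppressWarnings(
        stats::cor(x, vi_table[, r], use = "pairwise.complete.obs"))
      if (is.finite(rv) && abs(rv) > r_threshold) { drop <- TRUE; break }
    }
    if (!drop) retained <- c(retained, nm)
  }
  attr(retained, "flagged") <- flagged
  retained
}

#' Soil mask from 2-cluster k-means on per-pixel VI vectors
#'
#' Pixels are clustered (k = 2, 10 restarts under a fixed seed) in the
#' space of the supplied vegetation indices; the cluster with the lower
#' mean NDVI is labelled soil, so the decision does not depend on cluster
#' numbering. The returned mask is TRUE on vegetation.
#'
#' @param vi_layers Named list (or vi x row x col array with dimnames) of VI
#'   matrices for one plant window; must include "NDVI".
#' @param seed Integer seed for the restarts.
#' @return Logical matrix, TRUE = vegetation; pixels with any NA VI are
#'   FALSE. Attribute `provenance` = "kmeans".
#' @export
soilMaskKmeans <- function(vi_layers, seed = 1L) {
  if (is.array(vi_layers) && length(dim(vi_layers)) == 3L) {
    nms <- dimnames(vi_layers)[[1]]
    vi_layers <- stats::setNames(
      lapply(seq_len(dim(vi_layers)[1]), function(i) vi_layers[i, , ]), nms)
  }
  if (!"NDVI" %in% names(vi_layers))
    stop("vi_layers must include an NDVI layer for the soil rule")
  shape <- dim(vi_layers[[1]])
  X <- do.call(cbind, lapply(vi_layers, as.vector))
  ok <- stats::complete.cases(X)
  Xo <- X[ok, , drop = FALSE]
  uq <- unique(Xo)
  if (nrow(uq) < 2L) stop("all pixels identical: cannot separate soil")
  cl <- if (nrow(uq) == 2L) {
    # exactly two distinct pixel vectors: clustering is assignment
    d1 <- rowSums(sweep(Xo, 2, uq[1, ])^2)
    d2 <- rowSums(sweep(Xo, 2, uq[2, ])^2)
    ifelse(d2 < d1, 2L, 1L)
  } else {
    km <- withr::with_seed(seed, tryCatch(
      suppressWarnings(stats::kmeans(Xo, centers = 2L, nstart = 10L,
                                     iter.max = 100L,
                                     algorithm = "Lloyd")),
      error = function(e) {
        ctr <- uq[c(1L, which.max(rowSums(sweep(uq, 2, uq[1, ])^2))), ,
                  drop = FALSE]
        stats::kmeans(Xo, centers = ctr, iter.max = 50L)
      }))
    km$cluster
  }
  ndvi <- X[ok, which(names(vi_layers) == "NDVI")[1]]
  soil_cluster <- which.min(c(mean(ndvi[cl == 1L]), mean(ndvi[cl == 2L])))
  veg <- rep(FALSE, nrow(X))
  veg[ok] <- cl != soil_cluster
  m <- matrix(veg, shape[1], shape[2])
  attr(m, "provenance") <- "kmeans"
  m
}

# 8-connected component labels by iterative minimum-label propagation
labelComponents <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[mask] <- seq_len(sum(mask))
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  repeat {
    nl <- lab
    for (s in shifts) {
      cand <- translateMatrix(lab, s[1], s[2], fill = 0L)
      take <- mask & cand > 0L & cand < nl
      nl[take] <- cand[take]
    }
    if (identical(nl, lab)) break
    lab <- nl
  }
  lab[mask] <- match(lab[mask], sort(unique(lab[mask])))
  lab
}

#' Remove small contours from a vegetation mask
#'
#' 8-connected components of the TRUE region whose area is below
#' `min_area_fraction` of the largest component are removed; an empty mask
#' passes through unchanged.
#'
#' @param mask Logical matrix (TRUE = vegetation).
#' @param min_area_fraction Relative area threshold (default 0.05).
#' @return Filtered logical matrix; `provenance` attribute extended with
#'   "contour".
#' @export
contourFilter <- function(mask, min_area_fraction = 0.05) {
  prov <- c(attr(mask, "provenance"), "contour")
  if (!any(mask)) { attr(mask, "provenance") <- prov; return(mask) }
  lab <- labelComponents(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_area_fraction * max(sizes))
  out <- matrix(lab %in% keep & mask, nrow(mask), ncol(mask))
  attr(out, "provenance") <- prov
  out
}

#' Histogram-equalize RGB layers
#'
#' Standard 256-level histogram equalization applied independently per
#' layer: values are binned to levels 0..255 and remapped to
#' `round(255 * cdf(v))`, where the empirical cdf runs from the first
#' occupied level's mass to 1. Inputs in [0, 1] are scaled to the 0..255
#' range first; NA cells are ignored and preserved.
#'
#' @param rgb_layers Named list of numeric matrices (R, G, B), values in
#'   [0, 1] or already on 0..255.
#' @return List of equalized matrices on the 0..255 integer scale.
#' @export
equalizeRGB <- function(rgb_layers) {
  lapply(rgb_layers, function(v) {
    ok <- !is.na(v)
    if (!any(ok)) return(v)
    x <- v
    if (max(x[ok]) <= 1) x <- x * 255
    lev <- pmin(pmax(round(x), 0), 255)
    h <- tabulate(lev[ok] + 1L, nbins = 256L)
    cdf <- cumsum(h) / sum(h)
    out <- v
    out[ok] <- round(255 * cdf[lev[ok] + 1L])
    out
  })
}

#' Center a plant stack on its first-flight convex hull and crop
#'
#' The convex hull of the first-time-point vegetation pixels is computed;
#' its geometric centre is the mean of the hull vertices. Every layer of
#' every time point (and the masks) is translated by the integer pixel
#' shift that puts this centre on the window centre (vacated cells NA /
#' FALSE), and a centred window of `crop_fraction` of each dimension is
#' retained.
#'
#' @param stack A [PlantImageStack-class].
#' @param first_tp_mask Logical matrix: first-TP vegetation pixels.
#' @param crop_fraction Fraction of each dimension retained (default 0.70).
#' @return The centred, cropped [PlantImageStack-class]; attribute `shift`
#'   records the applied `c(dx, dy)`.
#' @export
centerAndCrop <- function(stack, first_tp_mask, crop_fraction = 0.70) {
  if (!any(first_tp_mask)) stop("first-TP mask is empty")
  idx <- which(first_tp_mask, arr.ind = TRUE)
  pts <- cbind(x = idx[, 2], y = idx[, 1])
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  ctr <- colMeans(hull)
  d <- dim(stack@values)
  wc <- c(x = (d[4] + 1) / 2, y = (d[3] + 1) / 2)
  dx <- round(wc["x"] - ctr["x"]); dy <- round(wc["y"] - ctr["y"])
  keep_r <- cropIndices(d[3], crop_fraction)
  keep_c <- cropIndices(d[4], crop_fraction)
  a <- array(NA_real_, c(d[1], d[2], length(keep_r), length(keep_c)))
  m <- array(FALSE, c(d[1], length(keep_r), length(keep_c)))
  for (t in seq_len(d[1])) {
    for (l in seq_len(d[2])) {
      sh <- translateMatrix(stack@values[t, l, , ], dy, dx)
      a[t, l, , ] <- sh[keep_r, keep_c]
    }
    shm <- translateMatrix(stack@mask[t, , ], dy, dx, fill = FALSE)
    m[t, , ] <- shm[keep_r, keep_c]
  }
  out <- new("PlantImageStack", values = a, tp_dat = stack@tp_dat,
             layer_names = stack@layer_names, mask = m,
             pixel_area_cm2 = stack@pixel_area_cm2)
  attr(out, "shift") <- c(dx = unname(dx), dy = unname(dy))
  out
}

cropIndices <- function(n, fraction) {
  keep <- floor(n * fraction)
  start <- floor((n - keep) / 2)
  seq.int(start + 1L, start + keep)
}
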