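#' Median of a layer over the vegetation mask
#'
#' Median over unmasked, non-missing cells; even counts average the two
#' central values. A fully masked layer yields NA.
#'
#' @param layer Numeric matrix.
#' @param mask Logical matrix, TRUE = include.
#' @return Scalar median or NA.
#' @export
layerMedian <- function(layer, mask = NULL) {
  v <- if (is.null(mask)) as.vector(layer) else layer[mask]
  v <- v[!is.na(v)]
  if (length(v) == 0L) return(NA_real_)
  stats::median(v)
}

#' Plant height: 90th percentile of the canopy-height image
#'
#' Linear interpolation between order statistics (quantile type 7) over the
#' unmasked cells.
#'
#' @inheritParams layerMedian
#' @param height_image Canopy-height matrix (m).
#' @return Scalar (same units as input) or NA if fully masked.
#' @export
plantHeightFeature <- function(height_image, mask = NULL) {
  v <- if (is.null(mask)) as.vector(height_image) else height_image[mask]
  v <- v[!is.na(v)]
  if (length(v) == 0L) return(NA_real_)
  unname(stats::quantile(v, 0.9, type = 7))
}

#' Aggregate leaf angle of a canopy-height image
#'
#' For each unmasked pixel p with canopy height H_p > 0, the pixel vector
#' P_p = (x_p - x_c, y_p - y_c, H_p) is formed in metres relative to the
#' window centre on the ground plane, and its angle to the unit vertical
#' V_c = (0, 0, 1) is arccos(P_p . V_c / ||P_p||). The aggregate is the
#' median of the per-pixel angles in degrees; a zero-length centre vector is
#' excluded.
#'
#' @param height_image Canopy-height matrix in metres.
#' @param mask Logical matrix (TRUE = vegetation) or NULL.
#' @param gsd_m Pixel size in metres (isotropic).
#' @param center Optional `c(col, row)` centre in pixel units; defaults to
#'   the window centre.
#' @return Median angle in degrees, in [0, 90], or NA.
#' @export
leafAngle <- function(height_image, mask = NULL, gsd_m, center = NULL) {
  d <- dim(height_image)
  if (is.null(center)) center <- c((d[2] + 1) / 2, (d[1] + 1) / 2)
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  idx <- which(mask & !is.na(height_image) & height_image > 0,
               arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NA_real_)
  dx <- (idx[, 2] - center[1]) * gsd_m
  dy <- (idx[, 1] - center[2]) * gsd_m
  h <- height_image[idx]
  nrm <- sqrt(dx^2 + dy^2 + h^2)
  keep <- nrm > 0
  if (!any(keep)) return(NA_real_)
  ang <- acos(pmin(pmax(h[keep] / nrm[keep], -1), 1)) * 180 / pi
  stats::median(ang)
}

#' Canopy volume from a height image
#'
#' Sum of the unmasked pixel canopy heights (converted from metres to cm)
#' multiplied by the pixel ground area in cm^2, giving cm^3.
#'
#' @param height_image Canopy-height matrix in metres.
#' @param mask Logical matrix or NULL.
#' @param pixel_area_cm2 Ground area of one pixel (cm^2).
#' @return Volume in cm^3 (>= 0 for non-negative heights).
#' @export
plantVolume <- function(height_image, mask = NULL, pixel_area_cm2) {
  if (pixel_area_cm2 <= 0) stop("pixel_area_cm2 must be > 0")
  v <- if (is.null(mask)) as.vector(height_image) else height_image[mask]
  v <- v[!is.na(v)]
  sum(v * 100) * pixel_area_cm2
}

#' Summarize one processed plant stack into per-TP features
#'
#' Level 1: medians of the RGB and MS layers over the vegetation mask (RGB
#' after histogram equalization, exactly in the filter-cascade order).
#' Level 2: medians of the vegetation indices. Level 3: 90th-percentile
#' plant height, leaf angle and volume from the canopy-height layer.
#'
#' @param stack A centred/cropped [PlantImageStack-class] whose mask slot
#'   holds the per-TP vegetation masks and which contains the layers
#'   R, G, B, blue, green, red, red_edge, NIR, height.
#' @param vi_names Character vector of VI names to summarize (default: the
#'   full registry).
#' @param gsd_m Pixel size (m) for the leaf-angle geometry.
#' @return data.frame(tp_dat, feature, value) in long form.
#' @export
featurizeStack <- function(stack, vi_names = viRegistry()$name, gsd_m) {
  d <- dim(stack@values)
  rows <- list()
  for (t in seq_len(d[1])) {
    msk <- stack@mask[t, , ]
    layers <- stats::setNames(
      lapply(seq_len(d[2]), function(l) stack@values[t, l, , ]),
      stack@layer_names)
    eq <- equalizeRGB(layers[c("R", "G", "B")])
    med <- c(vapply(eq, layerMedian, numeric(1), mask = msk),
             vapply(layers[c("blue", "green", "red", "red_edge", "NIR")],
                    layerMedian, numeric(1), mask = msk))
    vi <- vapply(vi_names, function(nm)
      layerMedian(computeVI(layers, nm), mask = msk), numeric(1))
    h <- layers[["height"]]
    ph <- plantHeightFeature(h, msk)
    ang <- leafAngle(h, msk, gsd_m = gsd_m)
    vol <- plantVolume(h, msk, stack@pixel_area_cm2)
    rows[[t]] <- data.frame(
      tp_dat = stack@tp_dat[t],
      feature = c(names(med), vi_names, "PH", "leaf_angle", "volume"),
      value = unname(c(med, vi, ph, ang, vol)))
  }
  do.call(rbind, rows)
}

#' Assemble the plants x (TP x feature) table
#'
#' Plants lacking a merged box contribute no rows and are excluded; a weight
#' recorded for a plant with no features is dropped with a message.
#'
#' @param feature_list Named list (names = plant ids) of long-form feature
#'   data.frames from [featurizeStack()].
#' @param weights Named numeric vector of harvest weights (g) keyed by
#'   plant id, or a data.frame(plant_id, weight_g).
#' @param features Optional subset of feature names to keep (e.g. the 8
#'   layer medians + retained VIs + PH/leaf_angle/volume).
#' @return A [FeatureTable-class] with columns `{feature}@{DAT}`.
#' @export
assembleFeatureTable <- function(feature_list, weights, features = NULL) {
  if (is.data.frame(weights))
    weights <- stats::setNames(weights$weight_g, weights$plant_id)
  ids <- names(feature_list)
  orphan <- setdiff(names(weights), ids)
  if (length(orphan))
    message(length(orphan), " weighed plant(s) without features dropped")
  long <- do.call(rbind, Map(function(df, id)
    cbind(plant_id = id, df), feature_list, ids))
  if (!is.null(features)) long <- long[long$feature %in% features, ]
  long$colname <- paste0(long$feature, "@", long$tp_dat)
  dats <- sort(unique(long$tp_dat))
  feats <- unique(long$feature)
  cols <- as.vector(outer(feats, dats, function(f, d) paste0(f, "@", d)))
  m <- matrix(NA_real_, length(ids), length(cols),
              dimnames = list(ids, cols))
  m[cbind(match(long$plant_id, ids), match(long$colname, cols))] <- long$value
  featureTable(m, weights = unname(weights[ids]),
               feature_names = feats, tp_dat = dats)
}

#' Standardize a feature table on training rows
#'
#' Per column, subtracts the mean and divides by the population standard
#' deviation (divisor n) computed on `fit_rows` only; the statistics are
#' stored in the returned object so held-out rows are transformed with the
#' training statistics, never their own.
#'
#' @param table A [FeatureTable-class].
#' @param fit_rows Row indices (or logical) defining the fitting set;
#'   default all rows.
#' @return The standardized [FeatureTable-class].
#' @export
standardizeFeatures <- function(table, fit_rows = seq_len(nrow(table@values))) {
  X <- table@values
  fit <- X[fit_rows, , drop = FALSE]
  ctr <- colMeans(fit, na.rm = TRUE)
  scl <- sqrt(colMeans(sweep(fit, 2, ctr)^2, na.rm = TRUE))
  bad <- which(!is.na(scl) & scl == 0)
  if (length(bad))
    stop("zero-variance column(s) on fit rows: ",
         paste(colnames(X)[bad], collapse = ", "))
  out <- table
  out@values <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  out@scale_center <- ctr
  out@scale_scale <- scl
  out
}
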