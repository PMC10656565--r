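#' @import methods
NULL

#' GeoTransform: affine georeferencing of a north-up raster
#'
#' Maps 0-based, half-open pixel coordinates to projected metric coordinates:
#' x = origin_x + col * gsd_x and y = origin_y - row * gsd_y, with rows
#' counted southward from the raster's upper-left corner.
#'
#' @slot origin_x,origin_y Projected coordinates (m) of the upper-left corner.
#' @slot gsd_x,gsd_y Pixel size (m); both strictly positive, gsd_y applied
#'   southward.
#' @export
setClass("GeoTransform",
  representation(origin_x = "numeric", origin_y = "numeric",
                 gsd_x = "numeric", gsd_y = "numeric"),
  validity = function(object) {
    if (length(object@gsd_x) != 1L || length(object@gsd_y) != 1L ||
        !is.finite(object@gsd_x) || !is.finite(object@gsd_y))
      return("gsd_x and gsd_y must be finite scalars")
    if (object@gsd_x <= 0 || object@gsd_y <= 0)
      return("gsd_x and gsd_y must be > 0")
    TRUE
  })

#' Construct a GeoTransform
#'
#' @param origin_x,origin_y Upper-left corner in projected coordinates (m).
#' @param gsd_x,gsd_y Pixel size in metres (gsd_y applied southward).
#' @return A [GeoTransform-class] object.
#' @examples
#' geoTransform(1000, 2000, 0.01, 0.01)
#' @export
geoTransform <- function(origin_x, origin_y, gsd_x, gsd_y = gsd_x) {
  new("GeoTransform", origin_x = as.numeric(origin_x),
      origin_y = as.numeric(origin_y),
      gsd_x = as.numeric(gsd_x), gsd_y = as.numeric(gsd_y))
}

setMethod("show", "GeoTransform", function(object) {
  cat(sprintf("GeoTransform: origin (%.6g, %.6g), gsd (%.6g, %.6g) m\n",
              object@origin_x, object@origin_y, object@gsd_x, object@gsd_y))
})

#' RasterLayer: one named 2-D raster with georeferencing
#'
#' @slot values Numeric matrix (rows southward, cols eastward); NA marks
#'   missing cells.
#' @slot gt A [GeoTransform-class].
#' @slot name Layer label, e.g. "NIR", "red", "R", "height".
#' @export
setClass("RasterLayer",
  representation(values = "matrix", gt = "GeoTransform", name = "character"),
  validity = function(object) {
    if (!is.numeric(object@values)) return("values must be a numeric matrix")
    v <- object@values
    if (any(!is.na(v) & !is.finite(v)))
      return("values must be finite or NA")
    TRUE
  })

#' Construct a RasterLayer
#' @param values Numeric matrix; NA marks missing cells.
#' @param gt A [GeoTransform-class].
#' @param name Layer label.
#' @return A [RasterLayer-class].
#' @export
rasterLayer <- function(values, gt, name = "layer") {
  new("RasterLayer", values = values, gt = gt, name = as.character(name)[1])
}

setMethod("show", "RasterLayer", function(object) {
  cat(sprintf("RasterLayer '%s': %d x %d px, gsd (%.4g, %.4g) m, %d NA\n",
              object@name, nrow(object@values), ncol(object@values),
              object@gt@gsd_x, object@gt@gsd_y, sum(is.na(object@values))))
})

#' @describeIn RasterLayer-class raster values matrix
#' @param x A RasterLayer.
#' @export
rasterValues <- function(x) x@values

#' @describeIn RasterLayer-class the layer's GeoTransform
#' @export
rasterGeoTransform <- function(x) x@gt

#' PlantImageStack: 4-D per-plant image stack
#'
#' Per-plant multi-temporal imagery ordered (time point, layer, row, col),
#' together with a per-time-point validity/vegetation mask and the pixel
#' footprint used for volume integration.
#'
#' @slot values 4-D numeric array, dimensions (tp, layer, row, col).
#' @slot tp_dat Integer days-after-transplanting, strictly increasing.
#' @slot layer_names Character labels of the layer dimension.
#' @slot mask Logical 3-D array (tp, row, col); TRUE marks vegetation/valid.
#' @slot pixel_area_cm2 Ground area of one pixel in cm^2.
#' @export
setClass("PlantImageStack",
  representation(values = "array", tp_dat = "integer",
                 layer_names = "character", mask = "array",
                 pixel_area_cm2 = "numeric"),
  validity = function(object) {
    d <- dim(object@values)
    if (length(d) != 4L) return("values must be a 4-D array (tp, layer, row, col)")
    if (d[1] != length(object@tp_dat)) return("tp dimension != length(tp_dat)")
    if (d[2] != length(object@layer_names)) return("layer dimension != length(layer_names)")
    if (is.unsorted(object@tp_dat, strictly = TRUE))
      return("tp_dat must be strictly increasing")
    md <- dim(object@mask)
    if (length(md) != 3L || any(md != d[c(1, 3, 4)]))
      return("mask must be a 3-D (tp, row, col) array matching values")
    if (length(object@pixel_area_cm2) != 1L || object@pixel_area_cm2 <= 0)
      return("pixel_area_cm2 must be a positive scalar")
    TRUE
  })

setMethod("show", "PlantImageStack", function(object) {
  d <- dim(object@values)
  cat(sprintf("PlantImageStack: %d TPs x %d layers x %d x %d px (pixel %.3g cm^2)\n",
              d[1], d[2], d[3], d[4], object@pixel_area_cm2))
  cat("  layers:", paste(object@layer_names, collapse = ", "), "\n")
  cat("  DAT:", paste(object@tp_dat, collapse = ", "), "\n")
})

#' @describeIn PlantImageStack-class the (tp, layer, row, col) array
#' @param x A PlantImageStack.
#' @export
stackValues <- function(x) x@values

#' @describeIn PlantImageStack-class days-after-transplanting per time point
#' @export
stackDAT <- function(x) x@tp_dat

#' @describeIn PlantImageStack-class layer labels
#' @export
stackLayers <- function(x) x@layer_names

#' @describeIn PlantImageStack-class the (tp, row, col) vegetation mask
#' @export
stackMask <- function(x) x@mask

#' Extract one layer of one time point as a matrix
#' @param x A PlantImageStack.
#' @param tp Time-point index (1-based).
#' @param layer Layer name or index.
#' @return Numeric matrix (row, col).
#' @export
stackLayer <- function(x, tp, layer) {
  if (is.character(layer)) layer <- match(layer, x@layer_names)
  if (is.na(layer)) stop("unknown layer")
  x@values[tp, layer, , , drop = TRUE]
}

#' FeatureTable: plants x (time point x feature) modeling substrate
#'
#' Wide per-plant feature matrix with column names `{feature}@{DAT}`,
#' aligned harvest weights, and (after standardization) the per-column
#' centring/scaling statistics needed to transform held-out rows.
#'
#' @slot values Numeric matrix, rows = plants (rownames = plant ids),
#'   columns named `{feature}@{DAT}`.
#' @slot feature_names Character vector of base feature names.
#' @slot tp_dat Integer DATs represented in the columns.
#' @slot weights Numeric harvest weight (g/plant) per row.
#' @slot scale_center,scale_scale Standardization statistics (empty until
#'   [standardizeFeatures()] is applied).
#' @export
setClass("FeatureTable",
  representation(values = "matrix", feature_names = "character",
                 tp_dat = "integer", weights = "numeric",
                 scale_center = "numeric", scale_scale = "numeric"),
  validity = function(object) {
    if (nrow(object@values) != length(object@weights))
      return("one weight per plant row required")
    if (is.null(colnames(object@values)) || anyDuplicated(colnames(object@values)))
      return("columns must be uniquely named {feature}@{DAT}")
    if (any(!is.na(object@weights) & object@weights <= 0))
      return("weights must be > 0 where present")
    TRUE
  })

#' Construct a FeatureTable
#' @param values Matrix of features, columns named `{feature}@{DAT}`.
#' @param weights Harvest weight (g) per row, aligned with rows.
#' @param feature_names,tp_dat Optional; derived from column names if omitted.
#' @return A [FeatureTable-class].
#' @export
featureTable <- function(values, weights, feature_names = NULL, tp_dat = NULL) {
  parsed <- parseFeatureColumns(colnames(values))
  if (is.null(feature_names)) feature_names <- unique(parsed$feature)
  if (is.null(tp_dat)) tp_dat <- sort(unique(parsed$dat))
  new("FeatureTable", values = values, feature_names = feature_names,
      tp_dat = as.integer(tp_dat), weights = as.numeric(weights),
      scale_center = numeric(0), scale_scale = numeric(0))
}

parseFeatureColumns <- function(cn) {
  sp <- regmatches(cn, regexpr("@[0-9]+$", cn))
  if (length(sp) != length(cn)) stop("column names must end in '@<DAT>'")
  data.frame(feature = sub("@[0-9]+$", "", cn),
             dat = as.integer(sub("^@", "", sp)),
             stringsAsFactors = FALSE)
}

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable: %d plants x %d columns (%d features x %d TPs)\n",
              nrow(object@values), ncol(object@values),
              length(object@feature_names), length(object@tp_dat)))
  cat(sprintf("  weights: %d present, mean %.0f g\n",
              sum(!is.na(object@weights)),
              mean(object@weights, na.rm = TRUE)))
  if (length(object@scale_center)) cat("  standardized: yes\n")
})

#' @describeIn FeatureTable-class the feature matrix
#' @param x A FeatureTable.
#' @export
featureValues <- function(x) x@values

#' @describeIn FeatureTable-class harvest weights (g/plant)
#' @export
plantWeights <- function(x) x@weights

#' @describeIn FeatureTable-class base feature names
#' @export
featureNames <- function(x) x@feature_names

#' @describeIn FeatureTable-class DATs represented in the table
#' @export
featureDAT <- function(x) x@tp_dat

setMethod("dim", "FeatureTable", function(x) dim(x@values))

#' Subset a FeatureTable by plant rows
#' @param x A FeatureTable.
#' @param i Row index.
#' @param j,drop Unused; full columns are always kept.
#' @param ... Unused.
#' @export
setMethod("[", "FeatureTable", function(x, i, j, ..., drop = FALSE) {
  new("FeatureTable", values = x@values[i, , drop = FALSE],
      feature_names = x@feature_names, tp_dat = x@tp_dat,
      weights = x@weights[i],
      scale_center = x@scale_center, scale_scale = x@scale_scale)
})
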