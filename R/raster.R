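#' Circularly roll a matrix
#'
#' Content moves `dy` rows down and `dx` columns right, wrapping around.
#' @param m Matrix.
#' @param dy,dx Integer shifts (rows down, columns right).
#' @export
rollMatrix <- function(m, dy, dx) {
  n <- nrow(m); p <- ncol(m)
  m[((seq_len(n) - 1L - dy) %% n) + 1L, ((seq_len(p) - 1L - dx) %% p) + 1L,
    drop = FALSE]
}

#' Translate a matrix without wrap-around
#'
#' Like [rollMatrix()] but vacated cells become `fill` (NA by default).
#' @inheritParams rollMatrix
#' @param fill Value for vacated cells.
#' @export
translateMatrix <- function(m, dy, dx, fill = NA) {
  out <- matrix(fill, nrow(m), ncol(m))
  sr <- intersect(seq_len(nrow(m)), seq_len(nrow(m)) + dy)
  sc <- intersect(seq_len(ncol(m)), seq_len(ncol(m)) + dx)
  if (length(sr) && length(sc)) out[sr, sc] <- m[sr - dy, sc - dx, drop = FALSE]
  out
}

#' Rasterize a 3-D point cloud to a plant-height layer
#'
#' Each cell takes the mean z of the points whose (x, y) falls inside it;
#' cells containing no point are filled by nearest-neighbour interpolation
#' from filled cells (grid-distance nearest, via multi-source dilation).
#'
#' @param cloud Numeric matrix with columns x, y, z in projected metres.
#' @param gt A [GeoTransform-class] for the target grid.
#' @param shape Integer `c(nrow, ncol)` of the target raster.
#' @return A [RasterLayer-class] named "height".
#' @export
rasterizeHeight <- function(cloud, gt, shape) {
  cloud <- as.matrix(cloud)
  if (is.null(cloud) || nrow(cloud) == 0L) stop("empty point cloud")
  col <- floor((cloud[, 1] - gt@origin_x) / gt@gsd_x) + 1L
  row <- floor((gt@origin_y - cloud[, 2]) / gt@gsd_y) + 1L
  keep <- col >= 1L & col <= shape[2] & row >= 1L & row <= shape[1]
  if (!any(keep)) stop("no points fall inside the raster extent")
  idx <- (col[keep] - 1L) * shape[1] + row[keep]
  sums <- rowsum(cloud[keep, 3], idx)
  cnts <- rowsum(rep(1, sum(keep)), idx)
  v <- matrix(NA_real_, shape[1], shape[2])
  v[as.integer(rownames(sums))] <- sums / cnts
  v <- fillNearest(v)
  rasterLayer(v, gt, "height")
}

# multi-source dilation: every empty cell ends up with the value of a
# grid-nearest (chessboard metric) filled cell
fillNearest <- function(v) {
  filled <- !is.na(v)
  if (!any(filled)) stop("all cells empty after rasterization")
  while (any(!filled)) {
    for (s in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                   c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))) {
      cand <- translateMatrix(v, s[1], s[2])
      take <- !filled & !is.na(cand)
      v[take] <- cand[take]
    }
    newly <- !is.na(v) & !filled
    if (!any(newly)) break
    filled <- !is.na(v)
  }
  v
}

#' Subtract the reference surface from a height layer
#'
#' Elementwise `height - surface`, with negative results clamped to zero so
#' soil-level noise cannot produce negative canopy volume downstream. The
#' reference surface is typically the first-flight height raster, taken
#' before the canopy covers the soil.
#'
#' @param height,surface [RasterLayer-class] objects on the same geometry.
#' @return A [RasterLayer-class] of canopy height.
#' @export
subtractSurface <- function(height, surface) {
  if (!identical(dim(height@values), dim(surface@values)) ||
      !isTRUE(all.equal(c(height@gt@origin_x, height@gt@origin_y,
                          height@gt@gsd_x, height@gt@gsd_y),
                        c(surface@gt@origin_x, surface@gt@origin_y,
                          surface@gt@gsd_x, surface@gt@gsd_y))))
    stop("height and surface geometry mismatch")
  rasterLayer(pmax(height@values - surface@values, 0), height@gt,
              height@name)
}

#' Integer translation between two images by phase cross-correlation
#'
#' Computes the normalized cross-power spectrum of the two images and takes
#' the integer-pixel argmax of its inverse Fourier transform. The returned
#' shift `c(dx, dy)` is the translation that maps `moving` onto `reference`
#' (content moved dx columns right and dy rows down produces `moving` from
#' `reference`); wrap-around is resolved to the interval (-N/2, N/2].
#'
#' @param reference,moving Numeric matrices of identical shape; NA cells are
#'   replaced by the image mean before transforming.
#' @return Named numeric `c(dx, dy)` in pixels.
#' @export
phaseCorrelationShift <- function(reference, moving) {
  if (!identical(dim(reference), dim(moving)))
    stop("images must share a shape")
  fix <- function(m) { m[is.na(m)] <- mean(m, na.rm = TRUE); m }
  reference <- fix(reference); moving <- fix(moving)
  if (stats::sd(reference) == 0 || stats::sd(moving) == 0)
    stop("constant image: phase undefined")
  cp <- stats::fft(moving) * Conj(stats::fft(reference))
  cp <- cp / pmax(Mod(cp), .Machine$double.eps)
  r <- Re(stats::fft(cp, inverse = TRUE))
  k <- arrayInd(which.max(r), dim(r)) - 1L
  wrap <- function(k, n) if (k > n / 2) k - n else k
  c(dx = wrap(k[2], ncol(r)), dy = wrap(k[1], nrow(r)))
}

#' Luminance grayscale of three RGB layers
#' @param r,g,b Numeric matrices.
#' @return Matrix 0.299 R + 0.587 G + 0.114 B.
#' @export
rgbToGray <- function(r, g, b) 0.299 * r + 0.587 * g + 0.114 * b

#' Register multispectral layers onto the RGB grid
#'
#' Two steps, in order: the MS layers are resampled to the RGB grid by
#' nearest-neighbour assignment (each RGB cell centre takes the value of the
#' MS pixel it falls in), then the whole MS set is aligned by the
#' phase-cross-correlation shift estimated between the resampled NIR layer
#' and the RGB luminance. Output geometry equals the RGB geometry.
#'
#' @param ms Named list of [RasterLayer-class] MS layers sharing one
#'   geometry; must contain "NIR".
#' @param rgb_ref List of the three RGB [RasterLayer-class] layers (named
#'   R, G, B) or a single grayscale reference layer.
#' @param max_shift_px Largest credible co-registration error in pixels;
#'   an estimate beyond it is treated as a failed estimation (the two
#'   orthomosaics share ground control, so true offsets are a few pixels at
#'   most) and no shift is applied.
#' @return Named list of registered MS [RasterLayer-class] layers, with an
#'   `attr(, "shift")` giving the applied `c(dx, dy)` correction.
#' @export
registerMSToRGB <- function(ms, rgb_ref, max_shift_px = 10L) {
  if (is(rgb_ref, "RasterLayer")) {
    gray <- rgb_ref@values; gt <- rgb_ref@gt
  } else {
    gray <- rgbToGray(rgb_ref$R@values, rgb_ref$G@values, rgb_ref$B@values)
    gt <- rgb_ref$R@gt
  }
  shape <- dim(gray)
  res <- lapply(ms, function(l) resampleNearest(l, gt, shape))
  if (all(is.na(res[[1]]@values))) stop("MS and RGB extents do not overlap")
  if (!"NIR" %in% names(res)) stop("MS set must contain an 'NIR' layer")
  sh <- phaseCorrelationShift(gray, res[["NIR"]]@values)
  if (any(abs(sh) > max_shift_px)) sh <- c(dx = 0, dy = 0)
  out <- lapply(res, function(l)
    rasterLayer(translateMatrix(l@values, -sh["dy"], -sh["dx"]), gt, l@name))
  attr(out, "shift") <- -sh
  out
}

# nearest-neighbour resampling: target cell centres mapped into the source
resampleNearest <- function(layer, gt, shape) {
  xc <- gt@origin_x + (seq_len(shape[2]) - 0.5) * gt@gsd_x
  yc <- gt@origin_y - (seq_len(shape[1]) - 0.5) * gt@gsd_y
  sg <- layer@gt
  scol <- floor((xc - sg@origin_x) / sg@gsd_x) + 1L
  srow <- floor((sg@origin_y - yc) / sg@gsd_y) + 1L
  v <- matrix(NA_real_, shape[1], shape[2])
  okc <- scol >= 1L & scol <= ncol(layer@values)
  okr <- srow >= 1L & srow <= nrow(layer@values)
  v[okr, okc] <- layer@values[srow[okr], scol[okc], drop = FALSE]
  rasterLayer(v, gt, layer@name)
}

#' Spatial-accuracy report for two RGB images
#'
#' Both inputs are converted to luminance grayscale; the displacement is the
#' phase-cross-correlation shift and the similarity is the Pearson
#' correlation of the flattened grayscales.
#'
#' @param rgb_a,rgb_b Lists of three [RasterLayer-class] layers (R, G, B) on
#'   the same geometry.
#' @return List with `shift_px` (dx, dy), `shift_mm`, and `correlation`.
#' @export
assessAlignment <- function(rgb_a, rgb_b) {
  ga <- rgbToGray(rgb_a$R@values, rgb_a$G@values, rgb_a$B@values)
  gb <- rgbToGray(rgb_b$R@values, rgb_b$G@values, rgb_b$B@values)
  sh <- phaseCorrelationShift(ga, gb)
  gt <- rgb_a$R@gt
  list(shift_px = sh,
       shift_mm = c(dx = unname(sh["dx"]) * gt@gsd_x * 1000,
                    dy = unname(sh["dy"]) * gt@gsd_y * 1000),
       correlation = stats::cor(as.vector(ga), as.vector(gb),
                                use = "complete.obs"))
}

#' Cut a per-plant 4-D image stack from co-registered rasters
#'
#' The pixel window is the smallest half-open window on the RGB grid that
#' covers the projected box; the identical window is cut from every layer of
#' every time point, yielding a (tp, layer, row, col) array.
#'
#' @param box One-row bounding-box data.frame in projected metres.
#' @param layers_by_tp List over time points; each element a named list of
#'   [RasterLayer-class] layers sharing the reference geometry.
#' @param tp_dat Integer DAT per time point.
#' @return A [PlantImageStack-class] (mask initialized all-TRUE);
#'   `pixel_area_cm2 = gsd_x * gsd_y * 1e4`.
#' @export
cutPlantStack <- function(box, layers_by_tp, tp_dat) {
  gt <- layers_by_tp[[1]][[1]]@gt
  shape <- dim(layers_by_tp[[1]][[1]]@values)
  px <- projectedBoxToPixel(box, gt)
  col0 <- floor(px["col0"]); col1 <- ceiling(px["col1"])
  row0 <- floor(px["row0"]); row1 <- ceiling(px["row1"])
  if (col0 < 0 || row0 < 0 || col1 > shape[2] || row1 > shape[1])
    stop("box outside raster extent")
  rows <- (row0 + 1L):row1; cols <- (col0 + 1L):col1
  layer_names <- names(layers_by_tp[[1]])
  a <- array(NA_real_, c(length(layers_by_tp), length(layer_names),
                         length(rows), length(cols)))
  for (t in seq_along(layers_by_tp))
    for (l in seq_along(layer_names))
      a[t, l, , ] <- layers_by_tp[[t]][[layer_names[l]]]@values[rows, cols]
  new("PlantImageStack", values = a, tp_dat = as.integer(tp_dat),
      layer_names = layer_names,
      mask = array(TRUE, c(length(layers_by_tp), length(rows), length(cols))),
      pixel_area_cm2 = gt@gsd_x * gt@gsd_y * 1e4)
}
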