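#' Bounding boxes as data frames
#'
#' Detections are carried as data frames with numeric columns
#' `xmin`, `ymin`, `xmax`, `ymax` in one projected CRS (m) and an optional
#' `source_tp` column. `boundingBoxes()` validates and normalizes such a
#' table; box centres (the BBc of the grid-distance rule) are always the
#' exact midpoints.
#'
#' @param xmin,ymin,xmax,ymax Numeric vectors of box edges (m).
#' @param source_tp Optional time-point label per box (default "merged").
#' @return A validated data.frame of boxes.
#' @export
boundingBoxes <- function(xmin, ymin, xmax, ymax, source_tp = "merged") {
  b <- data.frame(xmin = as.numeric(xmin), ymin = as.numeric(ymin),
                  xmax = as.numeric(xmax), ymax = as.numeric(ymax),
                  source_tp = rep(source_tp, length.out = length(xmin)),
                  stringsAsFactors = FALSE)
  if (any(b$xmin >= b$xmax) || any(b$ymin >= b$ymax))
    stop("degenerate bounding box: need xmin < xmax and ymin < ymax")
  b
}

#' Box centres
#' @param boxes A bounding-box data.frame.
#' @return Two-column matrix of (x, y) centres.
#' @export
boxCenters <- function(boxes) {
  cbind(x = (boxes$xmin + boxes$xmax) / 2, y = (boxes$ymin + boxes$ymax) / 2)
}

#' Transform a pixel-space rectangle to projected coordinates
#'
#' Pixel coordinates are 0-based and half-open, with the row axis running
#' southward, so a rectangle (col0, row0)-(col1, row1) maps to
#' x = origin_x + col * gsd_x, y = origin_y - row * gsd_y; the projected
#' y interval is reordered so ymin < ymax.
#'
#' @param box_px Numeric vector `c(col0, row0, col1, row1)` (0-based,
#'   half-open) or a 4-column matrix of such rows.
#' @param gt A [GeoTransform-class].
#' @param source_tp Optional source label.
#' @return A bounding-box data.frame in projected metres.
#' @examples
#' pixelBoxToProjected(c(0, 0, 2, 2), geoTransform(0, 0, 1, 1))
#' @export
pixelBoxToProjected <- function(box_px, gt, source_tp = NA) {
  if (is.null(dim(box_px))) box_px <- matrix(box_px, ncol = 4, byrow = TRUE)
  if (any(box_px[, 1] >= box_px[, 3]) || any(box_px[, 2] >= box_px[, 4]))
    stop("degenerate pixel rectangle")
  x0 <- gt@origin_x + box_px[, 1] * gt@gsd_x
  x1 <- gt@origin_x + box_px[, 3] * gt@gsd_x
  yA <- gt@origin_y - box_px[, 2] * gt@gsd_y
  yB <- gt@origin_y - box_px[, 4] * gt@gsd_y
  boundingBoxes(x0, pmin(yA, yB), x1, pmax(yA, yB), source_tp = source_tp)
}

#' Transform a projected box back to pixel coordinates
#'
#' Inverse of [pixelBoxToProjected()]; returns continuous 0-based pixel
#' coordinates `c(col0, row0, col1, row1)`.
#'
#' @param box One-row bounding-box data.frame (or list with xmin..ymax).
#' @param gt A [GeoTransform-class].
#' @export
projectedBoxToPixel <- function(box, gt) {
  c(col0 = (box$xmin - gt@origin_x) / gt@gsd_x,
    row0 = (gt@origin_y - box$ymax) / gt@gsd_y,
    col1 = (box$xmax - gt@origin_x) / gt@gsd_x,
    row1 = (gt@origin_y - box$ymin) / gt@gsd_y)
}

pairwiseOverlapAdjacency <- function(boxes, overlap_threshold) {
  n <- nrow(boxes)
  ix <- pmin(outer(boxes$xmax, boxes$xmax, pmin) - outer(boxes$xmin, boxes$xmin, pmax),
             Inf)
  iy <- outer(boxes$ymax, boxes$ymax, pmin) - outer(boxes$ymin, boxes$ymin, pmax)
  inter <- pmax(ix, 0) * pmax(iy, 0)
  area <- (boxes$xmax - boxes$xmin) * (boxes$ymax - boxes$ymin)
  minarea <- outer(area, area, pmin)
  adj <- inter / minarea > overlap_threshold
  diag(adj) <- TRUE
  adj
}

#' Merge per-time-point detections into one box per plant
#'
#' Boxes are grouped by connected components of the pairwise relation
#' "intersection area / min(area_a, area_b) > overlap_threshold" (transitive
#' closure, so chains across three flights merge even when the first and
#' last box barely overlap). Each group is replaced by its coordinate-wise
#' envelope -- the maximum height and width covering all member boxes.
#' Non-overlapping boxes pass through unchanged.
#'
#' @param boxes Bounding-box data.frame across time points (one CRS).
#' @param overlap_threshold Fraction of the smaller box's area that must be
#'   intersected for two boxes to be grouped (default 0.40).
#' @return Merged bounding-box data.frame with columns `xmin..ymax`,
#'   `source_tp = "merged"`, `n_merged`, and a `group` attribute giving the
#'   component id of each input box.
#' @export
mergeDetections <- function(boxes, overlap_threshold = 0.40) {
  if (is.null(boxes) || nrow(boxes) == 0L)
    return(boundingBoxes(numeric(0), numeric(0), numeric(0), numeric(0))[0, ])
  n <- nrow(boxes)
  adj <- pairwiseOverlapAdjacency(boxes, overlap_threshold)
  # connected components by label propagation to the minimum neighbour label
  comp <- seq_len(n)
  repeat {
    nc <- vapply(seq_len(n), function(i) min(comp[adj[i, ]]), numeric(1))
    if (identical(nc, comp)) break
    comp <- nc
  }
  comp <- match(comp, unique(comp))
  out <- do.call(rbind, lapply(split(seq_len(n), comp), function(ii) {
    data.frame(xmin = min(boxes$xmin[ii]), ymin = min(boxes$ymin[ii]),
               xmax = max(boxes$xmax[ii]), ymax = max(boxes$ymax[ii]),
               source_tp = "merged", n_merged = length(ii))
  }))
  rownames(out) <- NULL
  attr(out, "group") <- comp
  out
}

#' Build the sowing-grid point geometry
#'
#' Points at `origin + (i * plant_spacing, j * row_spacing)` for plants
#' i = 0..n_cols-1 within rows j = 0..n_rows-1; ids are row-major. Defaults
#' follow a 45 x 65 cm planting layout (within-row plant spacing x row
#' spacing).
#'
#' @param origin Numeric `c(x, y)` of the first plant (m).
#' @param n_rows,n_cols Grid extent (rows x plants per row), each >= 1.
#' @param plant_spacing_m Within-row spacing along x (default 0.45).
#' @param row_spacing_m Row spacing along y (default 0.65).
#' @return data.frame(plant_id, row, col, x, y).
#' @export
buildGrid <- function(origin, n_rows, n_cols,
                      plant_spacing_m = 0.45, row_spacing_m = 0.65) {
  stopifnot(n_rows >= 1, n_cols >= 1)
  g <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  g <- g[order(g$row, g$col), ]
  data.frame(plant_id = seq_len(nrow(g)), row = g$row, col = g$col,
             x = origin[1] + (g$col - 1L) * plant_spacing_m,
             y = origin[2] + (g$row - 1L) * row_spacing_m)
}

#' Index merged boxes to grid points
#'
#' For every grid point the Euclidean spatial distance SPd to every box
#' centre is computed; the nearest box with SPd < `max_dist_m` (the sowing
#' distance, 45 cm) is indexed to the point. A box may be claimed by at most
#' one plant: conflicts are resolved globally, nearest point wins, and the
#' loser is left unassigned.
#'
#' @param points Grid data.frame from [buildGrid()] (plant_id, x, y).
#' @param boxes Merged bounding-box data.frame.
#' @param max_dist_m Maximum assignment distance in metres (default 0.45).
#' @return data.frame(plant_id, box (index into `boxes`), xmin..ymax, spd_m);
#'   unassigned plants carry NA.
#' @export
assignBoxesToGrid <- function(points, boxes, max_dist_m = 0.45) {
  np <- nrow(points)
  out <- data.frame(plant_id = points$plant_id, box = NA_integer_,
                    xmin = NA_real_, ymin = NA_real_,
                    xmax = NA_real_, ymax = NA_real_, spd_m = NA_real_)
  if (is.null(boxes) || nrow(boxes) == 0L) return(out)
  ctr <- boxCenters(boxes)
  d <- sqrt(outer(points$x, ctr[, "x"], "-")^2 +
            outer(points$y, ctr[, "y"], "-")^2)
  d[d >= max_dist_m] <- Inf
  # global greedy: repeatedly take the overall nearest (point, box) pair
  while (any(is.finite(d))) {
    k <- arrayInd(which.min(d), dim(d))
    i <- k[1]; j <- k[2]
    out$box[i] <- j
    out$xmin[i] <- boxes$xmin[j]; out$ymin[i] <- boxes$ymin[j]
    out$xmax[i] <- boxes$xmax[j]; out$ymax[i] <- boxes$ymax[j]
    out$spd_m[i] <- d[i, j]
    d[i, ] <- Inf
    d[, j] <- Inf
  }
  out
}

#' Overall detection accuracy
#'
#' @param assignments Assignment table from [assignBoxesToGrid()].
#' @param n_total_plants Number of plants sown in the assessed field.
#' @return Fraction of plants with an indexed box.
#' @export
detectionAccuracy <- function(assignments, n_total_plants) {
  if (n_total_plants <= 0) stop("n_total_plants must be > 0")
  sum(!is.na(assignments$spd_m)) / n_total_plants
}
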