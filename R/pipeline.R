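#' Run the full individual-plant phenotyping pipeline on a field bundle
#'
#' End-to-end processing exactly in the field order: (1) detections from
#' the early detection flights are merged into one box per plant and
#' indexed to the sowing grid; (2) multispectral layers are registered to
#' the RGB geometry and the first-flight surface is subtracted from every
#' height raster; (3) a 4-D stack is cut per assigned plant; (4) per
#' flight, vegetation indices are computed and the noise-filter cascade is
#' applied (k-means soil mask on the VI stack, contour area filter,
#' RGB histogram equalization at summarization time); (5) stacks are
#' centred on the first-flight convex hull and cropped; (6) features are
#' summarized (layer medians, retained-VI medians, 90th-percentile height,
#' leaf angle, volume) and assembled into a [FeatureTable-class] against
#' the harvest weights.
#'
#' @param bundle A [FieldBundle-class].
#' @param detection_tps Indices of the flights whose detections are merged
#'   (default: every flight, so the merged envelope covers the mature
#'   canopy; pass e.g. `1:3` to mimic a detector run only on early
#'   flights).
#' @param overlap_threshold Box-merging overlap fraction (default 0.40).
#' @param max_dist_m Grid-assignment distance cut (default 0.45).
#' @param r_threshold VI-pruning correlation threshold (default 0.95).
#' @param crop_fraction Centre-crop fraction (default 0.70).
#' @param min_area_fraction Contour-filter relative area (default 0.05).
#' @param seed Seed for the k-means soil masks.
#' @return List with `features` (a [FeatureTable-class]), `assignments`,
#'   `accuracy`, `merged_boxes`, `retained_vis`, `vi_table` (the final-TP
#'   plant x VI median matrix the pruning saw).
#' @export
processBundle <- function(bundle, detection_tps = NULL,
                          overlap_threshold = 0.40, max_dist_m = 0.45,
                          r_threshold = 0.95, crop_fraction = 0.70,
                          min_area_fraction = 0.05, seed = 1L) {
  if (is.null(detection_tps)) detection_tps <- seq_along(bundle@tp_dat)
  detection_tps <- detection_tps[detection_tps <= length(bundle@tp_dat)]
  boxes <- do.call(rbind, lapply(bundle@detections[detection_tps],
                                 function(b) b[names(b) != "plant_truth"]))
  merged <- mergeDetections(boxes, overlap_threshold)
  assignments <- assignBoxesToGrid(bundle@grid, merged, max_dist_m)
  accuracy <- detectionAccuracy(assignments, nrow(bundle@grid))

  # register MS to the RGB geometry and build canopy-height layers
  # (first-flight raster is the reference surface)
  ms_names <- c("blue", "green", "red", "red_edge", "NIR")
  surface <- bundle@layers[[1]][["height"]]
  layers_by_tp <- lapply(seq_along(bundle@tp_dat), function(t) {
    L <- bundle@layers[[t]]
    reg <- registerMSToRGB(L[ms_names], L[c("R", "G", "B")])
    c(L[c("R", "G", "B")], reg,
      list(height = subtractSurface(L[["height"]], surface)))
  })

  assigned <- which(!is.na(assignments$spd_m))
  vi_names <- viRegistry()$name
  gsd <- bundle@gt@gsd_x
  stacks <- list()
  for (i in assigned) {
    stack <- cutPlantStack(assignments[i, ], layers_by_tp, bundle@tp_dat)
    d <- dim(stack@values)
    msk <- stack@mask
    for (t in seq_len(d[1])) {
      lyr <- stats::setNames(
        lapply(seq_len(d[2]), function(l) stack@values[t, l, , ]),
        stack@layer_names)
      vis <- stats::setNames(lapply(vi_names, function(nm)
        computeVI(lyr, nm)), vi_names)
      # a window fully covered by uniform canopy has nothing to separate;
      # treat it as all-vegetation rather than failing the plant
      m <- tryCatch(soilMaskKmeans(vis, seed = seed + i),
                    error = function(e) matrix(TRUE, d[3], d[4]))
      msk[t, , ] <- contourFilter(m, min_area_fraction)
    }
    stack@mask <- msk
    stacks[[as.character(assignments$plant_id[i])]] <-
      centerAndCrop(stack, msk[1, , ], crop_fraction)
  }

  # per-plant seasonal mean VI medians drive the correlation pruning:
  # averaging each plant's per-flight medians over the season removes the
  # common growth trajectory, so the pruning sees between-plant redundancy
  # rather than the shared time trend
  vi_table <- do.call(rbind, lapply(stacks, function(s) {
    per_tp <- vapply(seq_along(s@tp_dat), function(t) {
      lyr <- stats::setNames(
        lapply(seq_along(s@layer_names), function(l) s@values[t, l, , ]),
        s@layer_names)
      vapply(vi_names, function(nm)
        layerMedian(computeVI(lyr, nm), s@mask[t, , ]), numeric(1))
    }, numeric(length(vi_names)))
    rowMeans(per_tp, na.rm = TRUE)
  }))
  rownames(vi_table) <- names(stacks)
  retained <- pruneCorrelatedVIs(vi_table, r_threshold)

  feature_list <- lapply(stacks, featurizeStack, vi_names = retained,
                         gsd_m = gsd)
  weights <- stats::setNames(bundle@truth$weight_g, bundle@truth$plant_id)
  features <- assembleFeatureTable(
    feature_list, weights[names(feature_list)])
  list(features = features, assignments = assignments, accuracy = accuracy,
       merged_boxes = merged, retained_vis = retained, vi_table = vi_table)
}
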