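#' Write a multi-layer georeferenced TIFF
#'
#' Layers are written as 16-bit TIFF pages scaled by a per-file `scale`
#' (values stored as value/scale in [0, 1]); georeferencing goes to an ESRI
#' world file (`.tfw`) next to the image, and layer names plus the scale to
#' a small JSON sidecar (`.bands.json`). Values must already be quantized
#' to multiples of scale/65535 for a lossless round trip, as the synthetic
#' generator's integer-scaled reflectances are.
#'
#' @param layers Named list of [RasterLayer-class] objects on one geometry.
#' @param path Output path ending in `.tif`.
#' @param scale Scalar physical value corresponding to stored 1.0.
#' @return `path`, invisibly.
#' @export
writeGeoTIFF <- function(layers, path, scale = 1) {
  gt <- layers[[1]]@gt
  pages <- lapply(layers, function(l) {
    v <- l@values / scale
    if (any(v < 0 | v > 1, na.rm = TRUE))
      stop("values exceed the 16-bit scale range [0, ", scale, "]")
    v[is.na(v)] <- 0
    # writeTIFF truncates to 16-bit levels; centre each value on its level
    # so quantized inputs survive the floor exactly
    pmin((round(v * 65535) + 0.5) / 65535, 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  tfw <- sub("\\.tiff?$", ".tfw", path)
  writeLines(formatC(c(gt@gsd_x, 0, 0, -gt@gsd_y,
                       gt@origin_x + gt@gsd_x / 2,
                       gt@origin_y - gt@gsd_y / 2),
                     format = "f", digits = 12), tfw)
  jsonlite::write_json(
    list(bands = names(layers), scale = scale),
    sub("\\.tiff?$", ".bands.json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-layer georeferenced TIFF written by [writeGeoTIFF()]
#'
#' @param path Path to the `.tif`.
#' @return Named list of [RasterLayer-class] objects.
#' @export
readGeoTIFF <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  tfw <- as.numeric(readLines(sub("\\.tiff?$", ".tfw", path)))
  meta <- jsonlite::read_json(sub("\\.tiff?$", ".bands.json", path),
                              simplifyVector = TRUE)
  gt <- geoTransform(tfw[5] - tfw[1] / 2, tfw[6] - tfw[4] / 2,
                     tfw[1], -tfw[4])
  stats::setNames(lapply(seq_along(pages), function(i) {
    # undo the 16-bit quantization readTIFF applies (values are k/65535)
    v <- round(pages[[i]] * 65535) / 65535 * meta$scale
    rasterLayer(v, gt, meta$bands[i])
  }), meta$bands)
}

#' Write bounding boxes as a GeoJSON FeatureCollection of polygons
#'
#' @param boxes Bounding-box data.frame; extra columns become properties.
#' @param path Output `.geojson` path.
#' @export
writeBoxesGeoJSON <- function(boxes, path) {
  feats <- lapply(seq_len(nrow(boxes)), function(i) {
    b <- boxes[i, ]
    props <- as.list(b[setdiff(names(b), c("xmin", "ymin", "xmax", "ymax"))])
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = list(list(
           c(b$xmin, b$ymin), c(b$xmax, b$ymin), c(b$xmax, b$ymax),
           c(b$xmin, b$ymax), c(b$xmin, b$ymin)))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read axis-aligned boxes back from GeoJSON polygons
#'
#' @param path Path to a `.geojson` written by [writeBoxesGeoJSON()].
#' @return Bounding-box data.frame.
#' @export
readBoxesGeoJSON <- function(path) {
  fc <- jsonlite::read_json(path)
  if (length(fc$features) == 0L)
    return(boundingBoxes(numeric(0), numeric(0), numeric(0), numeric(0),
                         source_tp = character(0)))
  rows <- lapply(fc$features, function(f) {
    xy <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    cbind(data.frame(xmin = min(xy[, 1]), ymin = min(xy[, 2]),
                     xmax = max(xy[, 1]), ymax = max(xy[, 2])),
          as.data.frame(f$properties, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write grid points as GeoJSON
#' @param grid data.frame(plant_id, x, y, ...).
#' @param path Output path.
#' @export
writeGridGeoJSON <- function(grid, path) {
  feats <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    list(type = "Feature",
         properties = as.list(g[setdiff(names(g), c("x", "y"))]),
         geometry = list(type = "Point", coordinates = c(g$x, g$y)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read grid points from GeoJSON
#' @param path Path written by [writeGridGeoJSON()].
#' @return data.frame with x, y and the stored properties.
#' @export
readGridGeoJSON <- function(path) {
  fc <- jsonlite::read_json(path)
  rows <- lapply(fc$features, function(f)
    cbind(as.data.frame(f$properties, stringsAsFactors = FALSE),
          data.frame(x = f$geometry$coordinates[[1]],
                     y = f$geometry$coordinates[[2]])))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Persist a synthetic bundle to disk
#'
#' Writes per-flight RGB / MS / height rasters (16-bit TIFF + world file +
#' band sidecar), detections and grid as GeoJSON, the truth table as CSV
#' and a YAML manifest listing every file plus the generating
#' configuration. Integer-scaled reflectances round-trip losslessly.
#'
#' @param bundle A [FieldBundle-class].
#' @param directory Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
writeBundle <- function(bundle, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (file.access(directory, 2) != 0) stop("directory not writable")
  cfg <- bundle@config
  tps <- bundle@tp_dat
  files <- list()
  for (t in seq_along(tps)) {
    tag <- sprintf("tp%02d", t)
    L <- bundle@layers[[t]]
    f_rgb <- file.path(directory, paste0("rgb_", tag, ".tif"))
    f_ms <- file.path(directory, paste0("ms_", tag, ".tif"))
    f_h <- file.path(directory, paste0("height_", tag, ".tif"))
    f_det <- file.path(directory, paste0("detections_", tag, ".geojson"))
    writeGeoTIFF(L[c("R", "G", "B")], f_rgb)
    writeGeoTIFF(L[c("blue", "green", "red", "red_edge", "NIR")], f_ms)
    writeGeoTIFF(L["height"], f_h, scale = HEIGHT_SCALE_M)
    writeBoxesGeoJSON(bundle@detections[[t]], f_det)
    files[[t]] <- list(tp = t, dat = tps[t], rgb = basename(f_rgb),
                       ms = basename(f_ms), height = basename(f_h),
                       detections = basename(f_det))
  }
  writeGridGeoJSON(bundle@grid, file.path(directory, "grid.geojson"))
  utils::write.csv(bundle@truth, file.path(directory, "truth.csv"),
                   row.names = FALSE)
  manifest <- list(
    config = list(n_rows = cfg@n_rows, n_cols = cfg@n_cols,
                  plant_spacing_m = cfg@plant_spacing_m,
                  row_spacing_m = cfg@row_spacing_m, gsd_m = cfg@gsd_m,
                  margin_m = cfg@margin_m,
                  timepoints_dat = cfg@timepoints_dat,
                  growth = cfg@growth, spectral = cfg@spectral,
                  weight_model = cfg@weight_model, detector = cfg@detector,
                  seed = cfg@seed),
    grid = "grid.geojson", truth = "truth.csv", timepoints = files)
  yaml::write_yaml(manifest, file.path(directory, "manifest.yaml"))
  invisible(manifest)
}

#' Read a bundle written by [writeBundle()]
#'
#' @param directory Bundle directory containing `manifest.yaml`.
#' @return A [FieldBundle-class].
#' @export
readBundle <- function(directory) {
  manifest <- yaml::read_yaml(file.path(directory, "manifest.yaml"))
  mc <- manifest$config
  cfg <- fieldConfig(
    n_rows = mc$n_rows, n_cols = mc$n_cols,
    plant_spacing_m = mc$plant_spacing_m, row_spacing_m = mc$row_spacing_m,
    gsd_m = mc$gsd_m, margin_m = mc$margin_m,
    timepoints_dat = unlist(mc$timepoints_dat),
    max_radius_m = mc$growth$max_radius_m,
    max_height_m = mc$growth$max_height_m, rate = mc$growth$rate,
    midpoint_dat = mc$growth$midpoint_dat,
    vigor_sdlog = mc$growth$vigor_sdlog,
    bump_mid_dat = mc$spectral$bump_mid_dat,
    bump_width_d = mc$spectral$bump_width_d,
    bump_trunc = mc$spectral$bump_trunc,
    soil_noise_sd = mc$spectral$soil_noise_sd,
    beta_volume = mc$weight_model$beta_volume,
    beta_spectral = mc$weight_model$beta_spectral,
    noise_sd = mc$weight_model$noise_sd,
    miss_rate = mc$detector$miss_rate,
    jitter_sd_m = mc$detector$jitter_sd_m, seed = mc$seed)
  tps <- cfg@timepoints_dat
  layers <- vector("list", length(tps))
  detections <- vector("list", length(tps))
  for (t in seq_along(tps)) {
    fi <- manifest$timepoints[[t]]
    layers[[t]] <- c(readGeoTIFF(file.path(directory, fi$rgb)),
                     readGeoTIFF(file.path(directory, fi$ms)),
                     readGeoTIFF(file.path(directory, fi$height)))
    detections[[t]] <- readBoxesGeoJSON(file.path(directory, fi$detections))
  }
  grid <- readGridGeoJSON(file.path(directory, manifest$grid))
  truth <- utils::read.csv(file.path(directory, manifest$truth))
  radii <- outer(cfg@growth$max_radius_m *
                   pmin(truth$vigor^0.3,
                        0.49 * min(cfg@plant_spacing_m, cfg@row_spacing_m) /
                          cfg@growth$max_radius_m),
                 logisticSize(tps, cfg@growth))
  heights <- outer(cfg@growth$max_height_m * truth$vigor,
                   logisticSize(tps, cfg@growth))
  gt <- layers[[1]][[1]]@gt
  new("FieldBundle", config = cfg, gt = gt, layers = layers,
      tp_dat = tps, detections = detections, grid = grid,
      radii = radii, heights = heights, truth = truth)
}
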