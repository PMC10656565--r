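#' FieldConfig: full specification of a synthetic cabbage field
#'
#' Everything the generator needs: grid layout (45 x 65 cm default
#' spacing), ground sampling distance, flight calendar, logistic canopy
#' growth with a multiplicative lognormal per-plant vigor effect, the
#' spectral model separating vegetation from soil, the ground-truth weight
#' model, and the simulated detector's error rates.
#'
#' @slot n_rows,n_cols Grid extent (rows x plants per row).
#' @slot plant_spacing_m,row_spacing_m Within-row / between-row spacing (m).
#' @slot gsd_m Ground sampling distance per pixel (m).
#' @slot margin_m Soil margin around the grid (m).
#' @slot timepoints_dat Strictly increasing flight days after transplanting.
#' @slot growth list(max_radius_m, max_height_m, rate, midpoint_dat,
#'   vigor_sdlog): plant radius/height follow
#'   `max * vigor_effect * plogis(rate * (DAT - midpoint_dat))`.
#' @slot spectral list(bump_mid_dat, bump_width_d, soil_noise_sd): per-plant
#'   reflectance departs from the vegetation baseline in proportion to a
#'   mid-season Gaussian bump, so mid-season flights carry spectral signal
#'   the final flight does not.
#' @slot weight_model list(beta_volume, beta_spectral, noise_sd): true
#'   weight (g) = beta_volume * final volume (cm^3) + beta_spectral *
#'   mid-season mean NDVI + Normal(0, noise_sd), truncated positive.
#' @slot detector list(miss_rate, jitter_sd_m).
#' @slot seed Integer master seed; identical config implies a bit-identical
#'   bundle.
#' @export
setClass("FieldConfig",
  representation(n_rows = "integer", n_cols = "integer",
                 plant_spacing_m = "numeric", row_spacing_m = "numeric",
                 gsd_m = "numeric", margin_m = "numeric",
                 timepoints_dat = "integer", growth = "list",
                 spectral = "list", weight_model = "list",
                 detector = "list", seed = "integer"),
  validity = function(object) {
    if (object@plant_spacing_m <= 0 || object@row_spacing_m <= 0)
      return("spacings must be > 0")
    if (object@gsd_m <= 0) return("gsd must be > 0")
    if (is.unsorted(object@timepoints_dat, strictly = TRUE))
      return("timepoints_dat must be strictly increasing")
    mr <- object@detector$miss_rate
    if (mr < 0 || mr > 1) return("miss_rate must be in [0, 1]")
    if (object@growth$max_radius_m >
        min(object@plant_spacing_m, object@row_spacing_m) / 2)
      return("sizing error: max_radius_m exceeds half the minimum spacing (plants would overlap)")
    TRUE
  })

#' Construct a synthetic-field configuration
#'
#' Defaults describe a 10 x 10 plant field on the 45 x 65 cm layout at
#' 1 cm GSD, eight flights between 12 and 102 DAT, plants reaching ~0.36 m
#' diameter and ~0.25 m height with ~25 percent lognormal vigor variation,
#' and a weight model producing roughly 2.5-3.5 kg plants.
#'
#' @param n_rows,n_cols Grid extent.
#' @param plant_spacing_m,row_spacing_m,gsd_m,margin_m Field geometry (m).
#' @param timepoints_dat Flight calendar (DAT).
#' @param max_radius_m,max_height_m,rate,midpoint_dat,vigor_sdlog Growth
#'   model parameters.
#' @param bump_mid_dat,bump_width_d,bump_trunc,soil_noise_sd Spectral model
#'   parameters; the per-plant reflectance departure follows a truncated
#'   Gaussian bump over the season that is exactly zero far from its peak,
#'   so harvest-time reflectance carries no between-plant signal.
#' @param beta_volume,beta_spectral,noise_sd Weight model parameters
#'   (g/cm^3, g per NDVI unit, g).
#' @param miss_rate,jitter_sd_m Detector simulation parameters.
#' @param seed Master seed.
#' @return A [FieldConfig-class].
#' @export
fieldConfig <- function(n_rows = 10L, n_cols = 10L,
                        plant_spacing_m = 0.45, row_spacing_m = 0.65,
                        gsd_m = 0.01, margin_m = 0.5,
                        timepoints_dat = c(12L, 25L, 38L, 51L, 64L, 77L,
                                           90L, 102L),
                        max_radius_m = 0.18, max_height_m = 0.25,
                        rate = 0.09, midpoint_dat = 40,
                        vigor_sdlog = 0.2,
                        bump_mid_dat = 55, bump_width_d = 25,
                        bump_trunc = 0.05, soil_noise_sd = 0.01,
                        beta_volume = 0.16, beta_spectral = 2000,
                        noise_sd = 150,
                        miss_rate = 0.05, jitter_sd_m = 0.02,
                        seed = 1L) {
  new("FieldConfig", n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      plant_spacing_m = plant_spacing_m, row_spacing_m = row_spacing_m,
      gsd_m = gsd_m, margin_m = margin_m,
      timepoints_dat = as.integer(timepoints_dat),
      growth = list(max_radius_m = max_radius_m, max_height_m = max_height_m,
                    rate = rate, midpoint_dat = midpoint_dat,
                    vigor_sdlog = vigor_sdlog),
      spectral = list(bump_mid_dat = bump_mid_dat,
                      bump_width_d = bump_width_d, bump_trunc = bump_trunc,
                      soil_noise_sd = soil_noise_sd),
      weight_model = list(beta_volume = beta_volume,
                          beta_spectral = beta_spectral, noise_sd = noise_sd),
      detector = list(miss_rate = miss_rate, jitter_sd_m = jitter_sd_m),
      seed = as.integer(seed))
}

#' Zero every noise source of a configuration
#'
#' Sets the weight-model noise, detector miss rate and jitter, and soil
#' reflectance noise to zero, leaving the deterministic structure (growth,
#' spectral signal, vigor variation) untouched.
#'
#' @param config A [FieldConfig-class].
#' @return The noiseless [FieldConfig-class].
#' @export
noiselessConfig <- function(config) {
  config@weight_model$noise_sd <- 0
  config@detector$miss_rate <- 0
  config@detector$jitter_sd_m <- 0
  config@spectral$soil_noise_sd <- 0
  config
}

setMethod("show", "FieldConfig", function(object) {
  cat(sprintf("FieldConfig: %d x %d plants, %d TPs (%d..%d DAT), gsd %.3g m, seed %d\n",
              object@n_rows, object@n_cols, length(object@timepoints_dat),
              min(object@timepoints_dat), max(object@timepoints_dat),
              object@gsd_m, object@seed))
})

#' FieldBundle: a rendered synthetic field with ground truth
#'
#' @slot config The generating [FieldConfig-class].
#' @slot gt Shared [GeoTransform-class] of all rasters.
#' @slot layers List over time points; each element a named list of
#'   [RasterLayer-class] (R, G, B, blue, green, red, red_edge, NIR, height).
#' @slot tp_dat Flight DATs.
#' @slot detections List over time points of bounding-box data.frames.
#' @slot grid Sowing grid data.frame (plant_id, row, col, x, y).
#' @slot radii,heights Plants x TP matrices of rendered radius / max height
#'   (m).
#' @slot truth data.frame(plant_id, row, col, x, y, vigor, radius_final_m,
#'   volume_cm3, ndvi_mid, weight_g).
#' @export
setClass("FieldBundle",
  representation(config = "FieldConfig", gt = "GeoTransform",
                 layers = "list", tp_dat = "integer", detections = "list",
                 grid = "data.frame", radii = "matrix", heights = "matrix",
                 truth = "data.frame"),
  validity = function(object) {
    if (length(object@layers) != length(object@tp_dat))
      return("one layer set per time point required")
    if (anyDuplicated(object@truth$plant_id))
      return("plant ids must be unique")
    if (any(object@truth$weight_g <= 0)) return("weights must be > 0")
    TRUE
  })

setMethod("show", "FieldBundle", function(object) {
  cat(sprintf("FieldBundle: %d plants, %d TPs, rasters %d x %d px\n",
              nrow(object@truth), length(object@tp_dat),
              nrow(object@layers[[1]][[1]]@values),
              ncol(object@layers[[1]][[1]]@values)))
  cat(sprintf("  weight: %.0f +/- %.0f g/plant\n",
              mean(object@truth$weight_g), stats::sd(object@truth$weight_g)))
})

#' @describeIn FieldBundle-class the per-plant ground-truth table
#' @param x A FieldBundle.
#' @export
bundleTruth <- function(x) x@truth

#' @describeIn FieldBundle-class the sowing grid
#' @export
bundleGrid <- function(x) x@grid

#' @describeIn FieldBundle-class named raster layers of one time point
#' @param tp Time-point index.
#' @export
bundleLayers <- function(x, tp) x@layers[[tp]]

#' @describeIn FieldBundle-class detection boxes of one time point
#' @export
bundleDetections <- function(x, tp) x@detections[[tp]]

logisticSize <- function(dat, growth)
  stats::plogis(growth$rate * (dat - growth$midpoint_dat))

# truncated Gaussian: the per-plant spectral departure peaks mid-season and
# reaches exactly zero once the Gaussian falls below the truncation mass,
# i.e. all plants share one senescent reflectance by harvest
spectralBump <- function(dat, spectral) {
  tr <- if (is.null(spectral$bump_trunc)) 0.05 else spectral$bump_trunc
  g <- exp(-((dat - spectral$bump_mid_dat) / spectral$bump_width_d)^2)
  pmax(0, (g - tr) / (1 - tr))
}

# per-plant reflectance at one DAT: vegetation baseline plus mid-season
# departures driven by two latents -- a nutrition-like factor (qs, the one
# the weight model's spectral term sees, independent of plant size) and a
# chlorophyll-like factor (q2) that decorrelates the green / red-edge
# indices from the red / NIR ones. Departures follow the seasonal bump, so
# by harvest all plants converge to the same senescent reflectance.
plantReflectance <- function(qs, q2, dat, spectral) {
  b <- spectralBump(dat, spectral)
  cl <- function(v) pmin(pmax(v, 0.02), 0.98)
  nir <- cl(0.75 + 0.30 * (qs - 0.5) * b)
  red <- cl(0.15 - 0.20 * (qs - 0.5) * b)
  grn <- cl(0.32 + 0.10 * (q2 - 0.5) * b)
  re <- cl(0.42 + 0.10 * (qs - 0.5) * b - 0.08 * (q2 - 0.5) * b)
  list(blue = rep(0.05, length(qs)), green = grn,
       red = red, red_edge = re, NIR = nir,
       R = red, G = cl(0.45 + 0.10 * (q2 - 0.5) * b),
       B = rep(0.06, length(qs)))
}

soilReflectance <- function() {
  c(R = 0.30, G = 0.25, B = 0.20, blue = 0.15, green = 0.25, red = 0.30,
    red_edge = 0.27, NIR = 0.25)
}

quantize16 <- function(v, scale = 1) round(v / scale * 65535) / 65535 * scale

HEIGHT_SCALE_M <- 10  # heights stored as 16-bit fractions of 10 m

#' Generate a synthetic field bundle
#'
#' Plants are rendered as radially symmetric cosine-tapered height discs
#' carrying uniform per-plant vegetation reflectance on a noisy soil
#' background; radius and height follow the logistic growth curve at each
#' flight. True weight is computed from the emitted rasters themselves:
#' `beta_volume` times the final-flight surface-subtracted canopy volume
#' over the plant's disc plus `beta_spectral` times the mean NDVI over the
#' disc at the flight nearest the spectral mid-season, plus truncated
#' Gaussian noise. All randomness flows from the config seed, so identical
#' configs give bit-identical bundles.
#'
#' @param config A [FieldConfig-class].
#' @return A [FieldBundle-class].
#' @export
generateField <- function(config) {
  g <- config@growth
  n <- config@n_rows * config@n_cols
  tps <- config@timepoints_dat
  grid <- buildGrid(c(config@margin_m, config@margin_m),
                    config@n_rows, config@n_cols,
                    config@plant_spacing_m, config@row_spacing_m)
  W <- (config@n_cols - 1L) * config@plant_spacing_m + 2 * config@margin_m
  H <- (config@n_rows - 1L) * config@row_spacing_m + 2 * config@margin_m
  npx_c <- as.integer(round(W / config@gsd_m))
  npx_r <- as.integer(round(H / config@gsd_m))
  gt <- geoTransform(0, H, config@gsd_m)

  bundle <- withr::with_seed(config@seed, {
    vigor <- stats::rlnorm(n, 0, g$vigor_sdlog)
    # radius responds sub-linearly to vigor and is capped so neighbouring
    # plants can never touch; height carries the full vigor effect
    rad_fac <- pmin(vigor^0.3,
                    0.49 * min(config@plant_spacing_m, config@row_spacing_m) /
                      g$max_radius_m)
    radius_i <- g$max_radius_m * rad_fac
    height_i <- g$max_height_m * vigor
    radii <- outer(radius_i, logisticSize(tps, g))
    heights <- outer(height_i, logisticSize(tps, g))
    qs <- stats::runif(n)   # nutrition latent, independent of plant size
    q2 <- stats::runif(n)   # chlorophyll latent (spectral nuisance)

    soil <- soilReflectance()
    layer_names <- c("R", "G", "B", "blue", "green", "red", "red_edge",
                     "NIR", "height")
    xc <- (seq_len(npx_c) - 0.5) * config@gsd_m
    yc <- H - (seq_len(npx_r) - 0.5) * config@gsd_m
    layers <- vector("list", length(tps))
    for (t in seq_along(tps)) {
      mats <- stats::setNames(vector("list", length(layer_names)),
                              layer_names)
      for (nm in names(soil))
        mats[[nm]] <- matrix(
          pmin(pmax(soil[nm] + stats::rnorm(npx_r * npx_c, 0,
                                            config@spectral$soil_noise_sd),
                    0), 1), npx_r, npx_c)
      mats[["height"]] <- matrix(0, npx_r, npx_c)
      refl <- plantReflectance(qs, q2, tps[t], config@spectral)
      for (i in seq_len(n)) {
        r <- radii[i, t]; h <- heights[i, t]
        ci <- which(abs(xc - grid$x[i]) <= r)
        ri <- which(abs(yc - grid$y[i]) <= r)
        if (length(ci) == 0L || length(ri) == 0L) next
        d <- sqrt(outer((yc[ri] - grid$y[i])^2, (xc[ci] - grid$x[i])^2, "+"))
        disc <- d <= r
        if (!any(disc)) next
        for (nm in setdiff(layer_names, "height")) {
          sub <- mats[[nm]][ri, ci, drop = FALSE]
          sub[disc] <- refl[[nm]][i]
          mats[[nm]][ri, ci] <- sub
        }
        sub <- mats[["height"]][ri, ci, drop = FALSE]
        sub[disc] <- h * cos(pi * d[disc] / (2 * r))
        mats[["height"]][ri, ci] <- sub
      }
      for (nm in setdiff(layer_names, "height"))
        mats[[nm]] <- quantize16(mats[[nm]])
      mats[["height"]] <- quantize16(mats[["height"]], HEIGHT_SCALE_M)
      layers[[t]] <- stats::setNames(
        lapply(layer_names, function(nm) rasterLayer(mats[[nm]], gt, nm)),
        layer_names)
    }

    # ground truth from the rendered rasters
    tp_mid <- which.min(abs(tps - config@spectral$bump_mid_dat))
    tp_fin <- length(tps)
    vol <- ndvi_mid <- numeric(n)
    h_fin <- layers[[tp_fin]][["height"]]@values
    h_ref <- layers[[1L]][["height"]]@values
    nir_m <- layers[[tp_mid]][["NIR"]]@values
    red_m <- layers[[tp_mid]][["red"]]@values
    for (i in seq_len(n)) {
      r <- radii[i, tp_fin]
      ci <- which(abs(xc - grid$x[i]) <= r)
      ri <- which(abs(yc - grid$y[i]) <= r)
      d <- sqrt(outer((yc[ri] - grid$y[i])^2, (xc[ci] - grid$x[i])^2, "+"))
      disc <- d <= r
      canopy <- pmax(h_fin[ri, ci, drop = FALSE] -
                     h_ref[ri, ci, drop = FALSE], 0)[disc]
      vol[i] <- sum(canopy * 100) * config@gsd_m^2 * 1e4
      rm <- radii[i, tp_mid]
      cim <- which(abs(xc - grid$x[i]) <= rm)
      rim <- which(abs(yc - grid$y[i]) <= rm)
      dm <- sqrt(outer((yc[rim] - grid$y[i])^2, (xc[cim] - grid$x[i])^2, "+"))
      dscm <- dm <= rm
      nirv <- nir_m[rim, cim, drop = FALSE][dscm]
      redv <- red_m[rim, cim, drop = FALSE][dscm]
      ndvi_mid[i] <- mean((nirv - redv) / (nirv + redv))
    }
    wm <- config@weight_model
    weight <- pmax(wm$beta_volume * vol + wm$beta_spectral * ndvi_mid +
                   stats::rnorm(n, 0, wm$noise_sd), 1)
    truth <- data.frame(plant_id = grid$plant_id, row = grid$row,
                        col = grid$col, x = grid$x, y = grid$y,
                        vigor = vigor, radius_final_m = radii[, tp_fin],
                        volume_cm3 = vol, ndvi_mid = ndvi_mid,
                        weight_g = weight)
    new("FieldBundle", config = config, gt = gt, layers = layers,
        tp_dat = tps, detections = list(), grid = grid,
        radii = radii, heights = heights, truth = truth)
  })
  bundle@detections <- lapply(seq_along(tps), function(t)
    simulateDetections(bundle, t))
  bundle
}

#' Simulate object-detector output for one flight
#'
#' One tight box per plant with positive rendered radius, each
#' independently dropped with probability `miss_rate` and with Gaussian
#' jitter of `jitter_sd_m` added to each edge (boxes are re-expanded to at
#' least one pixel if jitter degenerates them). Deterministic given the
#' bundle's seed and the time point.
#'
#' @param bundle A [FieldBundle-class].
#' @param tp Time-point index.
#' @return Bounding-box data.frame with a `plant_truth` column giving the
#'   generating plant id (for diagnostics only).
#' @export
simulateDetections <- function(bundle, tp) {
  if (tp < 1L || tp > length(bundle@tp_dat)) stop("no such time point")
  cfg <- bundle@config
  det <- cfg@detector
  seed2 <- as.integer((as.double(cfg@seed) * 7919 + tp * 104729) %%
                      2147483647)
  withr::with_seed(seed2, {
    r <- bundle@radii[, tp]
    keep <- r > 0
    n <- sum(keep)
    jit <- matrix(stats::rnorm(4L * n, 0, det$jitter_sd_m), n, 4L)
    drop <- stats::runif(n) < det$miss_rate
    x <- bundle@grid$x[keep]; y <- bundle@grid$y[keep]
    xmin <- x - r[keep] + jit[, 1]; xmax <- x + r[keep] + jit[, 2]
    ymin <- y - r[keep] + jit[, 3]; ymax <- y + r[keep] + jit[, 4]
    bad <- xmax - xmin < cfg@gsd_m
    mid <- (xmin + xmax) / 2
    xmin[bad] <- mid[bad] - cfg@gsd_m / 2; xmax[bad] <- mid[bad] + cfg@gsd_m / 2
    bad <- ymax - ymin < cfg@gsd_m
    mid <- (ymin + ymax) / 2
    ymin[bad] <- mid[bad] - cfg@gsd_m / 2; ymax[bad] <- mid[bad] + cfg@gsd_m / 2
    if (all(drop))
      return(cbind(boundingBoxes(numeric(0), numeric(0), numeric(0),
                                 numeric(0), source_tp = character(0)),
                   plant_truth = integer(0)))
    out <- boundingBoxes(xmin[!drop], ymin[!drop], xmax[!drop], ymax[!drop],
                         source_tp = tp)
    out$plant_truth <- bundle@grid$plant_id[keep][!drop]
    out
  })
}
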