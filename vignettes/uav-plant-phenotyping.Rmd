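---
title: "Individual-plant phenotyping from multi-temporal UAV imagery: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual-plant phenotyping from multi-temporal UAV imagery: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`uavpheno` turns per-flight UAV orthomosaics and plant detections into
per-plant, per-flight features and uses them to predict individual harvest
weight. This vignette explains the models and procedures, the parameters
that matter, the synthetic-field generator used for validation, and the
numerical conventions and known limitations. Everything shown here is
computed by the package's tests or by `scripts/acceptance.R`; no numbers
are asserted that the code does not produce.

## The geolocation model

An object detector run on several early-season flights produces one
rectangle per visible plant per flight. Two rules turn these into one
georeferenced box per plant:

* **Merging.** Two boxes are related when their intersection area exceeds
  40 % of the *smaller* box's area. The smaller-box denominator makes the
  rule scale-robust when an early-season box sits inside a late-season
  one. Groups are the connected components of this relation — transitive
  closure, because a mid-season box often bridges an early and a late box
  that barely touch each other — and each group is replaced by its
  coordinate-wise envelope. Both of these are interpretations: the
  overlap denominator and the closure rule are not forced by the
  40-percent criterion itself, so they are frozen here and documented.
* **Grid assignment.** The sowing grid (default 45 cm between plants
  within a row, 65 cm between rows) gives each plant a point `Pc`. A box
  with centre `BBc` is indexed to the nearest point within
  `SPd = ‖Pc − BBc‖ < 0.45 m` (the sowing distance). A box can serve at
  most one plant; conflicts are resolved globally, nearest pair first.
  The conflict rule is another free choice — a detector occasionally
  merges two neighbours into one box — and "globally nearest wins" is the
  deterministic option.

Pixel rectangles convert to projected coordinates with the 0-based,
half-open convention, row axis southward: `x = origin_x + col · gsd_x`,
`y = origin_y − row · gsd_y`.

## Raster processing

* **Canopy height.** The photogrammetric point cloud is rasterized by
  per-cell mean; empty cells take the value of the grid-nearest filled
  cell (multi-source dilation). The first flight, taken before the canopy
  closes, serves as the reference surface and is subtracted per pixel;
  negative differences are clamped to zero so soil-level noise can never
  produce negative canopy volume. Whether the study's surface reference
  was per-pixel or a field scalar is unknowable from the outside; the
  per-pixel choice is strictly more general.
* **Registration.** Multispectral layers are first resampled to the RGB
  grid by nearest-neighbour assignment, then aligned by the integer-pixel
  phase-cross-correlation shift between the resampled NIR layer and the
  RGB luminance (0.299 R + 0.587 G + 0.114 B). The NIR-versus-luminance
  pairing is an implementation choice; it needs the two modalities to
  share contrast polarity, which holds for bright canopy on darker soil.
  An estimated shift above `max_shift_px` (default 10) is treated as an
  estimation failure and not applied: co-produced orthomosaics with
  shared ground control disagree by millimetres, not decimetres.
  Sub-pixel refinement is deliberately omitted — at 1 cm GSD the residual
  co-registration error of such imagery is below one pixel.
* **Stack cutting.** The merged box defines the smallest covering
  half-open pixel window on the RGB grid; the same window is cut from
  every layer of every flight, giving the 4-D (flight, layer, row, col)
  stack with `pixel_area = gsd_x · gsd_y · 10⁴ cm²`.

## Vegetation indices and the filter cascade

The registry holds eleven camera-variant indices (GRVI, MGRVI, RGBVI each
for the RGB camera and the MS bands; GNDVI, NDRE, NDVI, RECI, SAVI from
the MS bands). Indices whose absolute Pearson correlation with an
already-retained index exceeds 0.95 are dropped in a greedy pass over a
frozen order (RGB variant before MS variant, then the MS-only indices);
because greedy survivors depend on order, the order is part of the
contract. The pruning matrix is built from each plant's *seasonal mean*
of per-flight VI medians: averaging over flights removes the growth
trajectory that every index shares, so the pruning measures between-plant
redundancy rather than the common time trend.

Three noise filters clean each plant window:

1. **Soil mask** — 2-cluster k-means (10 restarts under a fixed seed) on
   the per-pixel vectors of the VI stack; the cluster with the lower mean
   NDVI is soil. Labelling by the NDVI rule, not by cluster index, makes
   the decision invariant to initialization. A window fully covered by
   uniform canopy has nothing to separate and is treated as
   all-vegetation rather than failing the plant.
2. **Contour filter** — 8-connected components of the vegetation mask
   smaller than 5 % of the largest component are removed. The threshold
   is relative because absolute pixel counts would not transfer across
   window sizes; 5 % removes speckle while keeping any genuinely split
   leaf area.
3. **Histogram equalization** — applied to the RGB layers only, mapping
   each value to `round(255 · cdf(v))` on a 256-level scale. RGB medians
   are therefore computed on the equalized 0–255 scale, exactly in
   cascade order; the MS bands stay in reflectance units.

Each stack is then centred: the convex hull of the first-flight
vegetation pixels gives a centre as the mean of its *vertices* (not the
area centroid — a deliberate, documented reading of "averaging its
vertices"), all layers are shifted by the integer offset that puts this
centre on the window centre, and the central 70 % of each dimension is
retained. Retaining 70 % (rather than removing 70 %) is the
interpretation that does not truncate mature plants.

## Features

Per plant and flight: medians of the 3 RGB (equalized) and 5 MS layers
over the vegetation mask; medians of the retained VIs; and three
height-derived features — plant height as the 90th percentile of the
canopy-height image (linear-interpolation quantile), leaf angle, and
volume `Σ H_i · a_p` in cm³ (heights converted to cm first). The leaf
angle of a pixel is the angle between its vector
`P_p = (x_p − x_c, y_p − y_c, H_p)` (metres, anchored at the window
centre on the ground plane) and the vertical unit vector; the aggregate
is the per-pixel **median**, chosen for robustness since only a single
per-plant angle is wanted from a per-pixel definition. The anchor height
of the vertical reference is likewise unspecified in general; ground
level is the choice that makes a flat canopy read 90°.

Standardization (centre, divide by population SD) is always fitted on
training rows only — per split and per CV fold — and the stored
statistics transform held-out rows. Columns that are constant on a
training fold are dropped for that fit; they carry no information and
break PLS otherwise.

## Weight modeling

Five regressor families with deliberately standard search grids: lasso
and ridge over a 13-point log-spaced penalty grid 1e-3..1e3; PLS with
1..min(20, p) components; linear-kernel epsilon-SVR with cost over seven
log-spaced points 1e-2..1e2 and epsilon 0.1; random forest with 500
trees, `mtry ∈ {⌈p/3⌉, ⌈√p⌉}` and minimum node size {1, 5}. Grids are
spanned, not tuned: they cover the regularization range a practitioner
would scan. Hyperparameters are chosen by mean five-fold CV R² and the
winner is refitted on all training rows. The data split is 90/10 with
`floor(n/10)` test rows; folds are a seeded uniform shuffle without
stratification. One fold assignment can be shared between feature
selection and model assessment (`folds` argument), honouring the
convention that both stages see the same partitions.

Feature selection: exhaustive search enumerates all subsets (refused
above p = 15), sequential forward selection adds the best-scoring
feature per step (so the selection path has the prefix property), and
the embedded method ranks features by random-forest mean decrease in
impurity normalized to sum to one. The wrapper estimator defaults to
lasso with a small penalty grid.

Temporal schemes: `all_tps`; greedy fixed-interval walks (7/15/30 days)
that take the earliest flight at least N days after the previously
selected one — the right rule for irregular flight calendars; and the
growth-stage anchors 12, 34, 56, 80, 101 DAT mapped to the nearest
available flight (ties to the earlier). Designs are either single-flight
(the flight at the cutoff) or cumulative (all selected flights up to the
cutoff); the days-prior-to-harvest sweep walks the cutoff across each
scheme's flights.

Metrics: `R² = 1 − Σ(y−ŷ)²/Σ(y−ȳ)²` as printed, and
`RMSE = sqrt(Σ(y−ŷ)²/n)`. A widely circulated form of the RMSE formula
omits the division by n inside the root; only the mean form yields
g/plant at crop magnitudes, so the conventional form is implemented and
the discrepancy is noted here.

## The synthetic field

`generateField()` renders a complete study: plants on the 45 × 65 cm
grid as radially symmetric cosine-tapered height discs (smooth convex
support, so hull centering and contour filtering are genuinely
exercised), with uniform per-plant reflectance on a noisy soil
background. Defaults, chosen once as a realistic cabbage field and not
revisited:

| parameter | default | meaning |
|---|---|---|
| grid | 10 × 10 plants | ~100-plant field at 1 cm GSD |
| flights | 12–102 DAT, 8 TPs | ~13-day revisit over a 104-day season |
| max radius / height | 0.18 m / 0.25 m | ~36 cm mature rosette |
| logistic rate / midpoint | 0.09 / 40 DAT | near-plateau by ~90 DAT |
| vigor | lognormal, sdlog 0.2 | ~30 % CV in plant volume |
| weight model | 0.16 g/cm³ · V + 2000 g · NDVI_mid + N(0, 150 g) | ~3 kg ± 0.7 kg plants |
| detector | miss 5 %, jitter 2 cm/edge | imperfect detections |
| soil noise | sd 0.01 reflectance | k-means has real work to do |

Reflectance has two independent per-plant latents — a nutrition-like
factor driving NIR/red (the one the weight model's spectral term uses)
and a chlorophyll-like factor driving green/red-edge — both scaled by a
mid-season bump that is *exactly zero* by harvest (truncated Gaussian).
That shape encodes senescent convergence: every plant looks the same at
harvest, so the mid-season flights carry weight-relevant spectral
information that the final flight cannot supply. This is what makes
multi-temporal designs strictly more informative than the final flight
alone on this generator — the package's testable analogue of the
empirical finding that cumulative schemes beat single-flight ones. The
nutrition latent is deliberately independent of plant size; tying
spectral signal to vigor would let final volume proxy it and erase the
multi-temporal advantage.

Ground truth is computed from the *emitted rasters*: final-flight
surface-subtracted volume over each plant's disc, and mean NDVI over the
disc at the flight nearest the spectral midpoint. With the weight noise
at zero, ordinary least squares on these recomputed quantities recovers
the generating coefficients exactly — the generator cannot drift from
its own truth definition. Reflectances are quantized to 16-bit steps at
render time so that written TIFFs round-trip losslessly; heights are
quantized to 16-bit fractions of 10 m (0.15 mm steps).

What the generator does **not** emulate: photorealistic texture, shadow
and illumination gradients, SfM reconstruction error, detector
confidence scores, plant-shape asymmetry, overlapping canopies, and
real senescence spectra. Passing tests therefore demonstrate the
pipeline's correctness and its statistical behaviour under controlled
conditions, not performance on real imagery.

## Numerical choices and degenerate inputs

* Quantiles use linear interpolation between order statistics (R type 7).
* Standard deviations in standardization are population SDs (divisor n).
* Phase correlation reports integer shifts resolved to (−N/2, N/2];
  constant images are an error (undefined phase).
* k-means soil masking with exactly two distinct pixel vectors reduces
  to direct assignment; all-identical windows are an error at the
  operation level and an all-vegetation fallback at the pipeline level.
* VI cells with a zero denominator become missing, as do fully masked
  medians; design matrices drop all-missing columns (e.g. leaf angle at
  the surface-reference flight, where canopy height is identically zero)
  before dropping incomplete rows.
* Detector jitter that degenerates a box is re-expanded to one pixel
  around its midpoint.
* Hyperparameter configurations that cannot be fitted on a fold (e.g.
  more PLS components than the design's rank) are scored out of the grid
  search instead of aborting it.

## Problem sizes

The bundled experiments run on the 10 × 10-plant default field (8
flights, ~685 × 505 px rasters) — large enough for 90/10 splits and
five-fold CV to be meaningful, small enough that the full suite and the
acceptance script each run in minutes on a single core. Fields up to the
26 × 46 plants of a real trial are a matter of memory and patience, not
code paths.

## Known limitations

* Integer-pixel registration only; genuinely sub-pixel misalignment is
  not corrected (nor is it, at 1 cm GSD, worth correcting).
* The k-means soil mask assumes bimodal VI structure; heavy shadow or
  senescent soil cover would need a third class.
* Exhaustive selection is exponential and hard-refused above 15
  features; use SFS there.
* `mixOmics` PLS predictions require full-rank reduced designs; the
  grid-search guard handles this, but heavily duplicated columns waste
  candidate components.
* The greedy interval walk can select flights slightly farther apart
  than the nominal interval on sparse calendars — the correct behaviour
  for irregular revisit schedules, but worth knowing when comparing
  resolutions.
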