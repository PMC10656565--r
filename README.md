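# uavpheno

Individual-plant phenotyping and harvest-weight prediction from
multi-temporal UAV imagery.

Field crops that are sold by the piece — Chinese cabbage is the motivating
case — need phenotyping at the *individual plant* level, not the canopy
level. Given per-flight orthomosaics (RGB and five-band multispectral), a
height layer derived from photogrammetric point clouds, and per-flight
plant detections (e.g. from an object detector), `uavpheno`:

1. **Consolidates detections.** Boxes from different flights whose
   intersection exceeds 40 % of the smaller box are grouped (transitively)
   and replaced by their envelope, giving one georeferenced box per plant.
   Each box is indexed to the sowing grid by the spatial distance
   `SPd = sqrt((Pc_x − BBc_x)² + (Pc_y − BBc_y)²)` between the grid point
   `Pc` and the box centre `BBc`, accepting the nearest box with
   `SPd < 0.45 m` (the within-row sowing distance).
2. **Builds per-plant 4-D image stacks** (flight × layer × row × col):
   height rasters are surface-referenced against the first flight,
   multispectral layers are co-registered to the RGB geometry by phase
   cross-correlation and nearest-neighbour resampling, and each plant's
   pixel window is cut from every layer of every flight.
3. **Filters and summarizes.** Eleven vegetation indices (GRVI, MGRVI,
   RGBVI in RGB and MS variants; GNDVI, NDRE, NDVI, RECI, SAVI) are
   computed and pruned at Pearson |r| > 0.95; a three-stage noise cascade
   (2-cluster k-means soil mask on the VI stack, contour-area filter,
   RGB histogram equalization) cleans each window; stacks are centred on
   the first-flight convex hull and cropped to the central 70 %. Per
   flight and plant, the features are the 8 layer medians, the retained VI
   medians, the 90th-percentile plant height, the median leaf angle
   `arccos(P_p · V_c / ‖P_p‖‖V_c‖)`, and the canopy volume
   `Σ H_i · a_p` (cm³).
4. **Predicts weight.** Five regressors (PLS, lasso, ridge, linear SVM,
   random forest) are tuned by five-fold cross-validation on a 90/10
   split, with exhaustive, sequential-forward and random-forest-importance
   feature selection, under five temporal resolutions (all flights;
   7-/15-/30-day greedy intervals; growth-stage anchors 12/34/56/80/101
   DAT), in single-flight or cumulative mode, including a
   days-prior-to-harvest sweep. Metrics are `R² = 1 − Σ(y−ŷ)²/Σ(y−ȳ)²`
   and `RMSE = sqrt(mean((y−ŷ)²))` in g/plant.

A fully specified synthetic-field generator (`fieldConfig()`,
`generateField()`) renders cosine-tapered plants with logistic growth,
vigor variation, a mid-season spectral signal, simulated detector output
and ground-truth weights, so the complete pipeline is testable without
flying anything.

## Worked example

```r
library(uavpheno)

cfg    <- fieldConfig(seed = 7)        # 10 x 10 plants, 8 flights, 1 cm GSD
bundle <- generateField(cfg)
bundle
#> FieldBundle: 100 plants, 8 TPs, rasters 685 x 505 px
#>   weight: 3371 +/- 733 g/plant

res <- processBundle(bundle)
res$accuracy
#> [1] 1
res$retained_vis
#> [1] "GRVI-RGB"  "RGBVI-RGB" "GNDVI"     "NDRE"

ft  <- res$features
sp  <- splitData(nrow(featureValues(ft)), seed = 3)
des <- buildDesign(ft, temporalScheme("all_tps"))        # cumulative
cv  <- crossValidate(modelSpec("lasso"), des$X[sp$train, ],
                     des$y[sp$train], seed = 2)
evaluateOnTest(cv, des$X[sp$test, ], des$y[sp$test])[c("r2", "rmse")]
#> $r2
#> [1] 0.981
#> $rmse
#> [1] 129.8
```

All 100 plants are detected and assigned; with every flight's features the
lasso explains ~98 % of held-out weight variance on this synthetic field,
with an error of ~130 g/plant against a 733 g/plant spread. A single-flight
design on the same field reaches a mean CV R² of only ~0.78, showing what
the mid-season spectral information adds.

A thin CLI over the same functions lives in `inst/scripts/uavpheno.R`
(subcommands `synth-field`, `geolocate`, `features`, `sweep`).

## Vignette

`vignettes/uav-plant-phenotyping.Rmd` documents the model assumptions,
parameter choices, what the synthetic generator does and does not emulate,
and the package's numerical conventions.
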