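# shared fixtures, built once per test run and cached

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small noisy field: 4 x 4 plants, 5 flights
small_bundle <- function() cached("small_bundle", {
  generateField(fieldConfig(n_rows = 4L, n_cols = 4L,
                            timepoints_dat = c(12L, 34L, 56L, 80L, 101L),
                            seed = 42L))
})

# same layout with every noise source zeroed
small_noiseless_bundle <- function() cached("small_noiseless", {
  generateField(noiselessConfig(
    fieldConfig(n_rows = 4L, n_cols = 4L,
                timepoints_dat = c(12L, 34L, 56L, 80L, 101L), seed = 42L)))
})

# random axis-aligned boxes for merge tests
random_boxes <- function(n, seed, span = 5) {
  withr::with_seed(seed, {
    x <- runif(n, 0, span); y <- runif(n, 0, span)
    w <- runif(n, 0.2, 1.2); h <- runif(n, 0.2, 1.2)
    boundingBoxes(x, y, x + w, y + h, source_tp = seq_len(n))
  })
}

# brute-force union-find oracle over the pairwise overlap predicate
oracle_merge_groups <- function(boxes, threshold = 0.40) {
  n <- nrow(boxes)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    ix <- min(boxes$xmax[i], boxes$xmax[j]) - max(boxes$xmin[i], boxes$xmin[j])
    iy <- min(boxes$ymax[i], boxes$ymax[j]) - max(boxes$ymin[i], boxes$ymin[j])
    inter <- max(ix, 0) * max(iy, 0)
    a1 <- (boxes$xmax[i] - boxes$xmin[i]) * (boxes$ymax[i] - boxes$ymin[i])
    a2 <- (boxes$xmax[j] - boxes$xmin[j]) * (boxes$ymax[j] - boxes$ymin[j])
    if (inter / min(a1, a2) > threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# render one analytic cosine-tapered disc plant as a height matrix
render_disc <- function(radius_m, height_m, gsd_m = 0.01, pad_m = 0.05) {
  half <- radius_m + pad_m
  n <- ceiling(2 * half / gsd_m)
  ctr <- (n + 1) / 2
  xy <- (seq_len(n) - ctr) * gsd_m
  d <- sqrt(outer(xy^2, xy^2, "+"))
  h <- ifelse(d <= radius_m, height_m * cos(pi * d / (2 * radius_m)), 0)
  h
}

# closed-form volume of the cosine-tapered disc, via numeric integration
disc_volume_cm3 <- function(radius_m, height_m) {
  f <- function(r) height_m * cos(pi * r / (2 * radius_m)) * 2 * pi * r
  stats::integrate(f, 0, radius_m, rel.tol = 1e-10)$value * 1e6
}
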