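# Shared fixtures and independent oracles. Oracles are deliberately written
# with different algorithms/code paths than the package internals.

tiny_config <- function(seed = 11, n_species = 10, n_minimal = 2,
                        n_zones = 6, ...) {
  synthetic_config(bbox = c(10, -4, 20, 4), resolution = 0.05,
                   n_species = n_species, n_records_range = c(30, 80),
                   cluster_sd = 0.3, n_zones = n_zones, years = 2001:2020,
                   seed = seed, n_minimal = n_minimal, ...)
}

# one shared small world, built once per test run
.world_cache <- new.env(parent = emptyenv())
test_world <- function() {
  if (is.null(.world_cache$w)) .world_cache$w <- gen_world(tiny_config())
  .world_cache$w
}

# ... and one shared pipeline result on it
test_analysis <- function() {
  if (is.null(.world_cache$res)) .world_cache$res <- rrc_pipeline(test_world())
  .world_cache$res
}

# Vectorized point-in-convex-polygon (CCW vertices), strict interior not
# required; boundary counts as inside.
pip_convex <- function(px, py, poly) {
  inside <- rep(TRUE, length(px))
  nv <- nrow(poly)
  for (e in seq_len(nv)) {
    a <- poly[e, ]; b <- poly[if (e == nv) 1L else e + 1L, ]
    inside <- inside &
      ((b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1]) >= 0)
  }
  inside
}

# Monte-Carlo style coverage-weighted extent area oracle: a regular
# n_side x n_side lattice of sample points per cell; per-cell coverage is
# the fraction of lattice points inside the polygon.
lattice_extent_area <- function(poly, zones, zone_raster, water, grid,
                                n_side = 100) {
  if (rrcmap:::poly_area_signed(poly) < 0)
    poly <- poly[rev(seq_len(nrow(poly))), ]
  areas <- cell_area_km2(grid)
  total <- 0
  u <- (seq_len(n_side) - 0.5) / n_side
  for (row in seq_len(grid$nrow)) {
    n <- grid$ymax - (row - 1) * grid$res
    s <- n - grid$res
    for (col in seq_len(grid$ncol)) {
      z <- zone_raster$values[row, col]
      if (is.na(z) || !(z %in% zones) || water$values[row, col] == 1) next
      w0 <- grid$xmin + (col - 1) * grid$res
      px <- rep(w0 + u * grid$res, each = n_side)
      py <- rep(s + u * grid$res, times = n_side)
      frac <- mean(pip_convex(px, py, poly))
      total <- total + frac * areas[row]
    }
  }
  total
}

# O(n^2) repeated-medians oracle: builds the full pairwise slope matrix
# explicitly, then takes medians by sorting.
siegel_oracle <- function(x, y) {
  n <- length(x)
  M <- matrix(NA_real_, n, n)
  for (i in 1:n) for (j in 1:n)
    if (i != j) M[i, j] <- (y[j] - y[i]) / (x[j] - x[i])
  ms <- apply(M, 1, stats::median, na.rm = TRUE)
  slope <- stats::median(ms)
  list(slope = slope, intercept = stats::median(y - slope * x))
}
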