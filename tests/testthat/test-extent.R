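test_that("mcp with full inclusion is the plain convex hull", {
  lon <- c(0, 1, 1, 0, 0.5)
  lat <- c(0, 0, 1, 1, 0.5)
  h <- mcp(lon, lat, inclusion = 1)
  expect_false(h$degenerate)
  expect_equal(nrow(h$coords), 4)
  expect_equal(rrcmap:::poly_area(h$coords), 1)
  expect_equal(sort(h$kept), 1:5)
})

test_that("mcp drops the centroid-farthest records before hull construction", {
  set.seed(31)
  lon <- rnorm(100, 20, 0.5); lat <- rnorm(100, -5, 0.5)
  h <- mcp(lon, lat, inclusion = 0.95)
  expect_equal(length(h$dropped), 5)
  # oracle: sort by great-circle distance from the coordinate centroid
  d <- geosphere::distHaversine(cbind(lon, lat), c(mean(lon), mean(lat)))
  keep_idx <- order(d)[1:95]
  oracle_hull <- grDevices::chull(lon[keep_idx], lat[keep_idx])
  expect_setequal(h$kept, keep_idx)
  expect_equal(rrcmap:::poly_area(h$coords),
               rrcmap:::poly_area(cbind(lon[keep_idx], lat[keep_idx])[
                 oracle_hull, ]))
})

test_that("collinear records give a degenerate hull and fewer than 5 error", {
  h <- mcp(seq(0, 1, length.out = 6), seq(0, 2, length.out = 6),
           inclusion = 1)
  expect_true(h$degenerate)
  expect_error(refine_extent(h, 1, rrc_raster(grid_spec(0, 0, 1, 3, 3), 1),
                             rrc_raster(grid_spec(0, 0, 1, 3, 3), 0),
                             grid_spec(0, 0, 1, 3, 3)), "degenerate")
  expect_error(mcp(1:4, 1:4), "at least 5")
})

test_that("suitable zones follow the 5% zone share and 25% cover rules", {
  # coarse grid: each 1-km buffer sits inside a single 0.5-deg cell
  g <- grid_spec(0, 0, res = 0.5, ncol = 20, nrow = 10)
  zvals <- matrix(1L, 10, 20)
  zvals[, 11:20] <- 2L
  zr <- rrc_raster(g, zvals)
  lon_z1 <- rep(seq(0.25, 4.75, by = 0.5), length.out = 96)
  lon_z2 <- rep(seq(5.25, 9.75, by = 0.5), length.out = 4)
  lat <- rep(2.25, 100)
  # 96 records in zone 1 cells, 4 in zone 2: zone 2 share 4% < 5% -> dropped
  z <- suitable_zones(c(lon_z1, lon_z2), lat, zr)
  expect_identical(z, 1L)
  # at exactly 5% the zone is retained (inclusive threshold)
  z5 <- suitable_zones(c(lon_z1[1:95], lon_z2, lon_z2[1]), lat, zr)
  expect_identical(z5, c(1L, 2L))
  # single-zone raster: that zone
  zr1 <- rrc_raster(g, matrix(7L, 10, 20))
  expect_identical(suitable_zones(3, 2, zr1), 7L)
  # buffer leaving the raster is an error
  expect_error(suitable_zones(-0.001, 2, zr), "cover")
})

test_that("refined extent area is the coverage-weighted cell-area sum", {
  g <- grid_spec(0, 0, res = 1, ncol = 6, nrow = 6)
  zr <- rrc_raster(g, matrix(1L, 6, 6))
  land <- rrc_raster(g, matrix(0L, 6, 6))
  # polygon exactly covering the 4 cells [2,4]x[2,4]
  poly <- cbind(c(2, 4, 4, 2), c(2, 2, 4, 4))
  ext <- refine_extent(poly, 1L, zr, land, g)
  a <- cell_area_km2(g)
  rows <- c(4, 3)  # lat band [2,3) is grid row 4, [3,4) is row 3
  expect_equal(nrow(ext$cells), 4)
  expect_true(all(abs(ext$cells$w - 1) < 1e-12))
  expect_equal(ext$eoo_km2, 2 * a[rows[1]] + 2 * a[rows[2]])

  # flooding 2 of 4 equal-latitude cell pairs halves the area
  wvals <- matrix(0L, 6, 6)
  wvals[rows, 3] <- 1L   # the eastern column of the square is water
  ext2 <- refine_extent(poly, 1L, zr, rrc_raster(g, wvals), g)
  expect_equal(ext2$eoo_km2, ext$eoo_km2 / 2)

  # half-cell coverage gives weight 0.5
  poly_half <- cbind(c(2, 2.5, 2.5, 2), c(2, 2, 3, 3))
  ext3 <- refine_extent(poly_half, 1L, zr, land, g)
  expect_equal(nrow(ext3$cells), 1)
  expect_equal(ext3$cells$w, 0.5, tolerance = 1e-12)
})

test_that("coverage weights match a dense lattice sampling oracle", {
  w <- test_world()
  g <- w$zones$grid
  set.seed(42)
  # an irregular convex polygon in the middle of the study region
  ang <- sort(runif(7, 0, 2 * pi))
  poly <- cbind(14 + 1.2 * cos(ang), 0.5 + 0.9 * sin(ang))
  poly <- rrcmap:::convex_hull(poly)
  zones <- sort(unique(as.vector(w$zones$values)))
  ext <- refine_extent(poly, zones, w$zones, w$water, g)
  # restrict the oracle to the polygon's bounding block for speed
  sub <- function(r, rows, cols) rrc_raster(
    grid_spec(g$xmin + (min(cols) - 1) * g$res,
              g$ymax - max(rows) * g$res, g$res,
              length(cols), length(rows)),
    r$values[rows, cols, drop = FALSE])
  ci <- rrcmap:::cell_index(g, range(poly[, 1]), rev(range(poly[, 2])))
  rows <- (ci$row[1] - 1):(ci$row[2] + 1); cols <- (ci$col[1] - 1):(ci$col[2] + 1)
  gsub <- sub(w$zones, rows, cols)$grid
  oracle <- lattice_extent_area(poly, zones, sub(w$zones, rows, cols),
                                sub(w$water, rows, cols), gsub, n_side = 100)
  expect_equal(ext$eoo_km2, oracle, tolerance = 0.005)
  expect_true(all(ext$cells$w > 0 & ext$cells$w <= 1))
})

test_that("masking is monotone and order-insensitive", {
  w <- test_world()
  g <- w$zones$grid
  poly <- cbind(c(13, 16, 16, 13), c(-1, -1, 1.5, 1.5))
  all_zones <- sort(unique(as.vector(w$zones$values)))
  some <- all_zones[1:2]
  e_small <- refine_extent(poly, some, w$zones, w$water, g)
  e_big <- refine_extent(poly, all_zones, w$zones, w$water, g)
  expect_lte(e_small$eoo_km2, e_big$eoo_km2)
  # unmasked polygon area bounds the refined area
  no_water <- rrc_raster(g, matrix(0L, g$nrow, g$ncol))
  e_free <- refine_extent(poly, all_zones, w$zones, no_water, g)
  expect_lte(e_big$eoo_km2, e_free$eoo_km2 + 1e-9)
})

test_that("antimeridian-crossing polygons are rejected", {
  g <- grid_spec(-180, 0, res = 1, ncol = 360, nrow = 10)
  zr <- rrc_raster(g, matrix(1L, 10, 360))
  poly <- cbind(c(-179, 179, 179, -179), c(1, 1, 3, 3))
  expect_error(refine_extent(poly, 1L, zr, rrc_raster(g, matrix(0L, 10, 360)),
                             g), "antimeridian")
})

test_that("extent size classes split at 5,000 and 20,000 km^2", {
  expect_equal(extent_class(c(25000, 10000, 0, 20000, 5000, 4999.9)),
               c("wide", "regional", "local", "regional", "local", "local"))
  expect_error(extent_class(-1), "negative")
})
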