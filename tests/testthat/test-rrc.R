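mk_grid <- function(n = 4) grid_spec(0, 0, res = 1, ncol = n, nrow = n)
mk_r <- function(v, g = mk_grid()) rrc_raster(g, matrix(v, g$nrow, g$ncol))

# full-coverage extent over every cell of a small grid
full_extent <- function(g) {
  cells <- expand.grid(row = seq_len(g$nrow), col = seq_len(g$ncol))
  cells$w <- 1
  cells$area_km2 <- cell_area_km2(g)[cells$row]
  structure(list(polygon = cbind(c(g$xmin, g$xmax, g$xmax, g$xmin),
                                 c(g$ymin, g$ymin, g$ymax, g$ymax)),
                 zones = 1L, cells = cells,
                 eoo_km2 = sum(cells$w * cells$area_km2),
                 empty = FALSE, grid = g),
            class = "extent_mask")
}

test_that("cropland change excludes the 2000-03 baseline epoch", {
  g <- mk_grid(3)
  zero <- matrix(0, 3, 3)
  base <- zero; base[1, 1] <- 1          # cropland only in baseline
  e3 <- zero; e3[2, 2] <- 1              # first cropland in 2008-11
  maps <- list(rrc_raster(g, base), rrc_raster(g, zero), rrc_raster(g, e3),
               rrc_raster(g, zero), rrc_raster(g, zero))
  ch <- build_cropland_change(maps)
  expect_equal(ch$values[1, 1], 0)
  expect_equal(ch$values[2, 2], 1)
  expect_equal(attr(ch, "divisor"), 16)
  expect_error(build_cropland_change(maps[1:4]), "5 epoch")

  # random epochs vs cellwise truth-table oracle
  set.seed(14)
  eps <- lapply(1:5, function(i) rrc_raster(g, matrix(rbinom(9, 1, 0.4), 3, 3)))
  got <- build_cropland_change(eps)$values
  for (i in 1:3) for (j in 1:3) {
    v <- vapply(eps, function(r) r$values[i, j], numeric(1))
    expect_equal(got[i, j], as.integer(any(v[2:5] == 1) && v[1] == 0))
  }
})

test_that("tree-cover decline needs a 5-point drop in one comparison", {
  g <- mk_grid(1)
  tc <- function(a, b, c, d) list(mk_r(a, g), mk_r(b, g), mk_r(c, g),
                                  mk_r(d, g))
  expect_equal(build_treecover_decline(tc(80, 80, 80, 80))$values[1, 1], 0)
  expect_equal(build_treecover_decline(tc(80, 74, 74, 74))$values[1, 1], 1)
  # cumulative gradual decline of 3 per step does not count
  expect_equal(build_treecover_decline(tc(80, 77, 74, 71))$values[1, 1], 0)
  expect_equal(attr(build_treecover_decline(tc(1, 1, 1, 1)), "divisor"), 15)
  expect_error(build_treecover_decline(tc(120, 1, 1, 1)), "\\[0, 100\\]")
  # per-comparison rule on random stacks vs direct evaluation
  set.seed(15)
  g4 <- mk_grid(4)
  layers <- lapply(1:4, function(i)
    rrc_raster(g4, matrix(runif(16, 0, 100), 4, 4)))
  got <- build_treecover_decline(layers)$values
  v <- lapply(layers, `[[`, "values")
  oracle <- (v[[1]] - v[[2]] >= 5) | (v[[2]] - v[[3]] >= 5) |
    (v[[3]] - v[[4]] >= 5)
  expect_equal(got, oracle * 1L)
})

test_that("built-up and deforestation layers binarize correctly", {
  g <- mk_grid(2)
  b <- build_builtup_change(rrc_raster(g, matrix(c(0, 1, 2, 2), 2, 2)))
  expect_equal(as.vector(b$values), c(0, 0, 1, 1))  # stable (1) not counted
  expect_equal(attr(b, "divisor"), 20)
  expect_error(build_builtup_change(mk_r(3, g)), "\\{0, 1, 2\\}")
  d <- build_deforestation(rrc_raster(g, matrix(c(1, 0, 0, 1), 2, 2)))
  expect_equal(as.vector(d$values), c(1, 0, 0, 1))
  expect_equal(attr(d, "divisor"), 20)
  expect_error(build_deforestation(mk_r(2, g)), "binary")
})

test_that("unidirectional rates are changed area over extent per year", {
  g <- mk_grid(4)
  ext <- full_extent(g)
  # no change: 0; full conversion over 20 years: exactly 5 %/yr
  expect_equal(unidirectional_rrc(ext, mk_r(0, g), 20)$rate, 0)
  expect_equal(unidirectional_rrc(ext, mk_r(1, g), 20)$rate, 5)
  # equal-area cells: 3 of 10 changed with divisor 16 -> 100*0.3/16
  g1 <- grid_spec(0, 0, res = 0.1, ncol = 10, nrow = 1)
  ext1 <- full_extent(g1)
  ch <- matrix(0, 1, 10); ch[1, c(2, 5, 9)] <- 1
  got <- unidirectional_rrc(ext1, rrc_raster(g1, ch), 16)$rate
  expect_equal(got, 100 * 0.3 / 16)
  # rates live in [0, 100/n_years]
  set.seed(16)
  for (k in 1:10) {
    ch <- rrc_raster(g, matrix(rbinom(16, 1, runif(1)), 4, 4))
    r <- unidirectional_rrc(ext, ch, 20)$rate
    expect_gte(r, 0); expect_lte(r, 100 / 20)
  }
  expect_error(unidirectional_rrc(ext, mk_r(0, mk_grid(5)), 20), "grid")
})

test_that("bidirectional rates recover planted trends and zero the rest", {
  g <- mk_grid(4)
  ext <- full_extent(g)
  yrs <- 2001:2020
  # constant burned area: slope 0, not significant, rate 0
  st0 <- annual_stack("burned", yrs, rep(list(matrix(0.2, 4, 4)), 20), g)
  r0 <- bidirectional_rrc(ext, st0, "sum_area")
  expect_identical(r0$rate, 0)
  expect_true(r0$nonsignificant_zeroed)

  # noiseless planted burned-area slope b km^2/yr -> rate 100*b/A
  A <- ext$eoo_km2
  b <- 7.5
  frac_per_yr <- b / A
  st1 <- annual_stack("burned", yrs, lapply(seq_along(yrs), function(i)
    matrix(0.1 + frac_per_yr * (i - 1), 4, 4)), g)
  r1 <- bidirectional_rrc(ext, st1, "sum_area")
  expect_true(r1$significant)
  expect_equal(r1$rate, 100 * b / A, tolerance = 1e-10)

  # climate slope 0.02 degC/yr, noiseless -> rate exactly 0.02
  st2 <- annual_stack("tmin", yrs, lapply(seq_along(yrs), function(i)
    matrix(5 + 0.02 * (i - 1), 4, 4)), g)
  r2 <- bidirectional_rrc(ext, st2, "weighted_mean")
  expect_equal(r2$rate, 0.02, tolerance = 1e-12)
  expect_error(bidirectional_rrc(ext, st2, "weighted_mean",
                                 years = 2001:2002), "3 years")
})

test_that("decadal re-windowing returns the same constant planted slope", {
  g <- mk_grid(3)
  ext <- full_extent(g)
  yrs <- 2001:2020
  st <- annual_stack("vpd", yrs, lapply(seq_along(yrs), function(i)
    matrix(800 + 3 * (i - 1), 3, 3)), g)
  full <- bidirectional_rrc(ext, st, "weighted_mean")
  d1 <- bidirectional_rrc(ext, st, "weighted_mean", years = 2001:2010)
  d2 <- bidirectional_rrc(ext, st, "weighted_mean", years = 2011:2020)
  expect_equal(d1$rate, full$rate, tolerance = 1e-10)
  expect_equal(d2$rate, full$rate, tolerance = 1e-10)
  expect_equal(d1$n_years, 10)
})

test_that("annual reductions of monthly layers match cellwise oracles", {
  g <- mk_grid(3)
  set.seed(18)
  monthly <- lapply(1:12, function(i)
    rrc_raster(g, matrix(rnorm(9, 20, 5), 3, 3)))
  mm <- annual_min_max_temperature(monthly)
  ms <- annual_mean_seasonality(monthly)
  arr <- simplify2array(lapply(monthly, `[[`, "values"))
  for (i in 1:3) for (j in 1:3) {
    v <- arr[i, j, ]
    expect_equal(mm$min$values[i, j], min(v))
    expect_equal(mm$max$values[i, j], max(v))
    expect_equal(ms$mean$values[i, j], mean(v))
    expect_equal(ms$sd$values[i, j], sd(v))
  }
  expect_error(annual_min_max_temperature(monthly[1:11]), "12")
  # constant months: sd 0, min = max
  const <- rep(list(mk_r(7, g)), 12)
  expect_true(all(annual_mean_seasonality(const)$sd$values == 0))
  expect_equal(annual_min_max_temperature(const)$min$values,
               annual_min_max_temperature(const)$max$values)
  # 6/6 two-level alternation with amplitude a: sd = a * sqrt(12/11)
  a <- 2.5
  alt <- lapply(rep(c(-a, a), 6), function(s) mk_r(10 + s, g))
  expect_equal(annual_mean_seasonality(alt)$sd$values[1, 1],
               a * sqrt(12 / 11))
})

test_that("outlier removal uses the 3x interpercentile rule", {
  rates <- data.frame(species = sprintf("s%03d", 1:100),
                      cropland = rep(1, 100))
  expect_equal(nrow(remove_outliers(rates)$removed), 0)

  set.seed(19)
  rates$cropland <- rnorm(100)
  q <- quantile(rates$cropland, c(0.01, 0.99), names = FALSE)
  bound <- q[2] + 3 * (q[2] - q[1])
  rates$cropland[7] <- 10 * abs(bound)
  out <- remove_outliers(rates)
  expect_true("s007" %in% out$removed$species)
  expect_false("s007" %in% out$table$species)
  # survivors all lie inside the band recomputed directly
  q2 <- quantile(rates$cropland, c(0.01, 0.99), names = FALSE)
  ipr <- q2[2] - q2[1]
  inside <- rates$cropland >= q2[1] - 3 * ipr & rates$cropland <= q2[2] + 3 * ipr
  expect_setequal(out$table$species, rates$species[inside])
})

test_that("minimal-area imputation is mean per cell then median across cells", {
  # one minimal species sharing a 1-deg cell with a single valued neighbour
  occ <- data.frame(species = c("mini", "val1"),
                    lon = c(10.2, 10.7), lat = c(3.1, 3.9), label = "AAA")
  rrc <- data.frame(species = "val1", cropland = 1.25)
  imp <- impute_minimal_species("mini", occ, rrc)
  expect_equal(imp$cropland, 1.25)

  # species present in 3 cells whose cell means are 1, 2, 9 -> median 2
  occ2 <- data.frame(
    species = c("mini", "mini", "mini", "a", "b", "c"),
    lon = c(0.5, 1.5, 2.5, 0.6, 1.6, 2.6),
    lat = 0.5, label = "AAA")
  rrc2 <- data.frame(species = c("a", "b", "c"), cropland = c(1, 2, 9))
  expect_equal(impute_minimal_species("mini", occ2, rrc2)$cropland, 2)

  # no valued neighbour anywhere: NA
  occ3 <- data.frame(species = c("mini", "far"), lon = c(0.5, 40),
                     lat = c(0.5, 40), label = "AAA")
  expect_true(is.na(impute_minimal_species("mini", occ3,
    data.frame(species = "far", cropland = 3))$cropland))
})

test_that("imputation matches a brute-force two-stage oracle on a world", {
  w <- test_world()
  res <- test_analysis()
  minimal <- res$manifest$species_minimal
  expect_gt(length(minimal), 0)  # the fixture forces minimal species
  rrc <- res$rrc_clean
  imp <- res$imputed
  cell_of <- function(lon, lat) paste(floor(lon), floor(lat))
  for (sp in minimal) {
    cells <- unique(cell_of(w$occ$lon[w$occ$species == sp],
                            w$occ$lat[w$occ$species == sp]))
    vals <- vapply(cells, function(cl) {
      in_cell <- vapply(rrc$species, function(v) {
        sub <- w$occ[w$occ$species == v, ]
        cl %in% cell_of(sub$lon, sub$lat)
      }, logical(1))
      if (!any(in_cell)) NA_real_ else mean(rrc$cropland[in_cell])
    }, numeric(1))
    expected <- if (all(is.na(vals))) NA_real_ else median(vals, na.rm = TRUE)
    expect_equal(imp$cropland[imp$species == sp], expected)
  }
})
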