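test_that("generators are bit-identical under a fixed seed", {
  cfg <- tiny_config(seed = 7, n_species = 4, n_minimal = 1)
  w1 <- gen_world(cfg)
  w2 <- gen_world(cfg)
  expect_identical(w1$occ, w2$occ)
  expect_identical(w1$zones$values, w2$zones$values)
  expect_identical(lapply(w1$change, `[[`, "values"),
                   lapply(w2$change, `[[`, "values"))
  expect_identical(lapply(w1$stacks, `[[`, "layers"),
                   lapply(w2$stacks, `[[`, "layers"))
  expect_identical(w1$status, w2$status)
  expect_identical(unclass(w1$truth), unclass(w2$truth))
})

test_that("forced-minimal species get under five records and flag downstream", {
  cfg <- tiny_config(seed = 3, n_species = 6, n_minimal = 2)
  occ <- gen_occurrences(cfg)
  counts <- table(occ$species)
  expect_true(all(counts[c("sp001", "sp002")] < 5))
  flags <- flag_minimal_area(occ, species = names(counts))
  expect_true(all(flags$flagged[flags$species %in% c("sp001", "sp002")]))
  expect_equal(flags$reason[flags$species == "sp001"], "few_records")
})

test_that("degenerate bbox and label probabilities are validated", {
  expect_error(synthetic_config(bbox = c(10, 0, 10, 5)), "non-degenerate")
  expect_error(synthetic_config(label_probs = c(ZZZ = 1)), "unknown")
  cfg <- tiny_config(label_probs = c(AAA = 1), n_minimal = 0)
  occ <- gen_occurrences(cfg)
  expect_identical(nrow(filter_quality(occ)), nrow(filter_quality(occ,
                   allowed = "AAA")))
})

test_that("zone mosaic matches brute-force nearest-center assignment", {
  cfg <- tiny_config(seed = 21, n_zones = 4)
  z <- gen_zone_raster(cfg)
  ctr <- attr(z, "centers")
  g <- z$grid
  lons <- cell_lon(g); lats <- cell_lat(g)
  set.seed(9)
  rows <- sample(g$nrow, 40); cols <- sample(g$ncol, 40)
  for (k in seq_len(40)) {
    d <- sqrt((ctr[, 1] - lons[cols[k]])^2 + (ctr[, 2] - lats[rows[k]])^2)
    expect_equal(z$values[rows[k], cols[k]], which.min(d))
  }
  expect_setequal(unique(as.vector(z$values)), 1:4)
  # single zone: constant raster
  z1 <- gen_zone_raster(tiny_config(n_zones = 1))
  expect_true(all(z1$values == 1L))
})

test_that("change rasters realize planted fractions to within one cell", {
  cfg <- tiny_config(seed = 13, n_species = 1, n_minimal = 0)
  occ <- gen_occurrences(cfg)
  for (f in c(0, 0.3, 1)) {
    truth <- planted_truth(cfg, attr(occ, "centers"),
                           change_fracs = matrix(f, 1, 4,
                             dimnames = list("sp001",
                               c("cropland", "treecover", "builtup",
                                 "deforestation"))))
    res <- gen_change_raster(cfg, truth, "cropland")
    reg <- truth$regions$sp001
    m <- length(reg$rows) * length(reg$cols)
    got <- sum(res$raster$values[reg$rows, reg$cols])
    expect_equal(got, round(f * m))
    expect_equal(res$truth$realized_fracs["sp001", "cropland"], got / m)
    expect_lte(abs(res$truth$realized_fracs["sp001", "cropland"] - f), 1 / m)
    if (f == 0) expect_true(all(res$raster$values == 0))
    if (f == 1) expect_true(all(res$raster$values[reg$rows, reg$cols] == 1))
  }
  expect_error(planted_truth(cfg, attr(occ, "centers"),
                             change_fracs = matrix(1.2, 1, 4,
                               dimnames = list("sp001",
                                 c("cropland", "treecover", "builtup",
                                   "deforestation")))), "\\[0, 1\\]")
})

test_that("noiseless annual stacks are exactly linear at the planted slope", {
  cfg <- tiny_config(seed = 17, n_species = 1, n_minimal = 0)
  occ <- gen_occurrences(cfg)
  truth <- planted_truth(cfg, attr(occ, "centers"),
                         noise_sd = c(burned = 0, tmin = 0, tmax = 0,
                                      vpd = 0, vpd_seas = 0, prec = 0,
                                      prec_seas = 0))
  truth$trend_slopes["sp001", "tmin"] <- 0.02
  st <- gen_annual_stack(cfg, truth, "tmin")
  reg <- truth$regions$sp001
  r <- reg$rows[1]; cl <- reg$cols[1]
  series <- vapply(st$layers, function(l) l[r, cl], numeric(1))
  expect_equal(diff(series), rep(0.02, length(st$years) - 1))
  # and the Siegel estimator recovers it to machine precision
  fit <- siegel(st$years, series)
  expect_equal(fit$slope, 0.02, tolerance = 1e-12)
})

test_that("status categories are sampled at the requested probabilities", {
  sp <- sprintf("s%05d", 1:10000)
  probs <- c(LC = 0.5, EN = 0.2, DD = 0.3)
  st <- gen_status_table(sp, probs = probs, seed = 2)
  emp <- table(st$category) / length(sp)
  for (k in names(probs)) {
    se <- sqrt(probs[[k]] * (1 - probs[[k]]) / length(sp))
    expect_lt(abs(emp[[k]] - probs[[k]]), 3 * se)
  }
  expect_error(gen_status_table(sp, probs = c(XX = 1)), "unknown")
  st_lc <- gen_status_table(sp[1:10], probs = c(LC = 1), seed = 1)
  expect_true(all(status_group(st_lc$category) == "Not Threatened"))
})

test_that("planted truth serializes to a readable JSON sidecar", {
  w <- test_world()
  f <- tempfile(fileext = ".json")
  write_truth(w$truth, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_setequal(back$species, names(w$truth$regions))
  expect_equal(as.matrix(back$realized_fracs),
               unname(w$truth$realized_fracs), ignore_attr = TRUE)
})
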