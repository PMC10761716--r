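#' Configuration for a synthetic study region
#'
#' Bundles everything the generators need: a bounding box, a grid
#' resolution, species counts, occurrence-cluster geometry, the number of
#' climate-like zones, the span of calendar years, and one global seed that
#' is expanded into independent substreams per generator so components can
#' be regenerated individually without disturbing each other.
#'
#' @param bbox numeric `c(lon_min, lat_min, lon_max, lat_max)` in degrees;
#'   must be non-degenerate.
#' @param resolution grid cell size in degrees.
#' @param n_species number of species to simulate.
#' @param n_records_range integer `c(min, max)` occurrence records per
#'   species (before any forced-minimal override).
#' @param cluster_sd standard deviation (degrees) of the isotropic Gaussian
#'   occurrence clusters.
#' @param n_zones number of categorical zones in the zone mosaic.
#' @param years strictly increasing calendar years for annual stacks.
#' @param seed integer master seed; identical configs give bit-identical
#'   worlds.
#' @param label_probs named probabilities over the occurrence quality labels
#'   `AAA, AA, A, B, C, D, E, H`; need not sum to 1 (normalised).
#' @param n_minimal number of species forced to have fewer than five records
#'   so the minimal-area path is exercised.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(bbox = c(10, -4, 20, 4),
                             resolution = 0.05,
                             n_species = 50,
                             n_records_range = c(5, 120),
                             cluster_sd = 0.3,
                             n_zones = 6,
                             years = 2001:2020,
                             seed = 1,
                             label_probs = c(AAA = 0.35, AA = 0.2, A = 0.15,
                                             B = 0.1, C = 0.08, D = 0.05,
                                             E = 0.04, H = 0.03),
                             n_minimal = 0) {
  if (length(bbox) != 4 || bbox[3] <= bbox[1] || bbox[4] <= bbox[2])
    stop("bbox must be c(lon_min, lat_min, lon_max, lat_max) and non-degenerate")
  stopifnot(resolution > 0, n_species >= 1,
            length(n_records_range) == 2, n_records_range[1] >= 1,
            n_records_range[2] >= n_records_range[1],
            n_zones >= 1, length(years) >= 1, all(diff(years) > 0),
            n_minimal >= 0, n_minimal <= n_species)
  lab_ok <- c("AAA", "AA", "A", "B", "C", "D", "E", "H")
  if (!all(names(label_probs) %in% lab_ok))
    stop("unknown quality labels: ",
         paste(setdiff(names(label_probs), lab_ok), collapse = ", "))
  structure(list(bbox = bbox, resolution = resolution,
                 n_species = as.integer(n_species),
                 n_records_range = as.integer(n_records_range),
                 cluster_sd = cluster_sd, n_zones = as.integer(n_zones),
                 years = as.integer(years), seed = as.integer(seed),
                 label_probs = label_probs / sum(label_probs),
                 n_minimal = as.integer(n_minimal)),
            class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_config> %d species, bbox [%g,%g]x[%g,%g] ",
                     "at %g deg, %d zones, years %d-%d, seed %d\n"),
              x$n_species, x$bbox[1], x$bbox[3], x$bbox[2], x$bbox[4],
              x$resolution, x$n_zones, min(x$years), max(x$years), x$seed))
  invisible(x)
}

# Independent substream per generator component: the master seed is combined
# with a small fixed offset per component (and per variable where needed).
# Offsets stay small so derived seeds remain valid 32-bit integers.
.substream <- function(config, component, extra = 0L) {
  offs <- c(occurrences = 101L, zones = 211L, change = 307L, stack = 401L,
            status = 503L, water = 601L, truth = 701L)
  set.seed((config$seed %% 1000000L) * 1000L + offs[[component]] + extra)
}

#' Grid implied by a synthetic configuration
#' @param config a [synthetic_config()].
#' @return A [grid_spec()] covering the configured bounding box.
#' @export
config_grid <- function(config) {
  ncol <- max(1L, round((config$bbox[3] - config$bbox[1]) / config$resolution))
  nrow <- max(1L, round((config$bbox[4] - config$bbox[2]) / config$resolution))
  grid_spec(config$bbox[1], config$bbox[2], config$resolution, ncol, nrow)
}

#' Generate clustered occurrence records with quality labels
#'
#' Each species gets one or two isotropic Gaussian clusters placed inside
#' the bounding box; records are drawn around the cluster centres and
#' clamped to the box. Quality labels are sampled from the configured label
#' probabilities. The first `n_minimal` species are forced to three records
#' so they trip the minimal-area rule downstream.
#'
#' @param config a [synthetic_config()].
#' @return A data frame `(species, lon, lat, label)` with an attribute
#'   `centers`: per-species primary cluster centre used by the truth
#'   bookkeeping.
#' @export
gen_occurrences <- function(config) {
  .substream(config, "occurrences")
  bb <- config$bbox
  inset <- min(2 * config$cluster_sd, (bb[3] - bb[1]) / 4, (bb[4] - bb[2]) / 4)
  sp_ids <- sprintf("sp%03d", seq_len(config$n_species))
  out <- vector("list", config$n_species)
  centers <- matrix(NA_real_, config$n_species, 2,
                    dimnames = list(sp_ids, c("lon", "lat")))
  for (s in seq_len(config$n_species)) {
    n <- sample(config$n_records_range[1]:config$n_records_range[2], 1L)
    if (s <= config$n_minimal) n <- 3L
    k <- sample(1:2, 1L)
    ctr <- cbind(runif(k, bb[1] + inset, bb[3] - inset),
                 runif(k, bb[2] + inset, bb[4] - inset))
    centers[s, ] <- ctr[1, ]
    pick <- sample.int(k, n, replace = TRUE)
    lon <- rnorm(n, ctr[pick, 1], config$cluster_sd)
    lat <- rnorm(n, ctr[pick, 2], config$cluster_sd)
    # keep records a little inside the box so 1-km suitability buffers
    # never leave the gridded study region
    margin <- min(0.02, (bb[3] - bb[1]) / 20, (bb[4] - bb[2]) / 20)
    lon <- pmin(pmax(lon, bb[1] + margin), bb[3] - margin)
    lat <- pmin(pmax(lat, bb[2] + margin), bb[4] - margin)
    lab <- sample(names(config$label_probs), n, replace = TRUE,
                  prob = config$label_probs)
    out[[s]] <- data.frame(species = sp_ids[s], lon = lon, lat = lat,
                           label = lab, stringsAsFactors = FALSE)
  }
  occ <- do.call(rbind, out)
  rownames(occ) <- NULL
  attr(occ, "centers") <- centers
  occ
}

#' Generate a contiguous categorical zone mosaic
#'
#' Voronoi-style mosaic: `n_zones` centres are placed uniformly in the
#' bounding box and every grid cell takes the id of its nearest centre
#' (planar degree distance), giving contiguous zones that stand in for a
#' climate classification.
#'
#' @param config a [synthetic_config()].
#' @return A categorical [rrc_raster()] with integer values `1..n_zones`
#'   and an attribute `centers`.
#' @export
gen_zone_raster <- function(config) {
  .substream(config, "zones")
  g <- config_grid(config)
  bb <- config$bbox
  ctr <- cbind(runif(config$n_zones, bb[1], bb[3]),
               runif(config$n_zones, bb[2], bb[4]))
  lons <- cell_lon(g); lats <- cell_lat(g)
  v <- matrix(0L, g$nrow, g$ncol)
  for (r in seq_len(g$nrow)) {
    d2 <- outer(ctr[, 1], lons, function(cx, x) (cx - x)^2) +
      (ctr[, 2] - lats[r])^2
    v[r, ] <- if (config$n_zones == 1L) 1L
              else max.col(-t(d2), ties.method = "first")
  }
  r <- rrc_raster(g, v)
  attr(r, "centers") <- ctr
  r
}

#' Generate a binary water mask
#'
#' A handful of rectangular "lakes" are placed at random until roughly the
#' requested fraction of cells is water (value 1); everything else is land
#' (value 0).
#'
#' @param config a [synthetic_config()].
#' @param water_frac target water fraction of the grid, in `[0, 1)`.
#' @return A binary [rrc_raster()] (1 = water).
#' @export
gen_water_mask <- function(config, water_frac = 0.05) {
  stopifnot(water_frac >= 0, water_frac < 1)
  .substream(config, "water")
  g <- config_grid(config)
  v <- matrix(0L, g$nrow, g$ncol)
  target <- water_frac * g$nrow * g$ncol
  guard <- 0L
  while (sum(v) < target && guard < 1000L) {
    h <- sample(2:max(2L, g$nrow %/% 8), 1L)
    w <- sample(2:max(2L, g$ncol %/% 8), 1L)
    r0 <- sample.int(max(1L, g$nrow - h), 1L)
    c0 <- sample.int(max(1L, g$ncol - w), 1L)
    v[r0:(r0 + h - 1L), c0:(c0 + w - 1L)] <- 1L
    guard <- guard + 1L
  }
  rrc_raster(g, v)
}

#' Planted ground truth for a synthetic world
#'
#' Records, per species, the rectangular core region (in grid cells) around
#' its primary occurrence cluster, the true changed fraction per
#' unidirectional threat inside that region, and the true per-region trend
#' slope and noise level per annual variable. Recovery tests read truth only
#' from this record.
#'
#' @param config a [synthetic_config()].
#' @param centers per-species cluster centres, as attached to
#'   [gen_occurrences()] output (rows named by species).
#' @param change_fracs matrix (species x threat) of changed fractions in
#'   `[0, 1]`; default draws them uniformly on `[0, 0.4]`.
#' @param trend_slopes matrix (species x variable) of true slopes in native
#'   units per year; default draws modest warming/drying trends.
#' @param noise_sd named per-variable noise standard deviation.
#' @param region_deg side length (degrees) of each species' core region.
#' @return An object of class `planted_truth` with elements `regions`
#'   (per-species `list(rows, cols)`), `change_fracs`, `realized_fracs`
#'   (filled by [gen_change_raster()]), `trend_slopes`, `noise_sd`.
#' @export
planted_truth <- function(config, centers,
                          change_fracs = NULL,
                          trend_slopes = NULL,
                          noise_sd = c(burned = 0, tmin = 0.1, tmax = 0.1,
                                       vpd = 2, vpd_seas = 1, prec = 10,
                                       prec_seas = 4),
                          region_deg = 1.0) {
  .substream(config, "truth")
  g <- config_grid(config)
  sp <- rownames(centers)
  threats <- c("cropland", "treecover", "builtup", "deforestation")
  vars <- c("burned", "tmin", "tmax", "vpd", "vpd_seas", "prec", "prec_seas")
  if (is.null(change_fracs)) {
    change_fracs <- matrix(round(runif(length(sp) * length(threats), 0, 0.4), 3),
                           length(sp), length(threats),
                           dimnames = list(sp, threats))
  }
  if (any(change_fracs < 0 | change_fracs > 1))
    stop("planted changed fractions must lie in [0, 1]")
  if (is.null(trend_slopes)) {
    trend_slopes <- cbind(
      burned = runif(length(sp), -2, 2),          # km^2 / yr within region
      tmin = runif(length(sp), 0, 0.05),          # degC / yr
      tmax = runif(length(sp), 0, 0.05),
      vpd = runif(length(sp), -1, 4),             # Pa / yr
      vpd_seas = runif(length(sp), -0.5, 2),
      prec = runif(length(sp), -8, 8),            # mm / yr
      prec_seas = runif(length(sp), -2, 4))
    rownames(trend_slopes) <- sp
  }
  half <- region_deg / 2
  regions <- lapply(seq_along(sp), function(s) {
    ci <- cell_index(g, centers[s, 1], centers[s, 2])
    nr <- max(1L, round(half / g$res))
    rows <- max(1L, ci$row - nr):min(g$nrow, ci$row + nr)
    cols <- max(1L, ci$col - nr):min(g$ncol, ci$col + nr)
    list(rows = rows, cols = cols)
  })
  names(regions) <- sp
  structure(list(regions = regions, change_fracs = change_fracs,
                 realized_fracs = change_fracs * NA,
                 trend_slopes = trend_slopes, noise_sd = noise_sd),
            class = "planted_truth")
}

#' Generate a binary change raster with planted changed fractions
#'
#' Inside each species' core region, `round(fraction * n_cells)` cells are
#' switched on (sampled without replacement from the region), so the
#' realized changed fraction matches the planted one to within one cell.
#' Where regions of different species overlap, the union is kept and the
#' realized per-region fraction is recorded in the returned truth.
#'
#' @param config a [synthetic_config()].
#' @param truth a [planted_truth()].
#' @param threat one of `"cropland"`, `"treecover"`, `"builtup"`,
#'   `"deforestation"`.
#' @return A list: `raster` (binary [rrc_raster()]) and `truth` (updated
#'   [planted_truth()] with `realized_fracs[, threat]` filled).
#' @export
gen_change_raster <- function(config, truth, threat) {
  stopifnot(inherits(truth, "planted_truth"),
            threat %in% colnames(truth$change_fracs))
  .substream(config, "change",
             extra = match(threat, colnames(truth$change_fracs)))
  g <- config_grid(config)
  v <- matrix(0L, g$nrow, g$ncol)
  for (sp in names(truth$regions)) {
    reg <- truth$regions[[sp]]
    f <- truth$change_fracs[sp, threat]
    m <- length(reg$rows) * length(reg$cols)
    k <- round(f * m)
    if (k > 0) {
      cells <- arrayInd(sample.int(m, k), c(length(reg$rows), length(reg$cols)))
      v[cbind(reg$rows[cells[, 1]], reg$cols[cells[, 2]])] <- 1L
    }
  }
  for (sp in names(truth$regions)) {
    reg <- truth$regions[[sp]]
    truth$realized_fracs[sp, threat] <- mean(v[reg$rows, reg$cols])
  }
  list(raster = rrc_raster(g, v), truth = truth)
}

#' Generate an annual stack with planted linear trends
#'
#' Per cell, `value(year) = intercept + slope * (year - year_0) + noise`
#' with iid Gaussian noise of the variable's `noise_sd`. The slope is the
#' species' planted slope inside its core region (later-listed species win
#' where regions overlap) and 0 elsewhere; the intercept is a fixed smooth
#' north-south gradient. With `noise_sd = 0` every cell series is exactly
#' linear. For the `burned` variable the layer is a burned-area fraction in
#' `[0, 1]` per cell, trending at `slope / region_area` so that the summed
#' burned area inside the region trends at the planted slope (km^2/yr).
#'
#' @param config a [synthetic_config()].
#' @param truth a [planted_truth()].
#' @param variable one of the columns of `truth$trend_slopes`.
#' @param heavy_tails if `TRUE`, noise is drawn from a t distribution with 3
#'   degrees of freedom (scaled to `noise_sd`) to exercise robustness.
#' @return An [annual_stack()].
#' @export
gen_annual_stack <- function(config, truth, variable, heavy_tails = FALSE) {
  stopifnot(inherits(truth, "planted_truth"),
            variable %in% colnames(truth$trend_slopes),
            length(config$years) >= 3)
  .substream(config, "stack", extra = match(variable,
                                            colnames(truth$trend_slopes)))
  g <- config_grid(config)
  base <- switch(variable, burned = 0.05, tmin = 5, tmax = 25, vpd = 800,
                 vpd_seas = 120, prec = 1200, prec_seas = 60, 0)
  lat_grad <- matrix(rep(seq(0, 1, length.out = g$nrow), g$ncol),
                     g$nrow, g$ncol)
  intercept <- base * (1 + 0.1 * lat_grad)
  slope <- matrix(0, g$nrow, g$ncol)
  areas <- cell_area_km2(g)
  for (sp in rownames(truth$trend_slopes)) {
    reg <- truth$regions[[sp]]
    b <- truth$trend_slopes[sp, variable]
    if (variable == "burned") {
      reg_area <- sum(rep(areas[reg$rows], length(reg$cols)))
      slope[reg$rows, reg$cols] <- b / reg_area
    } else {
      slope[reg$rows, reg$cols] <- b
    }
  }
  sdv <- truth$noise_sd[[variable]]
  y0 <- config$years[1]
  layers <- lapply(config$years, function(yr) {
    noise <- if (sdv == 0) 0 else if (heavy_tails)
      matrix(rt(g$nrow * g$ncol, df = 3) * sdv / sqrt(3), g$nrow, g$ncol)
    else matrix(rnorm(g$nrow * g$ncol, 0, sdv), g$nrow, g$ncol)
    l <- intercept + slope * (yr - y0) + noise
    if (variable == "burned") l <- pmin(pmax(l, 0), 1)
    l
  })
  units <- switch(variable, burned = "fraction", tmin = , tmax = "degC",
                  vpd = , vpd_seas = "Pa", prec = , prec_seas = "mm", "")
  annual_stack(variable, config$years, layers, g, units)
}

#' Generate an IUCN status table
#'
#' One category per species, sampled independently from the supplied
#' probabilities over the recognised IUCN Red List codes.
#'
#' @param species character vector of species ids.
#' @param probs named probabilities over
#'   `EX, EW, RE, CR, EN, VU, LR/cd, NT, LR/nt, LC, LR/lc, DD, NE`.
#' @param seed integer seed.
#' @return Data frame `(species, category)`.
#' @export
gen_status_table <- function(species,
                             probs = c(CR = 0.03, EN = 0.07, VU = 0.1,
                                       NT = 0.1, LC = 0.5, DD = 0.1,
                                       NE = 0.1),
                             seed = 1) {
  known <- c("EX", "EW", "RE", "CR", "EN", "VU", "LR/cd", "NT", "LR/nt",
             "LC", "LR/lc", "DD", "NE")
  if (!all(names(probs) %in% known))
    stop("unknown IUCN category keys: ",
         paste(setdiff(names(probs), known), collapse = ", "))
  set.seed(seed)
  data.frame(species = species,
             category = sample(names(probs), length(species), replace = TRUE,
                               prob = probs / sum(probs)),
             stringsAsFactors = FALSE)
}

#' Assemble a complete synthetic world
#'
#' Convenience wrapper tying all generators together: occurrences, zone
#' mosaic, water mask, the four binary change rasters with their time-window
#' divisors, the burned-area and six climate annual stacks, a status table,
#' and the planted truth record.
#'
#' @param config a [synthetic_config()].
#' @param water_frac water fraction for [gen_water_mask()].
#' @param status_probs passed to [gen_status_table()].
#' @param truth optionally a pre-built [planted_truth()]; by default one is
#'   derived from the occurrence cluster centres.
#' @param heavy_tails passed to [gen_annual_stack()].
#' @return An object of class `synthetic_world`: list with `config`, `occ`,
#'   `zones`, `water`, `change` (named rasters), `divisors`, `stacks`
#'   (named [annual_stack()]s), `status`, `truth`.
#' @export
gen_world <- function(config, water_frac = 0.05, status_probs = NULL,
                      truth = NULL, heavy_tails = FALSE) {
  occ <- gen_occurrences(config)
  centers <- attr(occ, "centers")
  zones <- gen_zone_raster(config)
  water <- gen_water_mask(config, water_frac)
  if (is.null(truth)) truth <- planted_truth(config, centers)
  threats <- colnames(truth$change_fracs)
  change <- list()
  for (th in threats) {
    cr <- gen_change_raster(config, truth, th)
    change[[th]] <- cr$raster
    truth <- cr$truth
  }
  divisors <- c(cropland = 16, treecover = 15, builtup = 20,
                deforestation = 20)
  vars <- colnames(truth$trend_slopes)
  stacks <- lapply(vars, function(v)
    gen_annual_stack(config, truth, v, heavy_tails = heavy_tails))
  names(stacks) <- vars
  status <- if (is.null(status_probs))
    gen_status_table(rownames(centers), seed = config$seed)
  else gen_status_table(rownames(centers), probs = status_probs,
                        seed = config$seed)
  structure(list(config = config, occ = occ, zones = zones, water = water,
                 change = change, divisors = divisors, stacks = stacks,
                 status = status, truth = truth),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world> %d species, %d occurrence records, %s grid\n",
              x$config$n_species, nrow(x$occ), format(x$zones$grid)))
  cat(sprintf("  change rasters: %s\n  stacks: %s\n",
              paste(names(x$change), collapse = ", "),
              paste(names(x$stacks), collapse = ", ")))
  invisible(x)
}

#' Serialize a synthetic world's truth record
#'
#' Writes the planted truth (regions, planted and realized fractions,
#' slopes, noise levels) as a JSON sidecar so recovery tests can read the
#' ground truth without access to the generator call.
#'
#' @param truth a [planted_truth()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "planted_truth"))
  out <- list(
    regions = lapply(truth$regions, function(r)
      list(rows = range(r$rows), cols = range(r$cols))),
    change_fracs = as.data.frame(truth$change_fracs),
    realized_fracs = as.data.frame(truth$realized_fracs),
    trend_slopes = as.data.frame(truth$trend_slopes),
    noise_sd = as.list(truth$noise_sd),
    species = names(truth$regions))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
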