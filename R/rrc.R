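# Rate-of-recent-change engine: threat-layer preprocessing, unidirectional
# area-conversion rates, bidirectional significance-gated trend rates,
# outlier removal and minimal-area imputation.

.check_same_grid <- function(a, b)
  if (!grids_identical(a$grid, b$grid)) stop("rasters disagree on grid")

#' Build the cropland-expansion change layer
#'
#' From five binary cropland epoch maps (baseline 2000-03, then 2004-07,
#' 2008-11, 2012-15, 2016-19): a cell counts as converted if it is cropland
#' in any post-baseline epoch but was not cropland in the baseline. The
#' associated time-window divisor is 16 years.
#'
#' @param epoch_maps list of five binary [rrc_raster()]s in epoch order,
#'   baseline first.
#' @return Binary [rrc_raster()] with attribute `divisor = 16`.
#' @export
build_cropland_change <- function(epoch_maps) {
  if (length(epoch_maps) != 5) stop("cropland change needs 5 epoch layers")
  for (m in epoch_maps[-1]) .check_same_grid(epoch_maps[[1]], m)
  vals <- lapply(epoch_maps, `[[`, "values")
  if (!all(unlist(vals) %in% c(0, 1))) stop("epoch layers must be binary")
  post <- (vals[[2]] + vals[[3]] + vals[[4]] + vals[[5]]) > 0
  out <- (post & vals[[1]] == 0) * 1L
  r <- rrc_raster(epoch_maps[[1]]$grid, out)
  attr(r, "divisor") <- 16
  r
}

#' Build the tree-cover-decline change layer
#'
#' From four tree-cover percentage maps (2000, 2005, 2010, 2015): the three
#' consecutive difference maps are combined so a cell counts as declined if
#' any single consecutive comparison dropped by at least `min_drop`
#' percentage points. Gradual declines below `min_drop` per comparison do
#' not count. Divisor 15 years.
#'
#' @param tc_maps list of four [rrc_raster()]s with values in 0-100.
#' @param min_drop minimum drop (percentage points) in one comparison.
#' @return Binary [rrc_raster()] with attribute `divisor = 15`.
#' @export
build_treecover_decline <- function(tc_maps, min_drop = 5) {
  if (length(tc_maps) != 4) stop("tree-cover decline needs 4 layers")
  for (m in tc_maps[-1]) .check_same_grid(tc_maps[[1]], m)
  vals <- lapply(tc_maps, `[[`, "values")
  rng <- range(unlist(vals))
  if (rng[1] < 0 || rng[2] > 100) stop("tree cover must lie in [0, 100]")
  drop1 <- vals[[1]] - vals[[2]]
  drop2 <- vals[[2]] - vals[[3]]
  drop3 <- vals[[3]] - vals[[4]]
  out <- (pmax(drop1, drop2, drop3) >= min_drop) * 1L
  r <- rrc_raster(tc_maps[[1]]$grid, out)
  attr(r, "divisor") <- 15
  r
}

#' Build the built-up-expansion change layer
#'
#' Input coding: 0 no built-up, 1 stable built-up, 2 built-up expansion.
#' Only expansion (value 2) counts as change; stable built-up does not.
#' Divisor 20 years.
#'
#' @param raster an [rrc_raster()] with values in `{0, 1, 2}`.
#' @return Binary [rrc_raster()] with attribute `divisor = 20`.
#' @export
build_builtup_change <- function(raster) {
  if (!all(raster$values %in% c(0, 1, 2)))
    stop("built-up layer must have values in {0, 1, 2}")
  r <- rrc_raster(raster$grid, (raster$values == 2) * 1L)
  attr(r, "divisor") <- 20
  r
}

#' Build the deforestation change layer
#'
#' Forest-loss input is already binary (1 = complete canopy removal
#' 2000-2020); this is an identity pass-through that validates the coding
#' and attaches the 20-year divisor.
#'
#' @param raster binary [rrc_raster()].
#' @return Binary [rrc_raster()] with attribute `divisor = 20`.
#' @export
build_deforestation <- function(raster) {
  if (!all(raster$values %in% c(0, 1)))
    stop("deforestation layer must be binary")
  r <- rrc_raster(raster$grid, raster$values * 1L)
  attr(r, "divisor") <- 20
  r
}

#' Unidirectional rate of recent change
#'
#' The changed area inside the species extent (coverage-weighted geodesic
#' area of changed cells) divided by the extent area, times 100, divided by
#' the threat's time window in years: percent of extent converted per year.
#' Bounded in `[0, 100 / n_years]`, saturating exactly at full conversion.
#'
#' @param extent an [extent_mask()].
#' @param change binary change [rrc_raster()] on the extent's grid.
#' @param n_years time-window divisor (defaults to the raster's `divisor`
#'   attribute).
#' @return List `(rate, changed_km2, eoo_km2, n_years)` with `rate` in
#'   percent of extent per year.
#' @export
unidirectional_rrc <- function(extent, change, n_years = NULL) {
  stopifnot(inherits(extent, "extent_mask"), inherits(change, "rrc_raster"))
  if (!grids_identical(extent$grid, change$grid))
    stop("change raster not on the extent's grid")
  if (is.null(n_years)) n_years <- attr(change, "divisor")
  stopifnot(is.numeric(n_years), n_years > 0)
  if (extent$eoo_km2 <= 0)
    stop("extent area is zero; species belongs on the minimal-area path")
  ch <- change$values[cbind(extent$cells$row, extent$cells$col)]
  changed <- sum(extent$cells$w * extent$cells$area_km2 * (ch == 1))
  list(rate = 100 * changed / extent$eoo_km2 / n_years,
       changed_km2 = changed, eoo_km2 = extent$eoo_km2, n_years = n_years)
}

#' Yearly aggregate of a stack over an extent
#'
#' Burned-area mode (`sum_area`) sums coverage-weighted burned cell area
#' per year (km^2, cells count in proportion to their burned fraction);
#' climate mode (`weighted_mean`) averages the cell values with weights
#' equal to coverage fraction times cell area.
#'
#' @param extent an [extent_mask()].
#' @param stack an [annual_stack()] on the extent's grid.
#' @param mode `"sum_area"` or `"weighted_mean"`.
#' @return Numeric vector of yearly aggregates named by year.
#' @export
extent_series <- function(extent, stack,
                          mode = c("weighted_mean", "sum_area")) {
  mode <- match.arg(mode)
  stopifnot(inherits(extent, "extent_mask"), inherits(stack, "annual_stack"))
  if (!grids_identical(extent$grid, stack$grid))
    stop("stack not on the extent's grid")
  idx <- cbind(extent$cells$row, extent$cells$col)
  wa <- extent$cells$w * extent$cells$area_km2
  out <- vapply(stack$layers, function(l) {
    v <- l[idx]
    if (mode == "sum_area") sum(wa * v, na.rm = TRUE)
    else sum(wa * v, na.rm = TRUE) / sum(wa[!is.na(v)])
  }, numeric(1))
  names(out) <- stack$years
  out
}

#' Bidirectional rate of recent change
#'
#' Builds the yearly aggregate series over the extent, fits the Siegel
#' repeated-medians trend, and gates it on Mann-Kendall significance. For
#' burned area the significant slope (km^2/yr) is re-expressed as percent
#' of extent per year (`100 * slope / EOO area`); climate slopes stay in
#' native units per year. Non-significant trends yield an exact 0 with the
#' `nonsignificant_zeroed` flag.
#'
#' @param extent an [extent_mask()].
#' @param stack an [annual_stack()]; at least 3 years.
#' @param mode `"sum_area"` for burned area, `"weighted_mean"` for climate.
#' @param alpha significance level of the trend gate.
#' @param years optional subset of calendar years (decadal re-windowing).
#' @return List `(rate, slope, p_value, significant, nonsignificant_zeroed,
#'   series, n_years)`.
#' @export
bidirectional_rrc <- function(extent, stack,
                              mode = c("weighted_mean", "sum_area"),
                              alpha = 0.05, years = NULL) {
  mode <- match.arg(mode)
  series <- extent_series(extent, stack, mode)
  yrs <- stack$years
  if (!is.null(years)) {
    keep <- yrs %in% years
    yrs <- yrs[keep]; series <- series[keep]
  }
  if (length(yrs) < 3) stop("bidirectional RRC needs at least 3 years")
  fit <- slope_significance(yrs, as.numeric(series), alpha = alpha)
  rate <- if (!fit$significant) 0
  else if (mode == "sum_area") {
    if (extent$eoo_km2 <= 0) stop("extent area is zero")
    100 * fit$slope / extent$eoo_km2
  } else fit$slope
  list(rate = rate, slope = fit$slope, p_value = fit$p_value,
       significant = fit$significant,
       nonsignificant_zeroed = !fit$significant,
       series = series, n_years = length(yrs))
}

#' Annual minimum and maximum from monthly layers
#'
#' @param monthly list of 12 [rrc_raster()]s (one per month).
#' @return List of two rasters, `min` and `max` (cellwise over months).
#' @export
annual_min_max_temperature <- function(monthly) {
  if (length(monthly) != 12) stop("need 12 monthly layers")
  for (m in monthly[-1]) .check_same_grid(monthly[[1]], m)
  arr <- simplify2array(lapply(monthly, `[[`, "values"))
  g <- monthly[[1]]$grid
  list(min = rrc_raster(g, apply(arr, c(1, 2), min)),
       max = rrc_raster(g, apply(arr, c(1, 2), max)))
}

#' Annual mean and seasonality from monthly layers
#'
#' Seasonality is the cellwise standard deviation over the 12 months; the
#' mean is the cellwise average.
#'
#' @param monthly list of 12 [rrc_raster()]s.
#' @return List of two rasters, `mean` and `sd`.
#' @export
annual_mean_seasonality <- function(monthly) {
  if (length(monthly) != 12) stop("need 12 monthly layers")
  for (m in monthly[-1]) .check_same_grid(monthly[[1]], m)
  arr <- simplify2array(lapply(monthly, `[[`, "values"))
  g <- monthly[[1]]$grid
  list(mean = rrc_raster(g, apply(arr, c(1, 2), mean)),
       sd = rrc_raster(g, apply(arr, c(1, 2), stats::sd)))
}

#' Remove extreme-rate outlier species
#'
#' Per rate column, species whose rate lies more than three interpercentile
#' ranges (Q99 - Q1) above the 99% quantile or below the 1% quantile are
#' removed from the cross-status analysis and flagged.
#'
#' @param rrc wide rate table: data frame with a `species` column and one
#'   numeric column per threat/variable.
#' @param k multiplier on the interpercentile range (default 3).
#' @param probs the two anchor quantiles (default `c(0.01, 0.99)`).
#' @return List `(table, removed)`: the table without outlier species, and
#'   a data frame of removed species with the offending column.
#' @export
remove_outliers <- function(rrc, k = 3, probs = c(0.01, 0.99)) {
  num_cols <- setdiff(names(rrc), "species")
  removed <- NULL
  for (cl in num_cols) {
    v <- rrc[[cl]]
    q <- stats::quantile(v, probs, na.rm = TRUE, names = FALSE)
    ipr <- q[2] - q[1]
    bad <- !is.na(v) & (v > q[2] + k * ipr | v < q[1] - k * ipr)
    if (any(bad))
      removed <- rbind(removed,
                       data.frame(species = rrc$species[bad], column = cl,
                                  rate = v[bad], stringsAsFactors = FALSE))
  }
  bad_sp <- unique(removed$species)
  list(table = rrc[!(rrc$species %in% bad_sp), , drop = FALSE],
       removed = if (is.null(removed))
         data.frame(species = character(0), column = character(0),
                    rate = numeric(0)) else removed)
}

#' Impute rates for minimal-area species from co-occurring species
#'
#' Minimal-area species (too few records or too small an occupied area for
#' extent-based rates) inherit rates from the species around them: on a
#' coarse grid (default 1 degree), each cell's value per threat is the mean
#' rate over all valued species with an occurrence record in that cell; a
#' minimal-area species' imputed rate is the median of the values of the
#' cells it occurs in. Species occupying only cells with no valued
#' neighbour get `NA`.
#'
#' @param minimal_species character vector of species to impute.
#' @param occ occurrence data frame `(species, lon, lat, ...)` covering both
#'   valued and minimal species.
#' @param rrc wide rate table of the valued species (`species` + rate
#'   columns).
#' @param grid_res coarse-grid resolution in degrees (default 1).
#' @return Data frame `species` + one imputed column per rate column, with
#'   an `imputed` flag column.
#' @export
impute_minimal_species <- function(minimal_species, occ, rrc, grid_res = 1) {
  num_cols <- setdiff(names(rrc), "species")
  cell_of <- function(lon, lat)
    paste(floor(lon / grid_res), floor(lat / grid_res))
  occ$cell <- cell_of(occ$lon, occ$lat)
  valued <- occ[occ$species %in% rrc$species, c("species", "cell")]
  valued <- unique(valued)
  valued <- merge(valued, rrc, by = "species")
  cell_means <- stats::aggregate(valued[num_cols], by = list(cell = valued$cell),
                                 FUN = mean, na.rm = TRUE)
  out <- lapply(minimal_species, function(sp) {
    cells <- unique(occ$cell[occ$species == sp])
    hit <- cell_means[cell_means$cell %in% cells, num_cols, drop = FALSE]
    vals <- if (nrow(hit) == 0) rep(NA_real_, length(num_cols))
    else apply(hit, 2, stats::median, na.rm = TRUE)
    df <- as.data.frame(as.list(vals))
    names(df) <- num_cols
    cbind(data.frame(species = sp, stringsAsFactors = FALSE), df)
  })
  res <- do.call(rbind, out)
  res$imputed <- TRUE
  rownames(res) <- NULL
  res
}
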