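#' Filter occurrence records by quality label
#'
#' Keeps only records whose quality label is in the allowlist, then
#' collapses exact duplicate coordinates within each species (coordinates
#' compared after rounding to 6 decimal places, ~0.1 m). The default
#' allowlist keeps the reliable labels `AAA, AA, A, B, C` and drops the
#' problematic ones (`D, E, H`: coordinate/environment issues, unknown
#' range, duplicates, missing data). Species whose records are all filtered
#' out are simply absent from the result; they are picked up later by the
#' minimal-area flagging.
#'
#' @param occ data frame `(species, lon, lat, label)`.
#' @param allowed character vector of labels to keep; non-empty.
#' @return Filtered, deduplicated data frame with the same columns.
#' @export
filter_quality <- function(occ, allowed = c("AAA", "AA", "A", "B", "C")) {
  stopifnot(length(allowed) >= 1,
            all(c("species", "lon", "lat", "label") %in% names(occ)))
  if (any(occ$lon < -180 | occ$lon > 180 | occ$lat < -90 | occ$lat > 90))
    stop("occurrence coordinates outside WGS84 bounds")
  keep <- occ[occ$label %in% allowed, , drop = FALSE]
  key <- paste(keep$species, round(keep$lon, 6), round(keep$lat, 6))
  out <- keep[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Lambert cylindrical equal-area projection anchored at (0, 0):
# x = R * lon_rad, y = R * sin(lat_rad). Equal-area, so a fixed square
# tiling in (x, y) has constant true area at every latitude.
.cea_xy <- function(lon, lat) {
  cbind(x = .EARTH_R * lon * pi / 180, y = .EARTH_R * sin(lat * pi / 180))
}

#' Area of occupancy on a 2 x 2 km grid
#'
#' Counts the distinct occupied cells of a fixed, world-anchored 2 km
#' equal-area tiling (Lambert cylindrical equal-area anchored at 0N 0E) and
#' multiplies by 4 km^2 per cell. Duplicated points and point order do not
#' change the result.
#'
#' @param lon,lat coordinates in degrees; at least one point.
#' @param cell_km tile edge length in km (default 2).
#' @return Occupied area in km^2.
#' @export
compute_aoo <- function(lon, lat, cell_km = 2) {
  if (length(lon) == 0) stop("compute_aoo: no points for species")
  stopifnot(length(lon) == length(lat))
  xy <- .cea_xy(lon, lat)
  ix <- floor(xy[, 1] / cell_km)
  iy <- floor(xy[, 2] / cell_km)
  length(unique(paste(ix, iy))) * cell_km^2
}

#' Flag minimal-area species
#'
#' A species is flagged for the minimal-area path (bypassing extent and
#' rate computation, entering the imputation stage and priority-by-default)
#' when it has fewer than five occurrence records or an area of occupancy
#' under 10 km^2 on the 2 x 2 km grid. Both comparisons are strict, and a
#' degenerate convex hull found later can add a third reason via
#' `degenerate`.
#'
#' @param occ quality-filtered occurrence data frame
#'   `(species, lon, lat, ...)`.
#' @param species optionally the full species universe, so species whose
#'   records were all filtered away are still flagged (with 0 records).
#' @param min_records,min_aoo_km2 strict thresholds (defaults 5 and 10).
#' @return Data frame `(species, n_records, aoo_km2, flagged, reason)`
#'   with reason one of `few_records`, `small_aoo`, `""`.
#' @export
flag_minimal_area <- function(occ, species = NULL, min_records = 5,
                              min_aoo_km2 = 10) {
  if (is.null(species)) species <- unique(occ$species)
  res <- lapply(species, function(sp) {
    sub <- occ[occ$species == sp, , drop = FALSE]
    n <- nrow(sub)
    aoo <- if (n == 0) 0 else compute_aoo(sub$lon, sub$lat)
    reason <- if (n < min_records) "few_records"
    else if (aoo < min_aoo_km2) "small_aoo" else ""
    data.frame(species = sp, n_records = n, aoo_km2 = aoo,
               flagged = nzchar(reason), reason = reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
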