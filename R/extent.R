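#' Minimum convex polygon of the centroid-nearest records
#'
#' Estimates a species' extent of occurrence as the convex hull of its
#' occurrence records after discarding the fraction of records farthest
#' from the arithmetic coordinate centroid (great-circle distance), the
#' usual home-range MCP construction. With `inclusion = 1` this is the
#' plain convex hull. Hulls with zero area (collinear or repeated points)
#' are flagged degenerate rather than silently kept, since a line covers no
#' area.
#'
#' @param lon,lat record coordinates in degrees; at least 5 points.
#' @param inclusion fraction of records to retain (default 0.95); the
#'   `round((1 - inclusion) * n)` centroid-farthest records are dropped,
#'   distance ties broken by record order.
#' @return An object of class `mcp`: list with `coords` (CCW hull vertex
#'   matrix), `kept`/`dropped` record indices, `degenerate` flag,
#'   `centroid`.
#' @export
mcp <- function(lon, lat, inclusion = 0.95) {
  n <- length(lon)
  stopifnot(length(lat) == n, inclusion > 0, inclusion <= 1)
  if (n < 5)
    stop("mcp requires at least 5 records; route species to minimal-area path")
  ctr <- c(mean(lon), mean(lat))
  d <- geosphere::distHaversine(cbind(lon, lat), ctr)
  k_drop <- floor((1 - inclusion) * n + 0.5)
  ord <- order(-d, seq_len(n))   # farthest first, ties by record order
  dropped <- if (k_drop > 0) ord[seq_len(k_drop)] else integer(0)
  kept <- setdiff(seq_len(n), dropped)
  pts <- cbind(lon[kept], lat[kept])
  hull <- convex_hull(pts)
  degenerate <- nrow(hull) < 3 || poly_area(hull) <= 0
  structure(list(coords = hull, kept = kept, dropped = dropped,
                 degenerate = degenerate, centroid = ctr, inclusion = inclusion),
            class = "mcp")
}

#' @export
print.mcp <- function(x, ...) {
  cat(sprintf("<mcp> %d hull vertices from %d kept records (%d dropped)%s\n",
              nrow(x$coords), length(x$kept), length(x$dropped),
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

# Deterministic sample points covering a 1-km-radius disc around (lon, lat),
# with the disc approximated in degrees (1/111.32 deg latitude per km).
.disc_points <- function(lon, lat, buffer_km, n_side = 24) {
  dlat <- buffer_km / 111.32
  dlon <- dlat / cos(lat * pi / 180)
  u <- seq(-1 + 1 / n_side, 1 - 1 / n_side, length.out = n_side)
  g <- expand.grid(ux = u, uy = u)
  inside <- g$ux^2 + g$uy^2 <= 1
  cbind(lon = lon + g$ux[inside] * dlon, lat = lat + g$uy[inside] * dlat)
}

#' Climatically suitable zones for a species
#'
#' Implements the buffer rule used to mask unsuitable climate from a
#' species' polygon: around every occurrence record a 1-km-radius disc is
#' laid over the zone raster; cells covering at least `cell_cover` of the
#' disc's area are collected (across all records, with multiplicity), and
#' every zone covering at least `zone_frac` of the collected cells is
#' declared suitable. Disc/cell overlap is evaluated on a deterministic
#' ~450-point disc sample.
#'
#' @param lon,lat occurrence coordinates (degrees).
#' @param zone_raster categorical [rrc_raster()] of zone ids.
#' @param buffer_km buffer radius (default 1 km).
#' @param zone_frac minimum share of collected cells a zone must cover
#'   (default 0.05, inclusive).
#' @param cell_cover minimum share of the disc a cell must cover to be
#'   collected (default 0.25, inclusive).
#' @return Integer vector of suitable zone ids.
#' @export
suitable_zones <- function(lon, lat, zone_raster, buffer_km = 1,
                           zone_frac = 0.05, cell_cover = 0.25) {
  stopifnot(inherits(zone_raster, "rrc_raster"), length(lon) == length(lat),
            length(lon) >= 1)
  g <- zone_raster$grid
  zone_counts <- integer(0)
  total_cells <- 0L
  for (i in seq_along(lon)) {
    pts <- .disc_points(lon[i], lat[i], buffer_km)
    idx <- cell_index(g, pts[, 1], pts[, 2])
    ok <- !is.na(idx$row)
    if (!all(ok))
      stop("zone raster does not cover the buffered occurrence at (",
           lon[i], ", ", lat[i], ")")
    key <- paste(idx$row, idx$col)
    tab <- table(key)
    cover <- as.numeric(tab) / nrow(pts)
    hit <- names(tab)[cover >= cell_cover]
    for (h in hit) {
      rc <- as.integer(strsplit(h, " ")[[1]])
      z <- zone_raster$values[rc[1], rc[2]]
      if (is.na(z)) next
      zk <- as.character(z)
      zone_counts[zk] <- if (zk %in% names(zone_counts))
        zone_counts[[zk]] + 1L else 1L
      total_cells <- total_cells + 1L
    }
  }
  if (total_cells == 0L)
    stop("no cell covers >= ", cell_cover,
         " of any occurrence buffer; zones unusable")
  share <- zone_counts / total_cells
  sort(as.integer(names(share)[share >= zone_frac]))
}

#' Refine a species polygon into a masked, coverage-weighted extent
#'
#' Intersects the minimum convex polygon with the analysis grid, keeping
#' only cells whose zone is suitable and that are land, and records for
#' each surviving cell the exact fraction of the cell covered by the
#' polygon. The extent area is the coverage-weighted sum of geodesic cell
#' areas, the quantity all unidirectional rates are normalised by.
#'
#' @param polygon an [mcp()] object or a CCW vertex matrix (lon, lat).
#' @param zones integer vector of suitable zone ids (non-empty).
#' @param zone_raster,water_mask categorical zone layer and binary water
#'   layer (1 = water) on `grid`.
#' @param grid the analysis [grid_spec()]; must match the raster grids.
#' @return An object of class `extent_mask`: list with `polygon`, `zones`,
#'   `cells` data frame `(row, col, w, area_km2)` with weights in (0, 1],
#'   `eoo_km2`, `empty` flag, and `grid`.
#' @export
refine_extent <- function(polygon, zones, zone_raster, water_mask, grid) {
  if (inherits(polygon, "mcp")) {
    if (polygon$degenerate)
      stop("cannot refine a degenerate (zero-area) polygon")
    poly <- polygon$coords
  } else poly <- polygon
  stopifnot(is.matrix(poly), nrow(poly) >= 3, length(zones) >= 1,
            inherits(grid, "grid_spec"))
  if (!grids_identical(zone_raster$grid, grid) ||
      !grids_identical(water_mask$grid, grid))
    stop("zone raster and water mask must share the analysis grid")
  if (max(poly[, 1]) - min(poly[, 1]) > 180)
    stop("antimeridian-crossing polygons are not supported")
  if (poly_area_signed(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), ]

  # candidate cell block from the polygon bounding box
  eps <- grid$res * 1e-9
  c1 <- max(1L, floor((min(poly[, 1]) - grid$xmin) / grid$res) + 1L)
  c2 <- min(grid$ncol, floor((max(poly[, 1]) - eps - grid$xmin) / grid$res) + 1L)
  r1 <- max(1L, grid$nrow - floor((max(poly[, 2]) - eps - grid$ymin) / grid$res))
  r2 <- min(grid$nrow, grid$nrow - floor((min(poly[, 2]) - grid$ymin) / grid$res))
  areas <- cell_area_km2(grid)
  cells <- NULL
  if (c1 <= c2 && r1 <= r2) {
    nrb <- r2 - r1 + 1L; ncb <- c2 - c1 + 1L
    # corner lattice of the candidate block
    cx <- grid$xmin + (c1 - 1L + 0:ncb) * grid$res
    cy <- grid$ymax - (r1 - 1L + 0:nrb) * grid$res  # north to south
    # half-plane values per hull edge at every corner (CCW => inside >= 0)
    nv <- nrow(poly)
    inside_all <- matrix(TRUE, nrb + 1L, ncb + 1L)
    edge_neg <- vector("list", nv)
    for (e in seq_len(nv)) {
      a <- poly[e, ]; b <- poly[if (e == nv) 1L else e + 1L, ]
      f <- outer(cy - a[2], rep(b[1] - a[1], ncb + 1L)) -
        outer(rep(b[2] - a[2], nrb + 1L), cx - a[1])
      inside_all <- inside_all & (f >= 0)
      edge_neg[[e]] <- f < 0
    }
    corner_and <- function(m) m[1:nrb, 1:ncb, drop = FALSE] &
      m[1:nrb, 2:(ncb + 1), drop = FALSE] &
      m[2:(nrb + 1), 1:ncb, drop = FALSE] &
      m[2:(nrb + 1), 2:(ncb + 1), drop = FALSE]
    full_in <- corner_and(inside_all)
    empty <- matrix(FALSE, nrb, ncb)
    for (e in seq_len(nv)) empty <- empty | corner_and(edge_neg[[e]])

    res_list <- list()
    for (i in seq_len(nrb)) {
      row <- r1 + i - 1L
      for (j in seq_len(ncb)) {
        if (empty[i, j]) next
        col <- c1 + j - 1L
        w <- if (full_in[i, j]) 1 else {
          rect <- cell_bounds(grid, row, col)
          rect_cover_fraction(poly, rect)
        }
        if (w <= 1e-12) next
        z <- zone_raster$values[row, col]
        if (is.na(z) || !(z %in% zones)) next
        if (isTRUE(water_mask$values[row, col] == 1)) next
        res_list[[length(res_list) + 1L]] <-
          c(row, col, min(w, 1), areas[row])
      }
    }
    if (length(res_list)) {
      m <- do.call(rbind, res_list)
      cells <- data.frame(row = as.integer(m[, 1]), col = as.integer(m[, 2]),
                          w = m[, 3], area_km2 = m[, 4])
    }
  }
  if (is.null(cells))
    cells <- data.frame(row = integer(0), col = integer(0),
                        w = numeric(0), area_km2 = numeric(0))
  structure(list(polygon = poly, zones = zones, cells = cells,
                 eoo_km2 = sum(cells$w * cells$area_km2),
                 empty = nrow(cells) == 0, grid = grid),
            class = "extent_mask")
}

#' @export
print.extent_mask <- function(x, ...) {
  cat(sprintf("<extent_mask> %d cells, EOO area %.2f km^2, zones {%s}%s\n",
              nrow(x$cells), x$eoo_km2, paste(x$zones, collapse = ","),
              if (x$empty) " [empty]" else ""))
  invisible(x)
}

#' Classify extent size per IUCN criterion B ranges
#'
#' `wide` above 20,000 km^2, `regional` in (5,000, 20,000], `local` at or
#' below 5,000 km^2.
#'
#' @param area_km2 non-negative extent area(s) in km^2.
#' @return Character vector in `{"wide", "regional", "local"}`.
#' @export
extent_class <- function(area_km2) {
  if (any(area_km2 < 0)) stop("extent area cannot be negative")
  ifelse(area_km2 > 20000, "wide",
         ifelse(area_km2 > 5000, "regional", "local"))
}

#' Serialize / read an extent mask
#'
#' Cells go to a CSV of `(row, col, w)`; species id, suitable zones, the
#' grid and the extent area go to a JSON header alongside.
#'
#' @param x an [extent_mask()].
#' @param stem output path stem; writes `<stem>.csv` and `<stem>.json`.
#' @param species species id recorded in the header.
#' @return `stem`, invisibly.
#' @export
write_extent <- function(x, stem, species = "") {
  stopifnot(inherits(x, "extent_mask"))
  utils::write.csv(x$cells[, c("row", "col", "w")],
                   paste0(stem, ".csv"), row.names = FALSE)
  g <- x$grid
  hdr <- list(species = species, zones = x$zones, eoo_km2 = x$eoo_km2,
              grid = list(xmin = g$xmin, ymin = g$ymin, res = g$res,
                          ncol = g$ncol, nrow = g$nrow))
  jsonlite::write_json(hdr, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}
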