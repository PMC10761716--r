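# Hotspot mapping: stack rasterized species extents, count overlaps,
# normalise priority counts by total counts, and overlay per-threat
# hotspot presence.

#' Rasterize an extent to presence/absence
#'
#' Every cell carried by the extent (coverage weight > 0) becomes 1,
#' regardless of how small the coverage fraction is; presence is binary.
#'
#' @param extent an [extent_mask()].
#' @param grid target [grid_spec()]; must equal the extent's grid.
#' @return Binary [rrc_raster()].
#' @export
rasterize_extent <- function(extent, grid = extent$grid) {
  stopifnot(inherits(extent, "extent_mask"))
  if (!grids_identical(extent$grid, grid))
    stop("extent not on the requested grid")
  v <- matrix(0L, grid$nrow, grid$ncol)
  if (nrow(extent$cells))
    v[cbind(extent$cells$row, extent$cells$col)] <- 1L
  rrc_raster(grid, v)
}

#' Count overlapping species extents per cell
#'
#' Cellwise sum of the rasterized extents: the species-richness surface
#' for whatever set of extents is passed (all species, or the priority
#' candidates of one threat).
#'
#' @param extents list of [extent_mask()]s on a shared grid.
#' @param grid the shared [grid_spec()].
#' @return [rrc_raster()] of integer counts.
#' @export
count_stack <- function(extents, grid) {
  v <- matrix(0L, grid$nrow, grid$ncol)
  for (e in extents) {
    stopifnot(inherits(e, "extent_mask"))
    if (!grids_identical(e$grid, grid))
      stop("all extents must share the grid")
    if (nrow(e$cells)) {
      idx <- cbind(e$cells$row, e$cells$col)
      v[idx] <- v[idx] + 1L
    }
  }
  rrc_raster(grid, v)
}

#' Fraction of local species that are priority candidates
#'
#' Cellwise `priority / total`, masked (`NA`) where the total count is
#' zero. Errors if any cell has more priority than total species.
#'
#' @param priority_counts,total_counts count rasters from [count_stack()]
#'   on the same grid.
#' @return [rrc_raster()] of fractions in `[0, 1]` with `NA` outside any
#'   species extent.
#' @export
fraction_map <- function(priority_counts, total_counts) {
  if (!grids_identical(priority_counts$grid, total_counts$grid))
    stop("count rasters disagree on grid")
  p <- priority_counts$values; tot <- total_counts$values
  if (any(p > tot)) stop("priority count exceeds total count in some cell")
  f <- ifelse(tot > 0, p / tot, NA_real_)
  rrc_raster(total_counts$grid, f)
}

#' Overlay binarized per-threat hotspot maps
#'
#' A threat's hotspot layer is 1 wherever at least one priority species
#' for that threat is present. The overlay is the cellwise sum over the
#' six threat layers, i.e. the number of threats with exposed species per
#' cell (0-6).
#'
#' @param per_threat_hotspots list of exactly six binary [rrc_raster()]s
#'   (or count rasters, binarized internally) on a shared grid.
#' @return [rrc_raster()] with integer values 0-6.
#' @export
threat_overlay <- function(per_threat_hotspots) {
  if (length(per_threat_hotspots) != 6)
    stop("threat overlay needs exactly 6 layers")
  g <- per_threat_hotspots[[1]]$grid
  v <- matrix(0L, g$nrow, g$ncol)
  for (r in per_threat_hotspots) {
    if (!grids_identical(r$grid, g)) stop("overlay layers disagree on grid")
    v <- v + (r$values > 0)
  }
  rrc_raster(g, v)
}

#' Plot a hotspot (or any) raster layer
#'
#' Base-graphics image of a raster with a legend; masked cells are left
#' blank.
#'
#' @param x an [rrc_raster()].
#' @param main plot title.
#' @param col color ramp.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.rrc_raster <- function(x, main = "", col = grDevices::hcl.colors(32,
                            "YlOrRd", rev = TRUE), ...) {
  g <- x$grid
  z <- t(x$values[g$nrow:1, , drop = FALSE])  # image() wants x-y order
  graphics::image(x = g$xmin + (0:g$ncol) * g$res,
                  y = g$ymin + (0:g$nrow) * g$res,
                  z = z, col = col, xlab = "Longitude", ylab = "Latitude",
                  main = main, useRaster = TRUE, ...)
  invisible(x)
}
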