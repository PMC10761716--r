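# Mean Earth radius (km), IUGG value used for all geodesic cell areas.
.EARTH_R <- 6371.0088

#' Define a regular WGS84 longitude-latitude grid
#'
#' All raster layers in the package live on a `grid_spec`: a regular grid of
#' square (in degrees) cells with half-open extents `[west, east) x
#' [south, north)`. Rows are ordered north to south (row 1 is the
#' northernmost), matching the usual raster storage convention.
#'
#' @param xmin,ymin western and southern edge of the grid (decimal degrees).
#' @param res cell size in degrees; must be positive.
#' @param ncol,nrow number of columns and rows.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(0, 0, res = 0.5, ncol = 20, nrow = 10)
#' cell_area_km2(g)[1]  # area of a northernmost-row cell
#' @export
grid_spec <- function(xmin, ymin, res, ncol, nrow) {
  stopifnot(is.numeric(res), res > 0, ncol >= 1, nrow >= 1)
  g <- list(
    xmin = xmin, ymin = ymin, res = res,
    ncol = as.integer(ncol), nrow = as.integer(nrow),
    xmax = xmin + ncol * res, ymax = ymin + nrow * res
  )
  if (g$ymax > 90 + 1e-9 || ymin < -90 - 1e-9 ||
      g$xmax > 180 + 1e-9 || xmin < -180 - 1e-9)
    stop("grid extends beyond valid WGS84 longitude/latitude bounds")
  class(g) <- "grid_spec"
  g
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells at %g deg, extent [%g, %g] x [%g, %g]\n",
              x$nrow, x$ncol, x$res, x$xmin, x$xmax, x$ymin, x$ymax))
  invisible(x)
}

#' @export
format.grid_spec <- function(x, ...) {
  sprintf("%dx%d@%g[%g,%g,%g,%g]", x$nrow, x$ncol, x$res,
          x$xmin, x$ymin, x$xmax, x$ymax)
}

grids_identical <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-12))
}

#' Longitude of cell centers (one per column)
#' @param grid a [grid_spec()].
#' @return Numeric vector of length `ncol`.
#' @export
cell_lon <- function(grid) grid$xmin + (seq_len(grid$ncol) - 0.5) * grid$res

#' Latitude of cell centers (one per row, north to south)
#' @param grid a [grid_spec()].
#' @return Numeric vector of length `nrow`.
#' @export
cell_lat <- function(grid) grid$ymax - (seq_len(grid$nrow) - 0.5) * grid$res

#' Geodesic cell area per row (km^2)
#'
#' On a regular lon-lat grid, cell area depends on latitude only:
#' `(pi * R / 180 * res)^2 * cos(lat_center)` with `R = 6371.0088` km.
#'
#' @param grid a [grid_spec()].
#' @return Numeric vector of per-row cell areas (km^2), row 1 northernmost.
#' @export
cell_area_km2 <- function(grid) {
  (pi * .EARTH_R / 180 * grid$res)^2 * cos(cell_lat(grid) * pi / 180)
}

# (row, col) of cells containing points; half-open cells. Points outside the
# grid get NA.
cell_index <- function(grid, lon, lat) {
  col <- floor((lon - grid$xmin) / grid$res) + 1L
  row_s <- floor((lat - grid$ymin) / grid$res) + 1L  # counted from south
  row <- grid$nrow - row_s + 1L
  bad <- col < 1L | col > grid$ncol | row < 1L | row > grid$nrow
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = row, col = col)
}

# west, south, east, north bounds of a cell
cell_bounds <- function(grid, row, col) {
  w <- grid$xmin + (col - 1L) * grid$res
  s <- grid$ymax - row * grid$res
  c(w = w, s = s, e = w + grid$res, n = s + grid$res)
}

#' Construct a raster layer on a grid
#'
#' A thin container pairing a [grid_spec()] with a numeric matrix of values
#' (`nrow x ncol`, row 1 northernmost).
#'
#' @param grid a [grid_spec()].
#' @param values numeric matrix with `dim = c(grid$nrow, grid$ncol)`, or a
#'   single number to fill the grid.
#' @return An object of class `rrc_raster`.
#' @export
rrc_raster <- function(grid, values) {
  stopifnot(inherits(grid, "grid_spec"))
  if (length(values) == 1L)
    values <- matrix(values, grid$nrow, grid$ncol)
  stopifnot(is.matrix(values),
            nrow(values) == grid$nrow, ncol(values) == grid$ncol)
  structure(list(grid = grid, values = values), class = "rrc_raster")
}

#' @export
print.rrc_raster <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("<rrc_raster> %s  values: [%g, %g], NA: %d\n",
              format(x$grid), suppressWarnings(min(v)),
              suppressWarnings(max(v)), sum(!is.finite(x$values))))
  invisible(x)
}

#' Write / read a raster as an ESRI ASCII grid
#'
#' Plain-text `.asc` format: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows of
#' values north to south. All layers are WGS84 (EPSG:4326) by package
#' convention; the format itself carries no CRS tag.
#'
#' @param x an [rrc_raster()].
#' @param path file path.
#' @param nodata value used to encode `NA` cells.
#' @return `write_ascii_grid` returns `path` invisibly; `read_ascii_grid`
#'   returns an [rrc_raster()].
#' @export
write_ascii_grid <- function(x, path, nodata = -9999) {
  stopifnot(inherits(x, "rrc_raster"))
  g <- x$grid
  hdr <- c(
    sprintf("ncols %d", g$ncol), sprintf("nrows %d", g$nrow),
    sprintf("xllcorner %.10g", g$xmin), sprintf("yllcorner %.10g", g$ymin),
    sprintf("cellsize %.10g", g$res), sprintf("NODATA_value %g", nodata)
  )
  v <- x$values
  v[!is.finite(v)] <- nodata
  rows <- apply(v, 1L, function(r) paste(format(r, trim = TRUE, digits = 15),
                                         collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(vapply(kv, `[`, "", 2L))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% keys)) stop("malformed ASCII grid header in ", path)
  nodata <- if ("nodata_value" %in% keys) vals[["nodata_value"]] else -9999
  body <- lines[-(1:6)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != vals[["nrows"]])
    stop("ASCII grid body has ", length(body), " rows, header says ",
         vals[["nrows"]], ": ", path)
  v <- t(vapply(strsplit(trimws(body), "\\s+"),
                function(r) as.numeric(r), numeric(vals[["ncols"]])))
  v[v == nodata] <- NA_real_
  g <- grid_spec(vals[["xllcorner"]], vals[["yllcorner"]], vals[["cellsize"]],
                 vals[["ncols"]], vals[["nrows"]])
  rrc_raster(g, v)
}

#' Construct an annual raster stack
#'
#' One layer per calendar year on a shared grid; used for burned-area
#' indicators and the yearly climate variables. Temperature layers are stored
#' in degrees Celsius, vapour pressure deficit in Pa, precipitation in mm.
#'
#' @param variable variable name (e.g. `"tmin"`, `"vpd"`, `"burned"`).
#' @param years strictly increasing integer vector of calendar years.
#' @param layers list of value matrices, one per year.
#' @param grid the shared [grid_spec()].
#' @param units unit string recorded with the stack.
#' @return An object of class `annual_stack`.
#' @export
annual_stack <- function(variable, years, layers, grid, units = "") {
  stopifnot(length(years) == length(layers), length(years) >= 1,
            all(diff(years) > 0), inherits(grid, "grid_spec"))
  for (l in layers)
    stopifnot(is.matrix(l), nrow(l) == grid$nrow, ncol(l) == grid$ncol)
  structure(list(variable = variable, years = as.integer(years),
                 layers = layers, grid = grid, units = units),
            class = "annual_stack")
}

#' @export
print.annual_stack <- function(x, ...) {
  cat(sprintf("<annual_stack> %s [%s], %d years %d-%d on %s\n", x$variable,
              x$units, length(x$years), min(x$years), max(x$years),
              format(x$grid)))
  invisible(x)
}

#' Write / read an annual stack as ASCII grids plus a JSON header
#'
#' Each year becomes `<variable>_<year>.asc` in `dir`; a
#' `<variable>_stack.json` sidecar records variable, units and year order.
#' On reading, layers are reordered by year if the sidecar lists them
#' unsorted, with a warning.
#'
#' @param x an [annual_stack()].
#' @param dir directory (created if needed).
#' @param variable stack variable name to read.
#' @return `write_stack` returns `dir` invisibly; `read_stack` an
#'   [annual_stack()].
#' @export
write_stack <- function(x, dir) {
  stopifnot(inherits(x, "annual_stack"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- sprintf("%s_%d.asc", x$variable, x$years)
  for (i in seq_along(x$years))
    write_ascii_grid(rrc_raster(x$grid, x$layers[[i]]), file.path(dir, files[i]))
  meta <- list(variable = x$variable, units = x$units,
               years = x$years, files = files)
  jsonlite::write_json(meta, file.path(dir, paste0(x$variable, "_stack.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_stack
#' @export
read_stack <- function(dir, variable) {
  meta_path <- file.path(dir, paste0(variable, "_stack.json"))
  if (!file.exists(meta_path)) stop("no stack metadata at ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  ord <- order(meta$years)
  if (is.unsorted(meta$years))
    warning("stack years for '", variable, "' listed unsorted; reordering")
  rasters <- lapply(file.path(dir, meta$files[ord]), read_ascii_grid)
  g <- rasters[[1]]$grid
  for (r in rasters[-1])
    if (!grids_identical(r$grid, g)) stop("stack layers disagree on grid")
  annual_stack(meta$variable, meta$years[ord],
               lapply(rasters, `[[`, "values"), g, meta$units)
}
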