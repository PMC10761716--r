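# Delimited-text I/O for the pipeline's tables. All readers validate the
# column contract and coordinate bounds; rasters and stacks have their own
# readers in grid.R.

#' Read / write occurrence tables
#'
#' CSV with columns `species, lon, lat, label`. The reader validates the
#' header and WGS84 coordinate bounds.
#'
#' @param path CSV path.
#' @param occ occurrence data frame.
#' @return `read_occurrences` returns the data frame; `write_occurrences`
#'   returns `path` invisibly.
#' @export
read_occurrences <- function(path) {
  occ <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "lon", "lat", "label")
  if (!all(need %in% names(occ)))
    stop("occurrence file ", path, " must have columns ",
         paste(need, collapse = ", "))
  if (any(occ$lon < -180 | occ$lon > 180 | occ$lat < -90 | occ$lat > 90))
    stop("occurrence coordinates outside WGS84 bounds in ", path)
  occ[need]
}

#' @rdname read_occurrences
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(occ[, c("species", "lon", "lat", "label")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read / write IUCN status tables
#'
#' CSV with columns `species, category`; unknown category codes are
#' rejected by [status_group()] at use time, not here.
#'
#' @param path CSV path.
#' @param status status data frame.
#' @return The data frame, or `path` invisibly.
#' @export
read_status <- function(path) {
  st <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species", "category") %in% names(st)))
    stop("status file ", path, " must have columns species, category")
  st[c("species", "category")]
}

#' @rdname read_status
#' @export
write_status <- function(status, path) {
  utils::write.csv(status[, c("species", "category")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Write all pipeline outputs to a directory
#'
#' Writes the rate table, removed outliers, imputed rates, thresholds,
#' candidate table, congruence table and manifest (CSV/JSON) plus the
#' hotspot rasters (ASCII grid) produced by [rrc_pipeline()].
#'
#' @param result an `rrc_analysis` object from [rrc_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_outputs <- function(result, dir) {
  stopifnot(inherits(result, "rrc_analysis"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, f) utils::write.csv(df, file.path(dir, f),
                                        row.names = FALSE)
  w(result$rrc, "rrc_rates.csv")
  w(result$outliers, "outliers_removed.csv")
  if (!is.null(result$imputed)) w(result$imputed, "imputed_rates.csv")
  w(result$thresholds, "thresholds.csv")
  jsonlite::write_json(result$thresholds, file.path(dir, "thresholds.json"),
                       auto_unbox = TRUE, digits = NA)
  w(result$candidates, "candidates.csv")
  w(result$congruence, "congruence.csv")
  w(result$flags, "minimal_area_flags.csv")
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  write_ascii_grid(result$hotspots$all_species,
                   file.path(dir, "count_all_species.asc"))
  write_ascii_grid(result$hotspots$priority_union,
                   file.path(dir, "count_priority_union.asc"))
  write_ascii_grid(result$hotspots$fraction,
                   file.path(dir, "fraction_priority.asc"))
  write_ascii_grid(result$hotspots$overlay,
                   file.path(dir, "threat_overlay.asc"))
  for (th in names(result$hotspots$by_threat))
    write_ascii_grid(result$hotspots$by_threat[[th]],
                     file.path(dir, sprintf("count_priority_%s.asc", th)))
  invisible(dir)
}
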