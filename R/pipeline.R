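# End-to-end driver: occurrence QC -> refined extents -> rates of recent
# change -> outlier removal -> minimal-area imputation -> prioritization ->
# hotspot maps, with a reconciling run manifest.

.UNI_THREATS <- c("cropland", "treecover", "builtup", "deforestation")
.CLIM_VARS <- c("tmin", "tmax", "vpd", "vpd_seas", "prec", "prec_seas")

#' Column-to-threat mapping used for candidate counting and the overlay
#'
#' The six threats are the four land-conversion threats, burned area, and
#' climate change; the six climate variables collapse into the single
#' climate threat.
#'
#' @return Named character vector mapping rate columns to threat names.
#' @export
threat_map <- function() {
  stats::setNames(
    c(.UNI_THREATS, "burned", rep("climate", length(.CLIM_VARS))),
    c(.UNI_THREATS, "burned", .CLIM_VARS))
}

#' Run the full threat-exposure analysis
#'
#' Executes every stage of the analysis on a synthetic world (or any list
#' with the same components): quality filtering and minimal-area flagging,
#' MCP-95 extents masked to suitable zones and land, unidirectional and
#' bidirectional rates of recent change, outlier removal, imputation for
#' minimal-area species, percentile-threshold prioritization against the
#' status table, and hotspot rasters. Deterministic given the world.
#'
#' @param world a `synthetic_world` from [gen_world()], or a list with
#'   `occ`, `zones`, `water`, `change` (+`divisors`), `stacks`, `status`.
#' @param alpha significance level of the bidirectional trend gate.
#' @param q upper quantile level for priority thresholds.
#' @param allowed quality-label allowlist.
#' @param inclusion MCP record-inclusion fraction.
#' @param climate_years optional year subset for climate rates (decadal
#'   re-windowing); `NULL` uses the full window.
#' @param verbose print per-stage progress.
#' @return An object of class `rrc_analysis`: list with `flags`, `extents`,
#'   `extent_table` (species, eoo_km2, size class), `rrc` (wide rate
#'   table), `outliers`, `imputed`, `thresholds`, `candidates`,
#'   `congruence`, `hotspots`, `manifest`.
#' @export
rrc_pipeline <- function(world, alpha = 0.05, q = 0.95,
                         allowed = c("AAA", "AA", "A", "B", "C"),
                         inclusion = 0.95, climate_years = NULL,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  all_species <- sort(unique(world$occ$species))
  grid <- world$zones$grid

  say("QC: filtering %d records", nrow(world$occ))
  occ <- filter_quality(world$occ, allowed)
  flags <- flag_minimal_area(occ, species = all_species)
  minimal <- flags$species[flags$flagged]
  work <- setdiff(all_species, minimal)

  say("extents: %d species", length(work))
  extents <- list()
  degenerate <- character(0)
  extent_rows <- list()
  for (sp in work) {
    sub <- occ[occ$species == sp, ]
    hull <- mcp(sub$lon, sub$lat, inclusion = inclusion)
    if (hull$degenerate) {
      degenerate <- c(degenerate, sp)
      next
    }
    zones <- tryCatch(suitable_zones(sub$lon, sub$lat, world$zones),
                      error = function(e) integer(0))
    ext <- if (length(zones) == 0) NULL
    else refine_extent(hull, zones, world$zones, world$water, grid)
    if (is.null(ext) || ext$empty) {
      # unusable zones or fully masked: no area to measure rates over
      minimal <- c(minimal, sp)
      next
    }
    extents[[sp]] <- ext
    extent_rows[[sp]] <- data.frame(
      species = sp, eoo_km2 = ext$eoo_km2,
      size_class = extent_class(ext$eoo_km2), stringsAsFactors = FALSE)
  }
  analyzed <- names(extents)
  extent_table <- do.call(rbind, extent_rows)
  rownames(extent_table) <- NULL

  say("rates: %d species x %d layers", length(analyzed),
      length(world$change) + length(world$stacks))
  rrc_rows <- lapply(analyzed, function(sp) {
    ext <- extents[[sp]]
    row <- list(species = sp)
    for (th in names(world$change))
      row[[th]] <- unidirectional_rrc(ext, world$change[[th]],
                                      world$divisors[[th]])$rate
    for (v in names(world$stacks)) {
      mode <- if (v == "burned") "sum_area" else "weighted_mean"
      yrs <- if (v != "burned") climate_years else NULL
      row[[v]] <- bidirectional_rrc(ext, world$stacks[[v]], mode,
                                    alpha = alpha, years = yrs)$rate
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  rrc <- do.call(rbind, rrc_rows)

  say("outliers")
  outl <- remove_outliers(rrc)
  rrc_clean <- outl$table
  n_outlier <- length(unique(outl$removed$species))

  say("imputation: %d minimal-area species", length(minimal))
  imputed <- if (length(minimal) && nrow(rrc_clean))
    impute_minimal_species(minimal, world$occ, rrc_clean) else NULL

  say("prioritization")
  bidir_cols <- intersect(c("burned", .CLIM_VARS), names(rrc_clean))
  thresholds <- compute_thresholds(rrc_clean, q = q,
                                   bidirectional = bidir_cols,
                                   min_n = min(20, nrow(rrc_clean)))
  tm <- threat_map()
  candidates <- flag_candidates(rrc_clean, thresholds,
                                minimal_species = c(minimal, degenerate),
                                threat_of = tm)
  congruence <- congruence_summary(candidates, world$status)

  say("hotspots")
  total_counts <- count_stack(extents[analyzed], grid)
  prio_sp <- candidates$species[candidates$priority &
                                  candidates$priority_reason == "threat"]
  union_counts <- count_stack(extents[intersect(prio_sp, analyzed)], grid)
  threats <- unique(unname(tm))
  by_threat <- lapply(threats, function(th) {
    colflag <- paste0("threat_", th)
    sp <- candidates$species[candidates[[colflag]] %in% TRUE]
    count_stack(extents[intersect(sp, analyzed)], grid)
  })
  names(by_threat) <- threats
  hotspots <- list(
    all_species = total_counts,
    priority_union = union_counts,
    fraction = fraction_map(union_counts, total_counts),
    by_threat = by_threat,
    overlay = threat_overlay(by_threat))

  manifest <- list(
    n_input = length(all_species),
    n_analyzed = length(analyzed) - n_outlier,
    n_minimal_area = length(minimal),
    n_degenerate = length(degenerate),
    n_outlier_removed = n_outlier,
    species_minimal = minimal, species_degenerate = degenerate,
    species_outlier = unique(outl$removed$species),
    n_records_input = nrow(world$occ), n_records_qc = nrow(occ),
    alpha = alpha, quantile = q, inclusion = inclusion,
    allowed_labels = allowed,
    grid = format(grid))
  manifest$reconciles <- manifest$n_input ==
    manifest$n_analyzed + manifest$n_minimal_area +
    manifest$n_degenerate + manifest$n_outlier_removed

  structure(list(flags = flags, extents = extents,
                 extent_table = extent_table, rrc = rrc,
                 rrc_clean = rrc_clean, outliers = outl$removed,
                 imputed = imputed, thresholds = thresholds,
                 candidates = candidates, congruence = congruence,
                 hotspots = hotspots, manifest = manifest),
            class = "rrc_analysis")
}

#' @export
print.rrc_analysis <- function(x, ...) {
  m <- x$manifest
  cat("Threat-exposure analysis\n")
  cat(sprintf("  species: %d input = %d analyzed + %d minimal-area + %d degenerate + %d outlier\n",
              m$n_input, m$n_analyzed, m$n_minimal_area, m$n_degenerate,
              m$n_outlier_removed))
  cat(sprintf("  priority candidates: %d (%d by threat exposure, %d minimal-area)\n",
              sum(x$candidates$priority),
              sum(x$candidates$priority_reason == "threat"),
              sum(x$candidates$priority_reason == "minimal_area")))
  invisible(x)
}

#' @export
summary.rrc_analysis <- function(object, ...) {
  rates <- object$rrc_clean
  num_cols <- setdiff(names(rates), "species")
  stats_tab <- do.call(rbind, lapply(num_cols, function(cl) {
    v <- rates[[cl]]
    data.frame(column = cl, median = stats::median(v, na.rm = TRUE),
               q95 = stats::quantile(v, 0.95, na.rm = TRUE, names = FALSE),
               max = max(v, na.rm = TRUE), stringsAsFactors = FALSE)
  }))
  structure(list(analysis = object, rate_summary = stats_tab),
            class = "summary.rrc_analysis")
}

#' @export
print.summary.rrc_analysis <- function(x, ...) {
  print(x$analysis)
  cat("  rate summary (per column):\n")
  print(x$rate_summary, row.names = FALSE, digits = 4)
  cat("  congruence of candidates with status groups:\n")
  print(x$analysis$congruence, row.names = FALSE, digits = 3)
  invisible(x)
}
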