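Package: rrcmap
Title: Threat Exposure and Rates of Recent Change Within Species Extents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies species-level exposure to anthropogenic threats from
    gridded time series. Builds refined species extents from occurrence
    records (95% minimum convex polygons masked to climatically suitable
    zones and land), computes per-species rates of recent change for
    unidirectional land-conversion threats and bidirectional trend threats
    (robust Siegel repeated-medians slopes gated by a Mann-Kendall
    significance test), flags highly exposed species against IUCN Red List
    status groups using percentile thresholds, and maps hotspots of exposed
    species by stacking rasterized extents. Includes a synthetic-data
    generator with planted ground truth so the full pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
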