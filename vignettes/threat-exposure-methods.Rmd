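---
title: "Methods: quantifying threat exposure within species extents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying threat exposure within species extents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrcmap)
```

## The problem

Expert-based Red List assessment is slow and data-hungry, while the
pressures on species — land conversion, fire-regime change, climate change —
shift on decadal time scales. `rrcmap` implements a data-driven exposure
screen: for each species it measures the *rate of recent change* (RRC) of
each threat inside the species' range over roughly the last two decades, and
flags the most exposed species as candidates for (re-)assessment. Exposure
is deliberately measured independently of any species' sensitivity or
adaptive capacity: the output is a prioritisation aid, not a risk verdict.

## Species extents

The unit of analysis is the *species extent*, built in three steps.

1. **MCP-95.** The extent of occurrence is estimated as the minimum convex
   polygon of the quality-filtered occurrence records after discarding the
   5% of records farthest (great-circle) from the arithmetic coordinate
   centroid. Which records constitute the "outer" 5% is not uniquely
   defined; we use centroid distance with ties broken by record order,
   matching the common home-range MCP convention. Records kept are a
   conservative range estimate: distant stragglers (country centroids, old
   or mislabelled collections) are cheap to exclude and expensive to keep.
2. **Climate-zone masking.** Wide-ranging hulls cover large climatically
   unsuitable areas. Around every record a 1-km-radius buffer is laid over a
   categorical climate-zone raster; cells covering at least 25% of the
   buffer's area are collected, and zones covering at least 5% of the
   collected cells are the species' suitable zones. Both thresholds are
   inclusive ("at least"). The 25% rule is read as *relative to the buffer
   area*, the more conservative of the two possible readings. The buffer is
   a disc in degree space scaled by `1/cos(latitude)` in longitude; at a 1 km
   radius the planar approximation error is negligible.
3. **Coverage-weighted area.** The polygon is intersected with the analysis
   grid; cells in unsuitable zones or water are dropped, and each surviving
   cell contributes `w * a(cell)` to the extent area, where `w` is the exact
   fraction of the cell covered by the polygon (Sutherland–Hodgman clipping
   of the convex hull against the cell rectangle) and
   `a = (pi R/180 * res)^2 cos(lat)` km² with `R = 6371.0088` km. Coverage
   fractions are computed in the longitude–latitude plane, which is exact to
   first order within a single small cell; absolute areas always come from
   the geodesic formula. The test suite checks the weighted areas against a
   dense-lattice sampling oracle at 10⁴ points per cell.

Species with fewer than five records, with an area of occupancy below
10 km² (distinct occupied cells of a fixed 2×2 km equal-area tiling,
anchored Lambert cylindrical equal-area at 0°N 0°E — the projection is our
choice; an equal-area tiling is the only one that preserves the km²
semantics at all latitudes), or with a zero-area (collinear) hull bypass the
rate computation entirely: single- or few-cell extraction from global grids
is dominated by map error, so these species are flagged minimal-area,
prioritised by default, and later given imputed rates. Both thresholds are
strict (`< 5`, `< 10 km²`), following their "less than"/"smaller than"
definitions.

## Rates of recent change

**Unidirectional threats** (cropland expansion, tree-cover decline, built-up
expansion, deforestation) are one-way conversions: once converted, a cell
stays counted even if later abandoned. Each threat arrives as a binary
change layer with a time-window divisor `Y`:

| threat | rule | Y (yr) |
|---|---|---|
| cropland | converted in any epoch after the 2000–03 baseline, excluding baseline cropland | 16 |
| tree cover | any single consecutive 5-year comparison dropping ≥ 5 percentage points | 15 |
| built-up | expansion class only (stable built-up excluded) | 20 |
| deforestation | complete canopy loss 2000–2020 | 20 |

The rate is `100 * (changed area within extent) / (extent area) / Y`, in
percent of extent per year, bounded by `100 / Y` (5 %/yr for a 20-year
window — the saturation a fully converted extent reaches). The 5-point
tree-cover rule is applied per comparison, not cumulatively: three
successive 3-point drops do not trip it.

**Bidirectional threats** (burned area; minimum and maximum temperature,
vapour pressure deficit and its seasonality, precipitation and its
seasonality) can move either way. Per year we aggregate over the extent —
summed coverage-weighted burned area (km²), or the coverage-and-area
weighted mean of the climate variable — and fit a robust trend to the
yearly series with **Siegel repeated medians**: per point the median of its
pairwise slopes, then the median over points. The estimator has a 50%
breakdown point, so single anomalous years cannot move it. Annual
temperature extremes are the min/max over 12 monthly layers; seasonality is
the (sample) standard deviation over the 12 months.

The slope only becomes a rate if the trend is *significant*; otherwise the
rate is stored as exact 0 (flagged), and those zeros participate in the
percentile thresholds below. For the significance gate we use the
two-sided **Mann–Kendall test** (Kendall's tau of value against year) at
α = 0.05. A seemingly natural alternative — a signed-rank test on the
per-point median slopes — is not usable: those per-point slopes share
pairwise terms and are strongly mutually correlated, so the signed-rank
null distribution does not apply and the test rejects a true null far more
often than α. Mann–Kendall is the standard companion test for median-based
trend slopes, and its calibration (rejection rate within three binomial
standard errors of α under a Gaussian null at n = 20) is verified by the
test suite and recomputed by `scripts/acceptance.R`. Ties in the Kendall
statistic are handled by `stats::cor.test`'s tie-corrected normal
approximation. Significant burned-area slopes are re-expressed as percent
of extent per year (`100 * slope / extent area`); climate slopes stay in
native units per year. A 10-year re-windowing option recomputes climate
rates per decade, matching the Red List's re-evaluation cycle.

**Outliers and imputation.** Per rate column, species beyond three
interpercentile ranges (Q99 − Q1) outside the 1%/99% quantiles are removed
from the cross-status analysis. We read the "interquartile range" of the
rule as the Q99 − Q1 span its anchors define; anchoring a literal
Q75 − Q25 band at the 1%/99% quantiles would mix two unrelated scales.
Minimal-area species inherit rates from co-occurring species: on a 1° grid,
each cell's value is the mean rate of the valued species recorded in it
(presence means an occurrence record in the cell, not extent overlap), and
a species' imputed rate is the median over its occupied cells.

## Prioritisation and hotspots

Literature-defined exposure thresholds do not exist, so candidates are
defined relative to the assemblage: per rate column the 95th percentile
(type-7 linear interpolation, the R default — recorded so the order
statistics are reproducible) over all non-removed species, zeros included.
Bidirectional columns threshold both tails (5th and 95th percentiles),
since decreases in burned area or precipitation are threats too. A species
is a candidate when its rate *strictly exceeds* a threshold; with all
distinct rates this proposes ⌊0.05 N⌋ or ⌈0.05 N⌉ species per column. The
six climate variables collapse to a single climate threat for counting, so
each species faces 0–6 threats. Minimal-area species are priority by
default, with a distinct reason code.

Hotspots stack rasterized extents (presence per cell regardless of coverage
weight): counts of all species, counts of priority species per threat and
their union, the priority fraction (masked where no species occurs; the
denominator is the species with computed rates, since only they can be
threshold candidates), and a 0–6 overlay counting threats with at least one
priority species per cell — presence, not a count threshold, makes a cell
part of a threat's hotspot layer.

Every run emits a manifest whose species accounting must reconcile exactly:
input = analyzed + minimal-area + degenerate-hull + outlier-removed.

## The synthetic-data generator

No global occurrence corpus or remote-sensing stack ships with the package;
instead `gen_world()` builds worlds with planted, recorded ground truth:

- clustered occurrences (one or two isotropic Gaussian clusters per
  species, sd 0.3°) with quality labels drawn from configurable
  probabilities weighted toward reliable labels, and a configurable number
  of species forced below five records;
- a contiguous zone mosaic (Voronoi of random centres) standing in for a
  climate classification, and rectangular "lakes" as a water mask;
- binary change layers realising each species' planted changed fraction to
  within one cell inside its core region;
- annual stacks that are exactly linear per cell at the planted slope plus
  iid Gaussian noise (a heavy-tailed t₃ option exercises robustness), and
  a status table sampled from configurable category probabilities.

One master seed expands into fixed per-component substreams, so identical
configurations give bit-identical worlds while components can be
regenerated independently. Defaults — 50 species, 5–120 records per
species, six zones, years 2001–2020, a 10° × 8° tropical-belt bounding box
at 0.05° resolution — keep a full end-to-end run around ten seconds while
leaving extents of hundreds to thousands of cells; tests mostly use
10-species worlds at the same resolution.

What the generator does *not* emulate: the real layers' native resolutions
(30 m–4.6 km) and their resampling chain, spatial autocorrelation in
climate noise, label-quality structure correlated with location, and
taxonomic name issues. Passing tests therefore demonstrate the pipeline's
arithmetic, invariances and statistical calibration — not robustness to the
messiness of real aggregator data.

## Numerical choices and degenerate inputs

- Duplicate coordinates are collapsed per species after rounding to six
  decimals (~0.1 m); duplicates count once toward AOO but all records count
  toward the five-record hull requirement.
- Coverage weights below 10⁻¹² are dropped; weights are clamped to (0, 1].
- Cells are half-open `[west, east) × [south, north)`, so a point on a
  shared edge belongs to exactly one cell.
- Polygons crossing the antimeridian are rejected with an explicit error —
  synthetic worlds never produce them and correct handling would complicate
  every geometric routine for no tested benefit (documented limitation).
- A degenerate hull (all kept records collinear) is flagged, not an error:
  the species is routed to the minimal-area path exactly like a
  zero-surviving-cell extent after masking.
- Constant series get slope 0 and p = 1 (never "significant"); series with
  duplicated years are rejected.
- Whether burned-area trends use the same α as climate is left as a single
  global α (default 0.05), configurable per run.

## Limitations

Exposure is not impact: a high rate flags a species for expert attention,
nothing more. Threat layers overlap (deforestation followed by cropland
counts twice across columns) and attribution is out of scope, as are
cross-threat correlations. The percentile thresholds are relative to the
assemblage analysed, so absolute comparability across runs requires a fixed
species pool.
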