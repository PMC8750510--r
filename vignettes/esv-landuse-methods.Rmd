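---
title: "Methods: land-use change, ecosystem-services valuation and spatial response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: land-use change, ecosystem-services valuation and spatial response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esvland)
```

## The problem

Rapid urbanization converts cropland, forest and wetland into built-up
land, and with each hectare converted the flow of ecosystem services —
food, raw materials, climate and hydrological regulation, soil
retention, biodiversity habitat, landscape amenity — changes. `esvland`
chains the standard quantitative treatment of that process: account for
the land-use change itself, price it with the equivalent-factor method,
and then ask *where* the resulting value surface clusters, heats, cools
and drifts.

The package works on categorical rasters reclassified to a fixed
seven-class scheme (`lu_classes()`: cropland, forest, grassland, water,
wetland, bare, built-up), a zone partition standing in for
administrative units, and a per-class × per-function value coefficient
table.

## Change accounting

`class_areas()` converts cell counts to areas (`area = cells ×
cell_area`; both km² and hm² are carried, since coefficients are per
hectare while areas are conventionally reported per km²).
`area_change_table()` derives, at full precision, area ratios,
variations (`later − earlier`, an exact identity) and rates of change
(`variation / earlier × 100`); a rate whose baseline is zero is
undefined and flagged `NA` rather than reported as infinite. Rounding
to the conventional two decimals happens only in the print/report
layer. Published change tables assembled from unrounded GIS areas can
disagree with their own printed per-date areas by a km² or two; this
package always keeps the identity exact, so such discrepancies surface
as data inconsistencies instead of being reproduced.

`transfer_matrix()` cross-tabulates two dates into a from × to area
matrix. Cells that are nodata at *either* date are excluded from both
marginals, which buys an exact conservation law: row sums equal date-t
areas and column sums equal date-t+1 areas on the common mask, and
`areas(t) %*% P` reproduces `areas(t+1)` exactly. Rows with no area at
the first date get an all-zero probability row and are flagged, not
normalised.

## Equivalent-factor valuation

The standard equivalent value is defined as one-seventh of the annual
economic value of the average grain yield of one hectare of cropland.
As a formula over a crop table (yield per hectare `q`, sown area `m`,
price `p`):

$$E_n = \frac{1}{7}\,\frac{\sum_i p_i q_i m_i}{\sum_i m_i}.$$

The sown-area-weighted form is the only dimensionally consistent
reading (a naive `Σ q_i p_i / M` would divide a per-hectare quantity by
an area); it yields currency·hm⁻² as required, and
`standard_equivalent_value()` implements exactly this.
`scale_coefficients()` multiplies a dimensionless equivalent-factor
table by `En`; the packaged `esv_coefficients()` table is already
scaled (USD·hm⁻²·a⁻¹) and treated as authoritative. Built-up land is
carried as an explicit zero row — it has no coefficients in the source
framework, and an explicit row keeps every matrix aligned with the
seven-class transfer matrices. Negative coefficients are legitimate
(cropland's water-supply coefficient is −31.60: paddy agriculture
consumes more water than it supplies) and are never clamped. Per-class
totals `VC_i` are derived by summing the eleven function coefficients;
where a published table's printed total row disagrees with its own
columns by a cent or two, the sum wins.

Valuation is then linear algebra: `ESV_i = A_i VC_i`,
`ESV_f = Σ_i A_i VC_if`, with additivity (class totals = function
totals = grand total) and linearity in areas holding to floating-point
tolerance by construction, and asserted as properties in the tests.
`zonal_esv()` distributes the same computation over a zone partition;
zone values sum to the global total exactly, and cells outside every
zone accumulate into a flagged `unassigned` attribute.

Currency is an opaque metadata label; no exchange-rate conversion is
performed anywhere.

## Spatial weights

Zone contiguity is computed from the zone-id matrix: rook neighbours
share a cell edge, queen neighbours an edge or corner. The default for
the package's analyses is queen contiguity — the default of the desktop
GIS tools this workflow usually runs in — row-standardised for Moran's
I (`style = "W"`), binary with a unit self-weight for Gi\*
(`include_self = TRUE`, since the focal zone belongs to its own
neighbourhood). Moran weights must have `w_ii = 0`; the two statistics
therefore take differently-built weight objects, and each validates the
form it requires. Zones with no neighbours are flagged islands,
excluded from statistics rather than imputed.

## Global Moran's I

$$I = \frac{\sum_i \sum_j W_{ij}(x_i-\bar x)(x_j-\bar x)}{S^2 \sum_i \sum_j W_{ij}},
\qquad S^2 = \tfrac{1}{n}\sum_i (x_i-\bar x)^2.$$

With the population variance in the denominator this is the classic
form: −1 on a perfectly dispersed rook checkerboard, null expectation
`E[I] = −1/(n−1)`, bounded by [−1, 1] under row-standardised weights
(binary weights can exceed the bounds slightly, which is documented
rather than clipped). Inference is by random relabelling permutations
(default 999) under a caller-supplied seed, with the analytic
expectation reported alongside; the default alternative is `greater`
(clustering). The Moran scatter (standardised values vs. their spatial
lag) is returned as data, not a plot, so it can be written to CSV.

Constant fields are an error — the statistic is undefined at zero
variance — not an `NA`.

## Getis–Ord Gi\*

$$G_i^* = \frac{\sum_j \omega_{ij} x_j - \bar x \sum_j \omega_{ij}}
{S\sqrt{\dfrac{n\sum_j \omega_{ij}^2 - (\sum_j \omega_{ij})^2}{n-1}}},
\qquad S = \sqrt{\tfrac{1}{n}\sum_j x_j^2 - \bar x^2}.$$

`S` uses the population (divide-by-n) form, which makes the z-score
exactly invariant under adding a constant and under positive scaling of
the values — an invariance the tests assert numerically; the `n−1`
stays under the root of the weight-variance term. When a zone's
neighbourhood spans essentially all zones the root collapses to zero
and the score is undefined; such zones are flagged, not scored. A zone
layout as small as 3×3 already triggers this for its center zone under
queen contiguity, which is worth knowing before interpreting tiny maps.

`classify_hotspots()` bins z at |z| = 1.65 / 1.96 / 2.58 into the
seven-way cold99…hot99 scale; a score exactly on a boundary goes to the
*stronger* class (so z = 1.96 is hot95). Whether published confidence
maps derive from z thresholds or permutation p-values is rarely stated;
z thresholds are the implemented reading.

## Gravity model

The ESV-weighted centroid per date is
`x̄ = Σ m_i x_i / Σ m_i` (and likewise ȳ); with nonnegative masses it
stays inside the convex hull of zone coordinates. Negative zonal ESV is
rejected as a mass rather than reinterpreted. The inter-date shift is
summarised by the Euclidean distance and by a direction computed with
the two-argument arctangent, which absorbs the quadrant-adjustment
coefficient of the piecewise single-argument formula. Because the
angular reference convention is often left unstated in applied work,
both are reported: counterclockwise-from-east in [0°, 360°), and the
compass bearing (clockwise from north). An interval whose direction
differs from its predecessor's by more than 90° is flagged a
*reversal* — the signature of a drift regime change such as urban
expansion overturning a greening trend. Zero-length intervals have
undefined angles and never flag reversals.

All geometry is planar (km); no geodesy. At provincial extents on an
equal-area projection the error of that choice is far below the
kilometre scale of reported shifts.

## The synthetic generator

`simulate_landscape()` draws date 1 i.i.d. from the initial class
proportions (optionally clumped by a modal filter of configurable
radius — ties broken deterministically toward the lower class index)
and advances each cell independently through the user's row-stochastic
transition matrix. Independence per cell is a deliberate design choice:
it makes the empirical transfer matrix a table of binomial proportions,
so parameter recovery is analytically checkable (each `P̂_ij` within 3
binomial standard errors of `P_ij`), and class proportions converge to
the eigen-computed stationary distribution. What the generator does
*not* emulate: spatial contagion of change (real urban growth is
clustered at the urban fringe), anisotropy, road/river morphology, or
classification error. Passing tests therefore validate the accounting,
valuation and statistics machinery — not any claim about realistic
landscape pattern.

Defaults mirror the data regime the pipeline targets: 1 cell = 1 km² =
100 hm², a seven-class legend, and a default transition matrix in which
cropland and forest leak a few percent per step into near-absorbing
built-up land. A single integer seed governs every draw and is recorded
in the simulation spec and run manifest.

`generate_zones()` tiles the grid into near-equal rectangles (an even
split with remainders spread over leading bands) — contiguous,
non-overlapping, exhaustively covering, with known centroids in planar
km. `simulate_crop_table()` draws log-uniform yields (3–9 t/hm²), sown
areas (1e5–1e6 hm²) and prices (2000–3000 currency/t), bracketing
provincial grain statistics so that simulated `En` lands near published
equivalent values (≈ 2000–2500 currency/hm²).

## Pipeline and problem sizes

`run_pipeline()` has three entry modes. *Table mode* runs only the
accounting + valuation stages from per-date class areas (the packaged
five-date provincial table by default) — it touches no raster code and
completes in well under a second; it exists because the original 1-km
provincial rasters are not redistributable, while their published
summary tables are. *Synthetic mode* runs everything from a
`landscape_spec`; *raster mode* ingests ASCII grids plus a
reclassification scheme CSV. Each stage aborts with an error naming the
stage; a JSON manifest records seed, versions and shapes.

The test suite exercises grids up to 100×100 cells with 25–100 zones
and 999 permutations — sizes chosen so the full property suite runs in
a few seconds while keeping binomial standard errors small enough for
3σ parameter-recovery bounds to be informative.

## Known limitations

- Raster I/O is plain ASCII grid; GeoTIFF and vector GIS formats are
  out of scope, as is any reprojection or grid alignment — inputs must
  share one grid.
- Zone partitions are rectangle tilings; arbitrary polygon zones can be
  supplied only as a pre-rasterised zone-id matrix.
- Local Moran (LISA) typologies and multiple-testing correction of
  local statistics are not implemented (the workflow this package
  codifies applies none).
- Sub-pixel class fractions are not modelled; a cell is wholly one
  class.
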