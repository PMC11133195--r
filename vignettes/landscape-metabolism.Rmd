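---
title: "Landscape-metabolism metrics: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landscape-metabolism metrics: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landmetab)
```

`landmetab` computes, for every equal-area hexagon of a categorical
land-cover map, a chain of indicators that together describe how a
metropolitan landscape is configured (pattern and connectivity), how heavily
society draws on its primary production, and what that implies for its
capacity to host biodiversity and supply ecosystem services. This vignette is
the package's own account of that model: what each stage assumes, which
parameters matter and why they default to what they do, and where we had to
make choices the method's verbal description leaves open.

## Spatial frame

All inputs are assumed to share one planar, equal-area coordinate system; the
package performs no reprojection. The raster is row-major with the origin at
the top-left corner, and areas are `cell count × cell size²` with no
spherical correction — appropriate at the 1:100,000, regional scale the
method targets.

Analysis units are flat-top hexagons of `cell_area` (default 2,000 ha),
generated row-wise from the top-left of the extent and clipped to it. A
raster cell belongs to the hexagon containing its centre; for a regular
hexagonal tiling that is exactly the nearest-centre rule (the tiling is the
Voronoi diagram of its centres), with boundary ties going to the lower
`hex_id`. Boundary hexagons whose valid (non-nodata, in-extent) coverage
falls below `min_valid_fraction` (default 0.5) are excluded from every
downstream statistic, and cover proportions in retained hexagons are
renormalised over valid cells, so each retained row of the composition
matrix sums to one. Both the retention threshold and the count of exclusions
are reported rather than silently applied, since the original hexagon design
does not say how edge units were treated.

## Heterogeneity (H′)

Pattern is measured as Shannon entropy over *habitat categories*, not raw
legend classes: the legend groups covers into eight habitats (forest,
shrubland, grassland, heterogeneous crops, sugarcane, pastures, water,
rocky/sandy) plus a single "no habitat" category pooling urban, industrial
and degraded covers. Because the index is asserted to live on [0, 1], we use
normalised entropy, `H' = -Σ p log p / log J`, with `J` the configured
number of categories (default: all categories present in the legend, nine
here). The printed form of the index omits the minus sign and the
normaliser; normalisation also makes the log base irrelevant. `J` is
configurable because the verbal definition counts "eight land covers" while
listing nine tokens; the choice is echoed in the output metadata.

## Connectivity (ECI)

For each functional ecological area *b* the landscape is converted into a
friction surface: `friction = base_cost / affinity(area(cell), b)` plus the
additive impact of every anthropogenic-barrier halo covering the cell;
impermeable barrier cells are removed from the traversal graph, and barrier
classes with no functional area of their own travel at the worst affinity in
the matrix. `base_cost` is 1 per cell length. Least accumulated costs
`X_i` from the source patches of area *b* (all its cells by default;
`min_patch` can require a minimum patch size) are exact Dijkstra distances
on the 8-connected cell graph with edge weight = mean of the two endpoint
frictions × step length (1, or √2 diagonally). The per-area index is

`ECI_b = 10 - 9 [ln(1 + X_i) / ln(1 + X_t)]^3`

and the total ECI is the plain mean over the *m* areas considered. Choices
worth flagging:

- **Exponent placement.** The published typography of the transform is
  ambiguous. We cube the log ratio, which preserves the index family's
  sigmoidal shape and pins `ECI_b` to [1, 10] on `X_i ∈ [0, X_t]`; the
  literal cube-the-denominator reading is available as
  `exponent = "denominator"` for sensitivity checks. Note the transform
  reaches 1, not 0, at `X_i = X_t`; a min–max rescaling of the hexagon means
  to [0, 10] is emitted alongside the raw index (`eci_rescaled`) since it is
  unstated whether the nominal 0–10 range involved such a rescaling.
- **Theoretical maximum.** `X_t` defaults to the grid diagonal (in steps) ×
  the maximum unmasked friction — the worst-case straight traverse — and is
  overridable by a constant. Accumulated costs above `X_t` (possible when
  barriers force detours) are clamped to it by default; a strict mode errors
  instead. Unreachable and masked cells carry `X_t`, i.e. minimal
  connectivity rather than missingness.
- **Functional areas.** Seven canonical areas (forest, shrubland,
  grassland/paramo, agroforestry mosaic, crops, pastures, sugarcane) act as
  connectivity *targets*, so `m = 7` on a full landscape. The hydrological
  network is carried as an eighth, traversable area with high affinity (0.8)
  to forest, reflecting its corridor role, without inflating `m`. The
  affinity and impact coefficients of the original application were
  expert-derived and never tabulated; the defaults shipped in
  `default_affinity()` encode only the expected ordering (structurally
  similar habitats high, intensive covers low) and are explicitly
  placeholders for user-supplied values.

## Metabolism (HANPP)

Per class, `ΔNPP_Lu = NPP_0 - NPP_act` and `HANPP = ΔNPP_Lu + NPP_h`, kept
both in t C/ha/yr and as a percent of `NPP_0`. The percent may legitimately
be negative (irrigated cropland out-producing the potential vegetation); the
raw value is preserved in all tabular output and clamped to [0, 100] only at
the IDC boundary, where `1 - HANPP/100` requires it. Harvest exceeding
actual production is rejected at load. NPP is supplied per class as a table
— the original mix of a global potential-NPP grid and census-derived actuals
is emulated by the table route. Hexagon values are composition-weighted
class values and therefore convex combinations of them.

## The IDC composite

`Le = (a H' + b ECI/10) / (a + b)` blends pattern and process; `IDC =
Le (1 - HANPP/100)`. The pattern term of the blend is identified with the
Shannon H′ above — the only pattern metric the method computes — and the
canonical weights default to `a = b = 1` since the original calibration is
not published. IDC is monotone: non-increasing in HANPP at fixed Le,
non-decreasing in H′ and ECI at fixed HANPP.

Hexagons are labelled by IDC bands: *anthropic* inside the published
0.05–0.3 bracket, *natural* in 0.3–0.5 when natural covers (forest,
seminatural and water typologies) exceed half the hexagon, *mosaic* at or
above 0.5, else unclassified. Only the anthropic bracket is published; the
other two thresholds are package choices, configurable and clearly labelled
as such. On the synthetic fixture, forested highland hexagons — nearly
undisturbed and well connected — often exceed 0.5 and are labelled mosaic;
this is the known behaviour that the composite loses discriminatory power as
non-anthropogenic covers dominate, not a classification bug.

## Ecosystem services

A panel of experts scores supply and demand of 21 CICES-derived services per
cover on the 0–5 Likert scale. Scores are averaged with equal weights and no
trimming. Capacity per (service, cover) is `S - D`; per cover, `ESC_i` is
the *mean* over services, which preserves the printed [−5, 5] range (a sum
variant exists behind a config switch). Multifunctionality counts breadth:
per section (provisioning, regulation/support, cultural), the fraction of
services whose mean supply reaches the threshold (default 3, "medium"),
averaged over the three sections and scaled by 5. Both the threshold and the
counting rule are reconstructions of the verbal definition — the original
per-cover tables exist only as images — and are configurable. The
multifunctionality analogue of the hexagon formula repeats the capacity
symbol in its source; it is implemented as `MF_j = Σ MF_i P_ij`, the evident
intent. Hexagon scores are convex combinations of cover scores.

## Statistical analyses

The stepwise multiple regression of IDC on cover proportions uses
bidirectional selection by AIC, scanning candidates in fixed column order
with no randomness, so selection is fully deterministic; a
p-threshold variant (enter 0.05 / remove 0.10) is available. Compositional
collinearity (proportions summing to one) is handled by fitting with an
intercept and letting selection drop redundant terms, mirroring the original
analysis, which applied no transformation. A numerically perfect fit stops
selection immediately — the Gaussian AIC is degenerate at zero residual
variance. p values are two-sided t tests with the `* < 0.050` flag and no
multiple-testing correction (none was applied originally; the report says
so). Constant predictors are dropped and listed; rank-deficient terms are
reported, never silently discarded. The IDC–ESC relationship is ordinary
least squares with R² the squared correlation.

## The synthetic landscape generator

Because the study's geodata are not deposited, every pipeline stage is
exercised on synthetic inputs whose structure mirrors the study region:

- **Zonation.** Three bands along one axis stand in for the elevation
  gradient — a monoculture valley (sugarcane ~78%, urban fabric, pastures),
  a mosaic mid-slope (five mosaic classes plus forest, shrub and pasture
  covers), and a natural highland (dense forest ~55%, paramo, shrubland).
  No DEM is modelled; the band index is the only "elevation".
- **Allocation.** Within each band, class targets are apportioned by
  largest remainder, patch nuclei are seeded and grown cell-by-cell in class
  round-robin over seeded frontiers until the targets are met exactly
  (clustering parameter 0.55, mean patch ≈ 12 cells; at clustering 0 the
  band is a random permutation of the exact target counts). A river and a
  valley road are rasterised last as linear features. Everything is a pure
  function of scenario + seed.
- **NPP and panel.** Typology-driven NPP draws place built covers near
  100% appropriation, sugarcane above the 61% intensive-use break (with
  negative land-use change from irrigation), mosaics intermediate and
  natural covers near zero. The 27-expert panel perturbs rounded latent
  supply/demand archetypes by ±1 with probability 0.2, clipped to 0–5.

The default grid is 60 × 100 cells at 500 m (150,000 ha, 75 retained
2,000 ha hexagons) — large enough for the gradient to express, small enough
that the full pipeline runs in under a second. What passing tests on this
fixture show is that the *machinery* reproduces the expected directional
structure (valley: higher HANPP, lower H′, ECI, IDC and ESC than the
slopes); they cannot validate the original coefficient values, maps or the
published regression table, all of which depend on the undeposited geodata.
The published area table, however, is reproduced exactly from its printed
class areas, including group roll-ups and percents on the printed
1,004,000 ha base (the printed class areas themselves sum to ~998,342 ha —
an internal inconsistency of the source table that the package reports
rather than reconciles; similarly, percents are computed against the
printed study-area total, and the printed prose totals for some groups
disagree with the table and are ignored in favour of the table).

## Numerical choices and degenerate inputs

- Report percents round half-up to one decimal, matching the published
  table's formatting; raw values are never rounded internally.
- Composition rows are renormalised over valid cells and checked to sum to
  1 within 1e−9.
- `eci_b` clamps `X_i > X_t` with a warning (strict mode raises); `X_i = 0`
  gives exactly 10 and, under the default exponent, `X_i = X_t` gives
  exactly 1.
- Empty functional areas (no source cells on the raster) are skipped with a
  warning and `m` shrinks accordingly.
- Degenerate regressions (zero-variance predictor, fewer than three finite
  pairs) raise typed errors rather than returning NaN.

## Known limitations

- No spatial autocorrelation correction in the regressions (absent from the
  original analysis as well); with 76–502 contiguous hexagons, standard
  errors are optimistic.
- Affinity/barrier coefficients are placeholders; results on real data will
  hinge on expert-supplied values.
- The generator's bands are one-dimensional and its panel archetypes are
  coarse; neither attempts to match the real region's geography or the real
  expert matrices.
- GeoTIFF input is not supported; rasters are exchanged as ESRI ASCII
  grids (any GIS can convert losslessly).
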