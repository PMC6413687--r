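---
title: "Methods: raster-based land use regression mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: raster-based land use regression mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lurmap)
```

# The model

A land use regression (LUR) model predicts a pollutant concentration at a
location as a linear combination of geographic predictors:

$$ C(s) \;=\; \beta_0 \;+\; \sum_j \beta_j \, X_j(s) $$

where each predictor $X_j$ is either

* a quantity summed over a **circular buffer** around $s$ (road length,
  traffic load, land-use area, population),
* a quantity summed over an **annulus** (ring) between two radii,
* the **inverse distance** to the nearest (major) road, or
* a **regional background estimate** interpolated from rural monitoring
  stations.

`lurmap` evaluates such models on a regular metric raster grid: every
predictor becomes a raster, buffer sums become focal operations, and the
model itself is per-cell map algebra. Six built-in models for the
Netherlands (annual averages: NO~2~, NO~2~ background, NO~x~, PM~2.5~,
PM~2.5~ absorbance, PM~10~) are shipped as data via `builtin_models()`;
user models use the same term vocabulary through `lur_model()` /
`read_model()`.

## Predictor vocabulary

| Id  | Meaning | Unit |
|-----|---------|------|
| RL / MRL | all-road / major-road length per cell | m |
| TL / TML / HTL | traffic load: intensity × length (TML restricted to major roads, HTL to heavy-duty traffic) | vehicles·day^-1^·m |
| IND / HAR / RES | industrial / harbour / residential area per cell | m^2^ |
| POP | inhabitants per cell | count |
| IDC / IDM | inverse distance to nearest (any / major) road | m^-1^ |
| BEO / BEX / BEP / BEA | regional background for NO~2~ / NO~x~ / PM~2.5~ / PM~2.5~ absorbance | µg·m^-3^ (BEA: 10^-5^ m^-1^) |

A buffered term is keyed `"<id>_<radius>"` (e.g. `POP_5000`), an annulus
`"<id>_<r_in>-<r_out>"` (e.g. `HTL_25-500`). The six built-in models
together need 16 distinct buffered predictors; `compute_predictor_stack()`
computes each exactly once.

# Grid and file conventions

* `grid_spec(x_min, y_max, cell_size, n_rows, n_cols)` describes a
  north-up grid in a projected metric CRS (geographic CRSs are rejected;
  all radii and distances are metres). Rows count from the north edge,
  columns from the west edge, 1-based; cells are half-open: a point on the
  west/north edge of a cell belongs to it, on the east/south edge to the
  neighbour.
* Rasters are read and written as **ESRI ASCII grids** (`.asc`) with a
  plain-text CRS sidecar. Values are printed with `%.17g`, which
  round-trips IEEE doubles exactly, so write → read is bit-identical and
  re-runs of the pipeline produce byte-identical files. The format was
  chosen because it is text (diffable, fixture-friendly) and universally
  readable by GIS software.
* Vector inputs are GeoJSON (roads as `LineString`s with `road_class`,
  `traffic_intensity`, `heavy_traffic_intensity`; land use and population
  zones as `Polygon`s) and CSV (stations, reclassification table).

# Numerical choices

**Rasterization.** Each road segment is clipped to the grid extent
(Liang–Barsky), cut at every grid-line crossing, and each piece is
assigned to the cell containing its midpoint. Per-cell lengths therefore
sum *exactly* to the clipped network length. Traffic load multiplies each
piece by the segment's daily intensity. Polygon class area is
all-or-nothing by cell centre (a cell holds `cell_size`² if its centre is
inside, else 0), and population is spread uniformly over each zone's
covered cells so that the total is conserved.

**Focal buffers.** A buffer kernel contains the integer offsets
$(d_c, d_r)$ with $(d_c^2 + d_r^2)\,\mathrm{cs}^2 \le r^2$ — membership by
cell-centre distance, ties at exactly the radius *included*. At 5 m cells
the 25 m kernel is the classic 81-cell discrete disk. Membership is
decided in exact integer arithmetic (no floating `sqrt` threshold), and an
annulus is summed directly over its ring offsets rather than by
subtracting two disks, so both equal a brute-force per-cell loop exactly.
Cells outside the grid contribute 0 (zero padding): border sums
underestimate what a larger domain would give, and a kernel lying entirely
off-grid sums to 0. `NA` cells contribute nothing, but a neighbourhood
whose in-grid cells are all `NA` stays `NA`.

Large grids can be processed in tiles (`tile_size`): tiles overlap by the
kernel half-width and every output cell accumulates its kernel in the same
order as the untiled run, so tiled output is **bit-identical** — `tile_size`
trades memory, never values. As a shortcut, a disk radius at least the
grid's cell-centre diameter yields the grand total in every cell.

**Distances.** `distance_to_network()` measures the exact Euclidean
point-to-polyline distance from each cell centre to the *vector* geometry
(brute force over segments — exactness over speed at the problem sizes the
package targets). The inverse-distance predictor is
$1/\max(d, d_{\min})$ with $d_{\min}$ defaulting to half a cell (2.5 m at
5 m cells), bounding the predictor on-road where $1/d$ would diverge.

**Backgrounds.** `idw_interpolate()` uses inverse-distance weights
$d^{-2}$ over stations within a 100 km search radius — exponent 2 is the
standard IDW choice and the radius spans any national-scale domain. A cell
whose centre falls within `cell_size / 100` of a station takes that
station's value exactly; cells with no station in range are `NA`. The
result is convex (bounded by the station value range). The PM~10~ model
has no background term.

**Evaluation.** `evaluate_model()` adds `intercept + Σ coef × raster` per
cell, checks term units and grid identity, and propagates `NA`. Negative
predictions are *not* clipped by default — they are counted by
`summary()` and can be truncated with `clip_zero = TRUE`. PM~coarse~ is
derived as PM~10~ − PM~2.5~.

# Validation

`validation_report()` compares observed and modelled values at paired
sites: $r^2$ is the squared Pearson correlation (the usual LUR
convention), $\mathrm{RMSE} = \sqrt{\overline{(o-m)^2}}$, bias is
$\overline{o-m}$ (positive = model underpredicts), plus a two-sided
one-sample t-test of the differences against zero (identically zero
differences report $t=0, p=1$). `screen_stations()` applies the routine
completeness rule: stations with strictly more than 20 % missing records
are excluded, survivors averaged over non-missing records.

# The synthetic scene

Real national input data are proprietary; `generate_scene()` builds a
fully seeded synthetic study area instead — by default 2 km × 2 km at 5 m
cells with a major ring road and crossing arterials, a minor street grid,
axis-aligned industrial/harbour/residential blocks, population spread over
the residential blocks, regional background stations on a jittered lattice
with a smooth large-scale gradient, and random validation sites.
Axis-aligned geometry keeps analytic lengths and areas available as test
oracles, and `forward_observations()` samples a model's own surface (plus
optional seeded noise) so the pipeline can be validated parameter-free:
with zero noise, $r^2 = 1$, RMSE = 0, bias = 0 must hold to floating
precision. The scene is a *test instrument*, not a realistic city — land
use blocks may overlap, roads are straight, and background gradients are
linear by construction.

# Pipeline

```{r, eval = FALSE}
scene <- generate_scene(scene_config(seed = 1))
cfg <- pipeline_config(grid = scene$spec, models = c("NO2", "PM10"),
                       out_dir = "out")
res <- run_pipeline(cfg, scene = scene)
```

`run_pipeline()` stages rasterize → distances → backgrounds → buffers →
maps, computes only what the requested models need, writes every raster
plus a `manifest.csv` (paths relative to `out_dir`, so identical runs are
byte-identical anywhere), and returns the stack and concentration rasters.
File-based runs read the GeoJSON/CSV inputs named in the config (or a YAML
file via `read_pipeline_config()`). `extract_points()` and
`validate_against_stations()` close the loop for exposure assessment and
validation; `inst/cli/lurmap.R` wraps the same calls for the shell.
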