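---
title: "Random-forest dasymetric population mapping: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-forest dasymetric population mapping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of what it computes and why:
the model, its assumptions, the parameters that matter, the synthetic world
that the tests run on, and the numerical decisions taken where the method
leaves room.

## 1. The estimation problem

Administrative census data give one number per polygon. A gridded population
product redistributes those numbers to ~100 m pixels using ancillary rasters,
under one hard constraint: **the pixel sum over every census unit must equal
the unit's count**. Everything else — which pixels within a unit receive more
people — is a modelling choice. `dasypop` makes that choice with a Random
Forest density model, in two steps.

### Step 1 — unit-level density model

Counts from each census year are first harmonized onto one fixed target zone
set (`reallocate_counts()`), because comparable multi-year surfaces require
identical estimation units: a source unit whose area falls (within a 0.1%
sliver tolerance) inside a single target is assigned completely to that
target; a straddling source contributes `count × intersection area / source
area` to each target it touches. Harmonized counts are kept real-valued —
conservation takes priority over integrality — and any count mass that
intersects no target is tracked explicitly as *unallocated*, never silently
dropped.

The response is the natural-log population density of each target zone,

$$y_z = \ln(\text{count}_z / \text{pixels}_z),$$

with people-per-pixel as the density unit (any fixed alternative — per km²,
per hectare — only shifts the response by a constant and leaves the final
product unchanged, because the predicted surface is used purely as relative
weights). Zones with zero counts are excluded from fitting (the log is
undefined; a +1 offset was rejected to keep the response interpretable);
they still receive predictions. Predictors are zonal **means** of the
covariate stack over each zone's usable pixels; richer zonal summaries
(quantiles, SDs) are deliberately out of scope.

The regression is a bootstrap ensemble of unpruned trees
(`fit_forest()`, backed by the classic `randomForest` implementation):

* `n_trees = 500`,
* terminal nodes grown to a **single observation** (`min_node_size = 1`),
* **all covariates candidate at every split** (`mtry = p`),
* per-observation out-of-bag (OOB) predictions retained.

These are the standard settings of this mapping framework; all three are
named, overridable configuration keys so a deviation is always explicit.
OOB error is reported as the mean squared OOB residual of log density
(`mse_log`) and as variance explained,
`1 − mse_log / popvar(y)` (`oob_error()`).

**One model per year.** The relationship between density and
distance-to-built-edge drifts where urban expansion outpaces population
growth (core densities fall while fringe densities rise). A model
parameterised on one year is then structurally wrong for another, so each
year is fitted independently, and `temporal_fit_comparison()` quantifies the
cost of ignoring this: on a generated world whose distance-decay rate varies
by year, it fits per-year models and one pooled model (over the covariates
common to all years) and compares pixel-level correlation of the final
surfaces with the ground truth. In the package's time-varying test regime
the per-year models win consistently; in the static regime the two are
close, which is exactly the diagnostic logic the per-year design rests on.

### Step 2 — dasymetric redistribution

`predict_density_surface()` applies the year's forest to every usable pixel
and back-transforms with `exp`, giving a strictly positive weighting layer
where defined. No smearing/bias correction is applied to the
back-transform: the surface enters only as relative weights within zones, so
any multiplicative bias cancels. `redistribute()` then computes

$$\mathrm{ppp}(p) = \text{count}_z \cdot \frac{w(p)}{\sum_{q \in z} w(q)},$$

which conserves each zone's total by construction (the tests require every
zone's relative residual below 1e−6; in practice it is ~1e−15). Policy
choices, all logged:

* zones whose usable weights sum to zero fall back to **uniform**
  allocation — census mass is never lost;
* in-zone pixels with missing covariates receive 0 when the zone has usable
  weight elsewhere (no covariate values are fabricated);
* pixels outside every zone, and zones without census records, are nodata
  and reported, not guessed.

`ppp_to_pph()` converts to people per hectare (`ppp / pixel area in ha`; on
the default 100 m grid the two coincide). The working-projection grid is the
mass-true reference product; the optional WGS84 export is a nearest-neighbour
convenience copy whose total may drift slightly — both totals are recorded in
the export report, and the geographic pixel size is chosen so ground area per
output pixel matches the source pixel area at the tangent latitude, keeping
the drift within ~1%.

## 2. The covariates

Built per year by `build_stack()`, on one aligned grid:

| layer | construction | units |
|---|---|---|
| `lights` | cellwise mean of the year's satellite rasters (`composite_lights()`); a cell is nodata iff nodata in any input | DN |
| `elevation` | as supplied | m |
| `slope` | Horn 3×3 finite differences, edge replication | degrees |
| `dist_water` | Euclidean distance to nearest rasterized water cell | m |
| `built_dist_<year>` | signed Euclidean distance to the built edge, one layer for the current year **and every preceding year** | m |

The signed distance *d* (`signed_distance_to_edge()`) is negative inside
built land and positive outside. The metric is centre-to-centre Euclidean
distance on the projected grid, computed with an exact separable
lower-envelope distance transform: a built cell's magnitude is its distance
to the nearest non-built cell centre, so |d| ≥ pixel size and 0 never occurs
— the sign partitions exactly along the mask, which the tests assert against
an all-pairs brute-force search. The preceding-years rule means year index
*t* carries *t* + 1 built-distance layers (5 total layers at the first year,
7 at the third): the ensemble can express density differences between old
cores and new fringe even when their current-year distances agree.

The earliest year's lights may be proxied by a different nominal acquisition
year — the year→raster mapping is configuration, not hard-coded.

## 3. The synthetic world

`generate_world()` supplies every input the pipeline needs, with known
ground truth. Construction, deterministic given one seed:

* **terrain**: smoothed Gaussian random field, rescaled to 0–500 m;
  **rivers**: monotone random-walk polylines, rasterized;
* **built extents**: seed blobs dilated per year (cellwise non-decreasing by
  construction; radii shrink automatically if the blobs would flood the
  grid);
* **lights**: a gain on the local built fraction plus per-satellite noise,
  clamped to the 0–63 digital-number range; the middle year carries two
  satellite rasters so the compositing path is exercised;
* **tessellations**: coarse zones are the Voronoi diagram of k-means centres
  on the pixel lattice (irregular, roughly even, administrative-looking);
  fine zones are Voronoi cells nested *exactly* inside each coarse cell, so
  validation counts aggregate exactly;
* **population**: per-pixel intensity

  $$\log \lambda(p) = \alpha - \beta_t \, d(p)/1000 + \gamma \, L(p)/L_{\max}
    + \zeta_{z(p)} + \varepsilon(p),$$

  with `d` the current year's signed built distance (m), `L` the noise-free
  expected lights, `ε ~ N(0, σ)` i.i.d. per pixel and year, and
  `ζ ~ N(0, σ_zone)` a per-coarse-zone random effect redrawn each year. The
  surface is rescaled so every coarse-zone total is an integer; census
  tables are exact zonal sums.

Defaults (chosen once, as the package's study conditions): 200×200 pixels at
100 m, 3 years, 100 coarse / 400 fine zones, α = 2 (≈ 7 people/pixel at the
built edge before lights), β = 1 per km (static regime) or (0.4, 1.0, 2.2)
per year (time-varying regime), γ = 1 on lights scaled to [0, ~1], σ = 0.2,
σ_zone = 0.55. The zone effect is the deliberate realism ingredient: it is
unit-level density variation that **no covariate carries** (local economy,
housing stock), so it bounds the achievable OOB variance explained — under
these defaults per-year fits land at roughly 0.86–0.95 variance explained
and 0.30–0.49 OOB log-density MSE — and, because census counts carry it, it
is exactly the component that redistribution recovers at the pixel level.
Without it, the world would be unrealistically easy (variance explained
0.99) and passing tests would say little.

What the generator does **not** emulate: real classification error in built
extents, sensor saturation and intercalibration in lights, coastlines and
nodata frontiers, non-nesting validation units, or any actual geography.
Passing tests therefore demonstrate that the machinery is correct and the
statistical logic sound under the model's own assumptions — not that any
particular accuracy will be achieved on real data.

## 4. Validation metrics

`validate_population()` aggregates the product to the finer tessellation and
computes, on both counts and densities:

* `rmse`, `mae`, and `mad` — with MAD defined as the **median absolute
  error** `median|pred − obs|` (an error summary robust to the few huge
  errors typical of skewed population data), not the median-centred
  deviation of the errors;
* `pct_rmse = 100 · rmse / mean(obs)` by default. The alternative
  `total(obs)` denominator is implemented behind the `pct_denominator`
  switch; the per-unit-mean reading is the default because it is the one
  consistent with %RMSE values near 100% on count data of this kind;
* `rmse_per_area` — the RMSE of per-unit density errors
  `(pred − obs)/pixels`. Algebraically this equals the densities-scale RMSE,
  and the test suite asserts that structural identity on fixtures.

## 5. Numerical choices and conventions

* **Grid model**: square pixels; row 1 is the northernmost row; extents are
  half-open; all computation in one projected CRS with metre units
  (distances and areas need linear units); only final export reprojects.
  The working projection is configurable — a local tangent-plane pair to
  WGS84 ships with the package.
* **Rasterization**: pixel-centre containment, boundary-inclusive
  point-in-polygon, ties broken by lowest unit id — deterministic and
  order-independent.
* **Alignment**: intersection extent at the finest pixel size;
  nearest-neighbour for categorical layers, bilinear (edge-replicated) for
  continuous ones; a bilinear target cell is nodata when any contributing
  source cell is.
* **Geometry**: intersection areas come from exact polygon clipping
  (convex clipping directly; ear-clipping triangulation for concave rings),
  not pixel counting, so harmonization is resolution-independent.
  Monte-Carlo point-sampling is used as an independent oracle in tests.
* **Distance transform**: exact separable lower-envelope algorithm on
  squared distances; nodata cells neither serve as features nor receive
  values.
* **Permutation importance**: per-tree OOB permutation — each tree's
  out-of-bag rows are permuted among themselves in the covariate of
  interest, the tree re-scores them, and the percent increase of the
  ensemble OOB MSE is averaged over `n_repeats` (default 5). Raw percent
  increase is reported, with no normalisation by the SD of per-tree
  differences. An identity-permutation hook returns exactly 0 for every
  covariate, pinning the implementation's degenerate case in tests.
* **Determinism**: every stochastic step (world generation, bootstrap,
  permutations) is seeded; two runs from the same configuration agree
  bit for bit, which the pipeline tests assert.
* **Degenerate inputs** fail loudly and early: all-built or all-open masks
  (edge undefined), DEMs smaller than 3×3, empty polygon sets, zones without
  census records, constant responses (variance explained reported as
  undefined rather than inflated).

## 6. Problem sizes used in the tests

Unit tests run on 60–80 pixel worlds with 20–25 model zones; the
property-level acceptance tests use the default 200×200 study conditions for
the pipeline invariants, 100 random masks for the distance-transform oracle,
a 10⁶-point Monte-Carlo oracle for harmonization, and five seeds for the
time-varying comparison. These sizes were chosen so the whole suite
exercises every code path at full ensemble settings (500 trees) while
remaining comfortable to run on a laptop.

## 7. Known limitations

* Polygons are single outer rings; holes and multipolygons are not
  represented (split units into several rows instead).
* No tiled/out-of-core processing: rasters must fit in memory.
* The projection machinery is a single configured pair, not a general CRS
  engine; datum transformations beyond it are out of scope.
* Validation assumes the product and validation tessellations share the
  working grid; non-nesting real-world units are aggregated by the same
  pixel-sum rule without special casing.
* The uniform fallback for zero-weight zones is a mass-conservation device,
  not an estimate; affected zones are listed in the run report and should be
  inspected.
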