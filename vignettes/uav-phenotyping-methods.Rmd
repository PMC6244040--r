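---
title: "Plot-scale trait extraction and growth-curve shape analysis: methods"
author: "phenocurves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plot-scale trait extraction and growth-curve shape analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenocurves)
```

## Overview

`phenocurves` implements a complete analysis chain for multi-temporal,
plot-scale field phenotyping of maize breeding trials imaged from a UAV:

1. **Trait extraction** from co-registered rasters: plant height (PH, cm)
   from crop surface models by vegetation segmentation, neighbourhood maxima
   and ordinary kriging; canopy cover (CC, fraction) and mean NDVI per plot.
2. **Derived growth traits**: the average growth rate of plant height
   (AGRPH, cm/day) and the contribution rate of plant height (CRPH, %)
   between adjacent growth stages, with screening of lodging and
   low-emergence plots.
3. **Distribution and group statistics**: per trait and stage, with a
   normality-gated coefficient of variation and one-way F-statistics across
   genetic-background groups.
4. **Shape clustering**: k-Shape partitional clustering of 4-stage trait
   series under the shape-based distance (SBD), with the cluster number
   chosen jointly by the Davies–Bouldin and Dunn indices.
5. **Typical curves**: per-cluster stage-mean trajectories with 95%
   confidence bands, classified by a zenith/adjacent-point naming grammar,
   plus genetic-background recognition rates and cross-trait membership
   overlap.

Because raw breeding-trial imagery is rarely distributable, the package
ships a seeded synthetic scene generator that emulates the statistical
structure the analysis assumes, with known ground truth for every plot.
All tests and examples run against generated scenes.

## Plant height at the plot scale

A crop surface model (CSM) is the per-pixel difference between a
growth-stage digital surface model (DSM, top of canopy) and the bare-soil
digital elevation model (DEM): `compute_csm()` returns `DSM − DEM`, a
canopy-height map in cm. Height above ground must be non-negative, which
fixes the direction of the difference.

A CSM mixes soil pixels (height ≈ 0) and plant pixels. Averaging them
would badly underestimate height; taking the single global maximum would
measure one leaf of one plant. The plot-scale method instead:

1. **Segments** plants from soil with the normalized green–red difference
   index, NGRDI = (ρ~green~ − ρ~red~)/(ρ~green~ + ρ~red~). Vegetation is
   NGRDI-positive, bare soil non-positive; `plant_mask_from_ngrdi()` uses
   the strict rule "plant iff NGRDI > 0" (a pixel exactly at 0 is soil).
2. **Clips** the masked CSM to the plot region of interest. Breeding plots
   are small and tightly packed, so leaves of adjacent plots cross plot
   borders at later stages; each plot rectangle is shrunk inward by 0.25 m
   (`plot_roi()`, configurable) before any statistic is computed.
3. **Collects neighbourhood maxima** (`block_maxima()`): the masked CSM is
   resampled to a coarser cell by max-aggregation and tiled into
   non-overlapping 3 × 3 windows; each window contributes its highest
   pixel, with that pixel's world coordinates and value. Max-aggregation
   (never averaging) keeps the upper-leaf pixels the method is built
   around. Partial edge windows are kept so small ROIs retain coverage.
   The resample cell defaults to 5 cm; the right value depends on the
   native DSM resolution (1–3 cm/pixel for typical mapping flights), and
   it is exposed as a parameter.
4. **Interpolates** the maxima by ordinary kriging over a grid covering the
   ROI (`krige_plot_height()`, grid spacing 5 cm by default) and takes the
   maximum of the interpolated surface as the representative plot height.

### Kriging details

The variogram is a spherical model (nugget, partial sill, range) fitted by
least squares to the binned empirical semivariogram (12 bins, pairs up to
0.75 of the maximum point distance). If the fit degenerates the model
falls back to a linear variogram through the origin, and with fewer than 5
points — too few to estimate any variogram — the maximum point value is
returned directly. Coincident point locations are deduplicated (keeping
the higher value) before the kriging system is solved. The kriging system
uses γ(0) = 0 on the diagonal, so the predictor interpolates the data
exactly: the returned height can never fall below the highest measured
maximum (the prediction grid always includes the data locations). On a
constant field the prediction is that constant.

### Conventions fixed for reproducibility

* A pixel belongs to a polygon iff its **centre** lies inside (even-odd
  rule via `mgcv::in.out`); raster origin at the top-left corner, world
  coordinates in metres, cell sizes in cm/pixel.
* NGRDI = 0 and NDVI = 0.1 classify as **non-plant** (strict
  inequalities).
* Zero-sum band pixels propagate as nodata.

## Canopy cover and mean NDVI

NDVI = (ρ~nir~ − ρ~red~)/(ρ~nir~ + ρ~red~); pixels with NDVI > 0.1 are
plant (`plant_mask_from_ndvi()`, threshold configurable). Canopy cover is
a pure area ratio: plant pixels inside the shrunk plot ROI over all ROI
pixels (`plot_cc()`). The plot NDVI value is the arithmetic mean over
those plant pixels (`plot_mean_ndvi()`); a plot with an empty plant mask
yields a missing value carrying a `"no-plant"` status rather than an
error, and the same convention holds for plant height
(`extract_plot_ph()`).

## Derived growth traits and outlier screening

With stage calendar dates in days after sowing (DAS; the default calendar
is 24/44/57/84 for the four critical stages S1–S4):

* AGRPH over interval *i* is `(PH[i+1] − PH[i]) / (DAS[i+1] − DAS[i])`
  (cm/day) — invariant to shifting all dates by a constant.
* CRPH over interval *i* is `(PH[i+1] − PH[i]) / PH[S4] × 100` (%) —
  invariant to rescaling heights by a positive constant, and the three
  intervals telescope to `(PH[S4] − PH[S1]) / PH[S4] × 100`.

`build_trait_table()` assembles per-stage extractions into one long table
and keys each derived value to the interval *starting* at its stage.

`filter_outlier_plots()` applies two screens, each logged per plot:

* **Lodging**: a strict height decrease between consecutive stages
  followed later by a strict increase. Lodged plants are knocked down and
  partially recover, which no healthy growth curve does. The rule is the
  weakest operationalization of that pattern (any dip-then-rebound), since
  no magnitude threshold is defensible without ground truth.
* **Low emergence**: canopy cover at S2 below 0.05. A plot that has not
  reached 5% cover by canopy closure onset was essentially not planted;
  0.05 matches the lowest early-stage cover seen in a healthy trial and is
  configurable.

## Distribution and group statistics

`describe_trait_stage()` reports n, mean, SD, min/max, quartiles (type-7),
adjusted Fisher–Pearson sample skewness and excess kurtosis
(`e1071::skewness`/`kurtosis`, type 2 — the convention under which a
near-normal sample scores near 0/0), the Shapiro–Wilk p-value, and the
**normality-gated CV**: `100·SD/mean` when the sample passes the test
(p > 0.05), `100·SD/median` when normality is rejected (p ≤ 0.05,
boundary included). The median basis is robust exactly for the skewed
samples that fail the gate. Shapiro–Wilk is defined for 3–5000
observations; larger samples are tested through 5000 evenly spaced order
statistics.

`correlation_matrix()` gives pairwise Pearson r with two-tailed t-test
p-values on pairwise-complete observations. `group_f_statistics()` runs
the classical one-way ANOVA F across the genetic-background groups
(GRP1–GRP4) per stage and reports the stages sorted by ascending F — the
compact answer to "at which stage do groups differ least/most".

## Shape clustering of trait series

Growth dynamics, not absolute levels, distinguish genotype groups, so
series are compared after z-normalization (mean 0, SD 1; a constant series
has no shape and maps to the zero vector). The **shape-based distance** is

> SBD(x, y) = 1 − max over shifts s of NCCc(x, y; s),

the coefficient-normalized cross-correlation maximized over all 2T − 1
alignment shifts. It is symmetric, lies in [0, 2], and is zero iff the
series agree up to shift and positive affine scaling. Four-stage series
are short, but the full 7-shift range is kept: the standard algorithm is
applied unchanged, and shift invariance costs nothing at this length.

**k-Shape** alternates (a) assignment of every series to the nearest
centroid by SBD and (b) centroid refinement by *shape extraction*: members
are shift-aligned to the current centroid and the new centroid is the
principal eigenvector of the centred member outer-product matrix — the
maximizer of the summed squared normalized cross-correlation. The
eigenvector's sign is fixed by whichever orientation has the smaller total
SBD to the members. Random initial assignment comes from the passed seed;
results are deterministic per seed.

Shape extraction maximizes a *squared*-correlation surrogate, so an
individual sweep can increase the SBD objective, and on short noisy series
the label sequence can oscillate between two states. `kshape_cluster()`
therefore tracks the best (lowest-objective) state seen and returns it;
the accepted objective sequence, exposed as `trace`, is non-increasing by
construction, and iteration stops at label stability or `max_iter`.
Emptied clusters are reseeded from the globally worst-fitted row.

### Cluster number

`select_cluster_number()` scans k = 2…k_max (default 20), computing the
Davies–Bouldin index (lower better) and Dunn index (higher better) with
SBD as the dissimilarity. When one k optimizes both simultaneously it
wins; otherwise — "minimize DBI and maximize DI simultaneously" is not an
algorithm — the declared fallback is the best sum of ranks (DBI ascending,
DI descending), ties to the smaller k, and the full CVI table is returned
so the choice is auditable. Degenerate configurations (coincident
centroids, all-singleton clusters) are flagged with warnings; at k close
to the number of series the indices lose meaning, which is why the scan is
capped well below the series count in practice.

## Typical curves and their names

A cluster's typical curve is its per-stage mean trajectory with 95%
confidence half-widths `t(0.975, n−1)·SD/√n` — the t interval, because
clusters are often small. The naming grammar uses two decisive points:

* the **zenith** Z*k*: the stage of the maximum mean (ties broken to the
  earliest stage for determinism), and
* the zenith's neighbour on its **longer arm**, judged against the
  straight chord from the zenith to that arm's endpoint: Z2 → adjacent S3
  against the Z2–P4 chord; Z3 → adjacent S2 against Z3–P1; Z4 → adjacent
  S3 against Z4–P1; and (an extension never exhibited in 4-stage maize
  data but needed for totality) Z1 → adjacent S2 against Z1–P4.

The adjacent point is **A** (above) or **B** (below) when its vertical
offset from the chord exceeds 2% of the curve's value range, else **O**
(on the line). The range-relative tolerance makes the name invariant to
positive affine transforms of the values and replaces a visual judgment
with an explicit, configurable constant. This yields the nine-type space
{Z2, Z3, Z4} × {A, B, O} plus Z1 edge cases.

`recognition_rate()` reports, per cluster or per pooled name-type, the
most frequent genetic-background group and its share in percent;
`membership_overlap()` compares two clusters' member sets as
`100·|A∩B|/min(|A|,|B|)` — the denominator is a declared choice, since an
overlap percentage between sets of unequal size is otherwise ambiguous.

## The synthetic scene generator

`generate_field_scene()` builds, from one seed, the structures the
pipeline consumes, with ground truth recorded at generation time:

* **Layout**: a grid of 2.4 m × 2 m plots separated by 0.4 m alleys,
  sown in rows 0.6 m apart at 6 plants/m² — the geometry of a dense maize
  breeding trial. Group labels are drawn in proportion 107:28:163:90
  (GRP1:GRP2:GRP3:GRP4), the composition of a 388-plot trial.
* **Terrain**: smooth low-frequency relief (sum of four random cosine
  waves) with 2 cm amplitude — flat enough to match a managed field,
  non-zero so CSM differencing is actually exercised.
* **Canopy**: every plant is a truncated paraboloid crown,
  `h(r) = H·max(0, 1 − (r/R)²)`, and the canopy is the pointwise maximum
  over plants added to the DEM. The paraboloid gives the mixed
  high/low-pixel structure the height method is designed for, with an
  analytically known apex; plant positions snap to pixel centres so the
  apex is attained exactly on the grid and the recorded truth equals
  `max(DSM − DEM)` per plot. Per stage, the tallest plant of a plot draws
  its apex from that stage's height range — defaults
  (1–26, 69–184, 117–251, 148–365 cm) follow the observed per-stage
  minima and maxima of a real trial — and the other plants sit at 60–95%
  of it with 2 cm jitter. Crown radius is 0.35 m scaled by
  `min(1, sqrt(H/150 cm))`, so young plants have small crowns.
* **Reflectance**: plant {green 0.12, red 0.06, NIR 0.45}, soil
  {green 0.10, red 0.12, NIR 0.14} — chosen to satisfy the segmentation
  separability invariants with margin (plant NGRDI +0.33 / NDVI 0.76;
  soil NGRDI −0.09 / NDVI 0.08). Bands take the plant value exactly where
  canopy height is positive, so the true plant-pixel set is recoverable by
  either index and per-plot mean NDVI is known exactly.
* **Config validation** rejects any reflectance pair that would break the
  NGRDI-sign or NDVI-threshold separability, and any geometry where the
  border shrink empties the plot.

`generate_trait_matrix()` plants labelled cluster structure for the
clustering stack: member series are prototype curves plus i.i.d. Gaussian
noise, with group labels drawn from per-cluster mixture rows. The test
prototypes share a common range (so one noise SD means the same relative
perturbation in every cluster) and are pairwise well separated under SBD
in both orientations — no prototype is a shift or a mirror image of
another, configurations that the shape-based distance deliberately
identifies and that would make any planted "truth" unrecoverable by any
shape-based method.

### What the generator does *not* emulate

Photogrammetric reconstruction noise and mosaicking artefacts; radiometric
miscalibration and within-canopy reflectance variation (bands are
piecewise constant); mixed border pixels; plant-to-plant shape variation
beyond apex scaling; tassels (a known source of field height
underestimation); lodging geometry (lodged plots are planted in *tables*,
not rendered in rasters). Passing tests therefore demonstrate that the
algorithms are implemented correctly and recover known structure under the
stated noise model — not that field-measured accuracies transfer to any
particular sensor or flight plan.

## Problem sizes and runtime choices

The test and example scenes are deliberately modest: 2 × 2-plot scenes at
2–8 cm/pixel for invariant checks, a 50-plot single-stage scene at
2 cm/pixel for height-recovery accuracy (mean absolute relative error ≤ 5%
and rank correlation ≥ 0.95 against truth), and 60–120 series for
clustering recovery (ARI ≥ 0.9 at noise equal to 10% of the prototype
range, planted k ∈ {2, 3, 4} recovered by the joint CVI rule). These sizes
keep the full suite under a minute while exercising every code path at
realistic resolutions.

## Known limitations

* The height method's accuracy depends on the resample cell relative to
  crown size; the 5 cm default suits 1–3 cm/pixel DSMs and dense canopies.
* The kriging maximum can slightly exceed the tallest input point
  (ordinary kriging weights may overshoot between points); this is a
  property of the interpolator, not a bug, and is bounded in practice by
  the variogram fit.
* Cluster validity indices degenerate as k approaches the series count;
  the scan cap, not the indices, prevents absurd selections there.
* The naming grammar assumes four stages; longer calendars get typical
  curves but no names.
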