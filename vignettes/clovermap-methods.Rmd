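---
title: "clovermap: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{clovermap: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `clovermap`, the parameters that
matter, the synthetic world the tests run on, and the numerical and design
choices a maintainer would want written down.

## 1. The problem and the approach

A mixed grass–clover sward photographed at millimetre resolution is a
texture of interleaved leaves. Pixel-wise classification of such imagery is
noisy ("salt and pepper") and expensive to label. Object-based image
analysis (OBIA) instead segments the image into spectrally homogeneous,
spatially contiguous objects and classifies objects. The chain is:
raster stack → mean-shift segmentation → per-object features → Random
Forest → species map → cover fractions per harvest subplot → regression
against dry-matter-yield (DMY) proportions.

## 2. Preprocessing

**Terrain.** The DTM is interpolated from surveyed ground points by
Delaunay triangulation (via `deldir`) with linear barycentric interpolation
inside the convex hull. Cells outside the hull are filled from the plane of
the triangle adjacent to the nearest hull edge and flagged — a choice that
is exact for affine terrain and well-behaved for the gentle surfaces the
generator produces. Collinear point sets raise an error rather than
guessing. `CHM = DSM − DTM`, with negative heights clamped to zero:
below-terrain canopy is physically impossible, and clamping keeps the
feature interpretable.

**Colour.** The HIS transform follows the HSL convention (intensity =
lightness = (max+min)/2), matching the GRASS-style tool family; hue of
achromatic pixels is defined as 0. For the analysis stack H, I and S are
rescaled to 0–255 so that a single DN-scale range radius governs all
segmentation bands.

**Vegetation indices.** The RGB indices use chromatic coordinates
(ExG = 2g − r − b, ExR = 1.4r − g, ExGR = ExG − ExR,
NGRDI = (G − R)/(G + R)). The multispectral set (CIg, EVI, GARI, GNDVI,
MCARI, MSAVI, NDVI, SR_717) uses the standard literature forms, frozen in
one registry (`compute_vis_ms`). The dual-green/dual-red/triple-red-edge
sensor needs a band-role mapping; the defaults (green 560, red 668, blue
475, red edge 705/717, NIR 840 nm) pick the wavelength closest to each
index's canonical definition and can be overridden via `ms_band_roles()`.
Zero denominators become nodata rather than infinities.

**Alignment.** Nearest-neighbour resampling onto a target grid, with
distance ties broken toward the upper-left source cell — deterministic and
idempotent. The coordinate convention throughout is (row, col) with origin
at the upper-left, half-open cells, and map y decreasing with row.

## 3. Mean-shift segmentation

Three parameters control the segmentation: `spatialr` (spatial radius in
pixels; the window is square, i.e. Chebyshev distance, matching windowed
implementations), `ranger` (spectral radius in radiometry units — DN for
8-bit imagery, reflectance for 0–1 imagery) and `minsize` (minimum region
size in pixels). Per pixel, the filter repeatedly averages the window
pixels whose spectral distance to the current value is at most `ranger`,
moving both value and position, until the value moves less than
`conv_threshold` (default 0.1 radiometry units) or `max_iter` (default
100) is reached — the cited tool family's defaults, both exposed.

Clustering forms 4-connected components whose adjacent modes differ by at
most `ranger`; 4-connectivity avoids corner-touching leakage between thin
leaves (switchable to 8 would be a one-line change in the C++ kernel, kept
out of the interface deliberately). Regions smaller than `minsize` are
merged, smallest first, into the 4-adjacent region with the nearest mean
spectral vector; ties go to the lower label id so runs are reproducible.
Labels are renumbered in row-major discovery order for the same reason.

Spectral distance uses all stacked bands unscaled (the segmentation stack
mixes DN-scale bands and a metre-scale CHM; the CHM's numeric range is
small, so it contributes little — consistent with stacking the raw
variables rather than standardizing them). Tiling, when enabled, applies
only to the (quadratic-cost) filter stage: tiles are filtered with an
overlap margin of `spatialr × max_iter` (capped at half the tile), only
core pixels are kept, and clustering/merging run on the assembled mode
grid. With a sufficient margin the tiled partition is bit-identical to the
untiled one, which the tests assert on a 128 × 128 scene.

## 4. Features, labelling, classification

**Zonal statistics** use the population (divide-by-n) standard deviation,
matching common zonal-statistics tools. Pixel membership is cell-centre
containment; a centre exactly on a polygon boundary counts as inside.

**Shape indices** are computed on the staircase (pixel-boundary) polygon,
consistent with the vectorization: A, P, P/A, P/√A, Sphericity =
2√(πA)/P, ShapeIndex = P/(2√(πA)) (exact reciprocal of the sphericity —
both kept for fidelity to the nine-column feature list), Dmax (polygon
diameter, computed from the convex hull), Dmax/A, Dmax/√A.

**Labelling.** A segment is selected when it lies entirely within a
labelled polygon or its interior intersects one with positive area
(`within_overlap`), or only in the first case (`within_only`). Because
segments are unions of grid cells and reference polygons are rectangles,
intersection areas are computed exactly as sums of per-cell rectangle
overlaps — no geometry engine, no approximation. A segment touching
several labelled polygons takes the class of the largest intersection;
exact ties exclude the segment with a warning (the least surprising rule;
the selection is logged per conflict).

**PCA** of the reference-polygon summary standardizes columns (correlation
PCA): bands, indices and heights live on incommensurable scales. Components
are ordered by decreasing variance and each loading vector is oriented so
its largest-magnitude entry is positive.

**Random Forest.** No suitable forest implementation is available in the
target environment, so the package ships a compact compiled one: bagged
CART trees, Gini impurity, `mtry` random candidate features per node
(default ⌊√p⌋), trees grown to purity (min node size 1), 500 trees.
If none of the `mtry` sampled features admits a valid split, the search
continues down the feature permutation (as ranger-style forests do) rather
than forcing a premature leaf. All randomness flows through R's RNG, so a
single seed reproduces training exactly; majority-vote ties resolve to the
lowest class code. No class-imbalance correction is applied — minority
classes being overlooked is a property of the modelled procedure, not a
defect to fix.

**Spatial cross-validation** holds out one field replicate per fold (8
plots, 4 replicates → 4 folds of 6 training and 2 test plots). Per-class
F1 is undefined (NA) when a class is absent from both truth and
predictions in a fold, and such classes are excluded from averages.

## 5. The synthetic world

Every test runs on generated scenes, so what the generator does (and does
not) emulate matters.

* **Patch structure:** one smoothed Gaussian random field per class,
  argmax after adding per-class offsets. The offsets are calibrated by a
  damped fixed-point iteration (step clamped to ±0.5 in log space, best
  iterate kept) so realized fractions match the priors; the calibration is
  deterministic given the fields. Patch correlation length defaults to
  0.08 m — patches of leaves, not single leaves.
* **Spectra:** per-class mean vectors plus spatially correlated Gaussian
  noise (correlation length 0.01 m, leaf-scale speckle), clipped to the
  sensor range. Defaults put the grass–clover Mahalanobis separation near
  6 (classifiable but not trivial) with grass darker than clover in every
  band. Plantain and weed sit between the two majors, slightly
  clover-ward: confusable minors whose misclassification splits between
  grass and clover (RGB) or leans to clover (MS) — the structure reported
  for real swards. `separation_scale` shrinks all class means toward their
  common centre to produce harder worlds.
* **Heights:** class means 0.15–0.17 m with 0.02 m noise — deliberately
  near-identical across classes so the CHM is a weak feature, as in a
  uniformly mown sward.
* **Terrain:** a deterministic sum of low-frequency sinusoids (amplitude
  5 cm), so TIN recovery is checkable analytically.
* **DMY link:** clover weight fraction w = βc / (βc + (1 − c)) with
  β = 0.5 — at 55% visible cover, ~38% of dry weight, encoding the rule of
  thumb that visible clover roughly doubles its weight share. Lognormal
  noise (sd 0.05) multiplies w before renormalization; non-clover classes
  split the remainder in proportion to cover; subplot totals are lognormal
  around 60 g (~200 g/m² over a 0.3 m² frame, an ordinary spring-cut
  yield).
* **Layout:** 2 mixtures × 4 replicates; mixture "2" is grass + clover
  (+5% weed), mixture "3" adds 10% plantain. Ten 0.55 × 0.55 m subplot
  frames are placed one per plot with two extras.

A green end-to-end test therefore establishes that the chain recovers a
known world with the modelled noise structure. It does **not** establish
field-level accuracy: the generator has no shadows, no BRDF, no
photogrammetric artifacts, no mixed-species occlusion, no registration
error between sensors, and its class spectra are stationary within a
scene. The field study this design models reached overall accuracies near
0.7; the synthetic world, lacking those nuisances, sits near 0.93 at the
default separation, and the tests assert behaviour (accuracy bands,
monotone degradation with separation, cover-recovery error bounds), not
the field numbers.

## 6. Numerical choices and degenerate inputs

* Realized class fractions approach priors as extent grows; the ±0.05
  assertion is made at 1000 × 1000 px.
* Convergence: mean-shift stops on spectral movement < 0.1 (squared
  comparison, no square root in the hot loop).
* Merging of a region with no 4-neighbour (isolated by nodata) leaves it
  untouched rather than looping.
* Zero-area polygons, all-zero confusion matrices, single-class training
  sets, zero-variance regressors, empty reference sets and subplots
  outside the mapped extent all raise errors; empty zones and zero-variance
  PCA columns are dropped with warnings.
* The experiment report is a pure function of (config, seed): per-fold and
  per-combination seeds are derived deterministically from the experiment
  seed, and rerunning writes byte-identical tables.
* "Insufficient object separation" (the rule that removes degenerate
  parameter combinations) is operationalized as a configurable floor on
  the scene-wide segment count, defaulting to the number of labelled
  reference polygons — fewer segments than labels cannot support a
  learning database. The designated combination for full-scene mapping
  defaults to the best pooled OA among the surviving combinations, and the
  mapping model is trained on the `within_overlap` learning database from
  all plots.

## 7. Known limitations

* Rasters are held in memory as matrices; scenes far beyond ~10⁷ pixels
  per plot need the tile-wise path and patience.
* Reference polygons are axis-aligned rectangles. The labelling logic is
  exact for them; arbitrary hand-digitized polygons would need the
  cell-centre rasterization path of `zonal_stats`, which is approximate at
  polygon edges.
* GeoTIFF/GeoPackage I/O is out of reach without a GDAL-backed stack in the
  environment; the package reads and writes ESRI ASCII grids, CSV and YAML
  instead. The in-memory contracts mirror the georeferenced-raster model,
  so swapping the I/O layer for `terra` would be mechanical.
* The vectorizer assumes each label is one 4-connected component (true for
  this pipeline's outputs); multi-part labels would need a component split
  first.
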