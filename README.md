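# clovermap

Object-based image analysis (OBIA) of species composition in mixed
grass–clover swards.

Grass–legume mixtures are the backbone of temperate forage production, and
the clover share of the sward drives both feed value and fertilization
decisions. Estimating that share by cutting, sorting, drying and weighing
biomass is slow and destructive; visual scoring is biased (visible clover
cover runs roughly twice the clover's dry-matter share). `clovermap`
implements the alternative: segment very-high-resolution aerial imagery of
the sward into objects, classify each object as grass, clover, plantain or
weed with a Random Forest, and convert the resulting species map into
per-subplot cover fractions that can be regressed against dry-matter-yield
(DMY) proportions.

The package is aimed at people building or studying such pipelines —
agronomists, remote-sensing researchers, method developers — and ships a
synthetic sward-scene generator with full ground truth so every stage is
testable without field data.

## The pipeline

1. **Synthetic scene** (`simulate_scene`): 8 plots (2 mixtures × 4
   replicates) of patchy 4-class cover (codes 1 = grass, 2 = clover,
   3 = plantain, 4 = weed) at 2 mm (RGB, DN 0–255) or 2 cm (10-band
   multispectral, reflectance 0–1) resolution, with a deterministic terrain,
   class-specific canopy heights, labelled reference polygons (~17% of plot
   area), 0.55 × 0.55 m subplot frames and a DMY table linked to true cover
   through the monotone distortion `w = βc / (βc + (1 − c))`.
2. **Preprocessing** (`preprocess_scene`): TIN-interpolated DTM from
   surveyed ground points, canopy height model `CHM = DSM − DTM`, HIS colour
   transform, vegetation indices (ExG, ExR, ExGR, NGRDI for RGB; CIg, EVI,
   GARI, GNDVI, MCARI, MSAVI, NDVI, SR_717 for MS), nearest-neighbour
   alignment and stacking.
3. **Segmentation** (`segment_image`): mean-shift filtering under the
   `spatialr` / `ranger` / `minsize` parameterization, mode clustering,
   small-region merging, vectorization.
4. **Features** (`build_feature_table`): zonal mean and (population) sd of
   every stack variable per segment, plus nine polygon shape indices
   (A, P, P/A, P/√A, Sphericity, ShapeIndex, Dmax, Dmax/A, Dmax/√A).
5. **Labelling** (`spatial_join_labels`): segments joined to reference
   polygons (`within` + `overlap`, or `within`-only), largest intersection
   wins; `reference_summary` / `pca_reference` reproduce the
   reference-polygon boxplot/PCA analysis.
6. **Classification** (`run_spatial_cv`): Random Forest (500 trees,
   mtry = ⌊√p⌋, min node size 1) under replicate-wise spatial 4-fold
   cross-validation; overall accuracy (OA) and class-wise F1.
7. **Quantification** (`predict_map`, `cover_fractions`,
   `regress_cover_vs_dmy`): full-scene species map, per-subplot cover
   fractions `cover % = class area / subplot area`, DMY proportions
   `weight % = class DMY / total DMY`, and the OLS regression of clover
   cover against clover DMY proportion (R² as squared Pearson r).

## Worked example

```r
library(clovermap)
cfg <- experiment_config(
  scene  = scene_config(extent_m = c(1.024, 1.024), pixel_size_m = 0.004),
  sensor = "rgb",
  grid   = data.frame(spatialr = 10, ranger = c(10, 30), minsize = c(30, 120)),
  seed   = 1)
report <- run_experiment(cfg)
print(report)
```

```
experiment_report: 2 combinations (1 kept), sensor rgb
 combination spatialr ranger minsize n_segments n_labeled        oa  kept
           1       10     10      30       6765      2201 0.9363925  TRUE
           2       10     30     120         87        49 0.8979592 FALSE
clover cover vs DMY: R^2 = 0.991, p = 1.73e-09 (combination 1)
```

Combination 1 (small segments) keeps 6765 segments, of which 2201 picked up
a label from the reference polygons; replicate-wise CV gives a pooled OA of
0.936. Combination 2 produced only 87 segments — fewer than the labelled
reference polygons — so it is flagged for insufficient object separation
and excluded from the summary, mirroring the general finding that
segmentations generating smaller objects classify better. The designated
(best-OA) combination then maps the whole scene and clips it by the ten
subplot frames:

```r
q <- report$quantification
q$regression
#> y = -4.124 + 0.685 x, R^2 = 0.991, p = 1.73e-09, n = 10
head(q$cover[q$cover$class == 2, c("subplot_id", "area_m2", "cover_pct")], 4)
#>    subplot_id    area_m2 cover_pct
#> 2          S1 0.16168766  53.45046
#> 6          S2 0.06000031  19.83481
#> 10         S3 0.16851226  55.70653
#> 14         S4 0.14014549  46.32909
```

The regression slope below 1 is the expected signature of the generator's
cover→weight distortion (visible clover overstates its weight share); R²
of 0.99 reflects the low-noise synthetic world, not field conditions.

## Command line

```sh
Rscript inst/cli/clovermap experiment --config scene.yaml --seed 1 --out out/
```

Subcommands: `simulate`, `preprocess`, `segment`, `features`, `label`,
`cv`, `map`, `quantify`, `experiment`. Outputs are plain text: ESRI ASCII
grids for rasters, CSV for tables, YAML for configurations.

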