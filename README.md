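# hepazone

Zonal phenotyping of hepatocyte organelles along the porto-central axis of
the liver lobule.

Hepatocyte function is zonated: lipid oxidation dominates near the portal
triad (PP), lipid synthesis and storage near the central vein (PC). That
division of labor is written into organelle architecture — mitochondrial
shape and density, lipid-droplet (LD) number and size, and the physical
contacts between mitochondria and LDs all change with lobular position and
with nutritional state (chow, fasting, Western diet). `hepazone` turns
multi-channel 2D fluorescence sections of the lobule into quantitative
zonal signatures of that architecture. It is aimed at labs doing liver
imaging who want per-cell organelle morphometry resolved along the tissue
axis, and at method developers who need a fully synthetic, ground-truthed
test bed for such pipelines.

## What it computes

* **Spatial model** — from central-vein (CV) and portal-vein (PV)
  annotations: axis length *L* (minimal boundary-to-boundary distance),
  each cell's normalized coordinate `d_norm = d_CV / L`, and its zonal bin
  `bin = 12 − floor(12 · d_norm)` (clamped to 1..12), so bin 12 touches the
  CV and bin 1 the portal vessels.
* **Segmentation** — a pluggable contract (any function from channel to
  label map, e.g. a learned model) with a classical fallback: watershed
  basins of the inverted actin + blurred-mitochondria guidance channel for
  cells; Otsu + connected components for organelles; an LD mean-intensity
  filter against false positives.
* **Morphometry and contacts** — per object: area, perimeter (weighted
  boundary-step contour length), circularity `4πA/P²` (1 for an ideal
  disk), eccentricity, solidity, Feret diameter, mean intensity. Per cell:
  counts, total/average areas, densities (organelle area fraction),
  percent mito–LD pixel overlap and exact minimal mito–LD distances.
* **Zonal signatures** — per-bin mean/sd/n profiles, standardized PCA with
  deterministic orientation, complete-linkage cluster heatmaps, Pearson
  condition-correlation matrices (displayed at 2 decimals), and bin ×
  condition overlap heatmaps.
* **Moderated statistics** — channel-loading and pooled-reference
  normalization, quantile normalization, row-wise linear-model contrasts
  (including diet-by-genotype difference-of-differences), empirical-Bayes
  variance shrinkage (`s²_post = (d₀s₀² + ds²)/(d₀+d)`, t on `d+d₀` df),
  Benjamini–Hochberg q-values, and zonation calls at p < 0.05 and fold
  change ≥ 1.2 (AND/OR switchable).
* **Synthetic lobules** — a generator rendering 250 µm axes of 12–16
  cells with per-bin target curves for mitochondrial circularity/density,
  LD count/size and mito–LD contact fraction, with exact ground-truth
  labels and bit-reproducible output; presets `CNTR`, `fasted`, `WD`.

## Worked example

Generate a control-diet axis, run the full pipeline against its labels and
summarize by bin:

```r
library(hepazone)

spec <- preset_condition("CNTR")
ax   <- generate_axis(spec, seed = 42)

axis <- measure_axis_length(ax$annotation)
axis$length_um
#> [1] 250.2

cells <- phenotype_axis(ax$image, ax$labels, ax$annotation, condition = "CNTR")
head(cells[, c("cell_id", "bin_index", "d_norm", "mito_count",
               "mito_avg_circularity", "ld_count", "overlap_pct")], 4)
#>   cell_id bin_index d_norm mito_count mito_avg_circularity ld_count overlap_pct
#> 1       1         1  0.953         16                0.881        1           0
#> 2       2         2  0.871         15                0.876        1           0
#> 3       3         3  0.789         19                0.864        1           0
#> 4       4         4  0.703         19                0.860        2           0

prof <- aggregate_by_bin(cells, condition = "CNTR")
round(prof$mean[c(1, 6, 12), c("mito_avg_circularity", "mito_density", "ld_count")], 3)
#>     mito_avg_circularity mito_density ld_count
#> R1                 0.881        0.080        1
#> R6                 0.824        0.105        2
#> R12                0.597        0.160        8

zonal_pca(prof, n_components = 2)$explained
#> [1] 0.629 0.102
```

Reading the output: periportal cells (bin 1, `d_norm` near 1) carry few,
small LDs and round mitochondria (circularity 0.88); pericentral cells
(bin 12) have elongated mitochondria (0.60), higher mitochondrial density
and eight-fold more LDs — the control-diet zonation gradient the package
is built to measure, and here recovered from rendered pixels rather than
copied from the generator curves. The first principal component of the
bin profiles captures that gradient (63% of variance).

Cell segmentation from the channels rather than ground truth:

```r
g   <- build_cell_guidance_channel(ax$image$channels$actin,
                                   ax$image$channels$mito,
                                   sigma_um = 2, pixel_size = 0.2)
seg <- segment_cells(g, pixel_size = 0.2)
```

Command-line wrappers for simulation and zonation calls live in
`inst/scripts/` (`simulate-axes.R`, `zonate.R`).

## Package layout

* `R/geometry.R` — vein annotations, axis length, coordinates, bins
* `R/segmentation.R` — guidance channel, backends, fallbacks, filters
* `R/features.R` — shape features, contact metrics, per-cell vectors
* `R/zonal.R` — bin profiles, PCA, clustering, correlations, heatmaps
* `R/synthetic.R` — condition specs, presets, axis generator
* `R/stats.R` — normalization, contrasts, moderation, zonation calls
* `vignettes/zonal-organelle-phenotyping.Rmd` — methods and design notes
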