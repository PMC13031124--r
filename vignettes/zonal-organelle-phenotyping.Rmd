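---
title: "Zonal organelle phenotyping along the porto-central axis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zonal organelle phenotyping along the porto-central axis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepazone)
```

## The measurement problem

Hepatocytes specialize along the porto-central (PP–PC) axis of the liver
lobule: lipid oxidation dominates periportally, lipid synthesis and storage
pericentrally. This zonation is visible in organelle architecture —
mitochondrial shape and density, lipid-droplet (LD) number and size, and
the physical contacts between the two organelles all vary with lobular
position and with nutritional state. `hepazone` quantifies that
architecture from 2D multi-channel fluorescence sections: each segmented
hepatocyte receives a spatial coordinate along its axis, per-cell organelle
features are extracted, and per-bin zonal signatures are compared across
conditions with multivariate summaries and moderated statistics.

## Spatial model: coordinates and bins

A cropped axis is annotated with central-vein (CV) and portal-vein (PV)
landmark masks. The axis length $L$ is the minimal boundary-to-boundary
Euclidean distance between the two landmarks (pixel-centre metric, reported
in µm); an `axis_record` override accepts a manually measured polyline
length for curved axes. Each cell's coordinate is

$$d_\mathrm{norm} = \frac{d_\mathrm{CV}}{L},$$

where $d_\mathrm{CV}$ is the Euclidean distance from the cell centroid to
the nearest CV boundary pixel. Values above 1 (cells beyond the cropped
axis) are clamped and flagged rather than dropped, with a switch to drop.
The axis is partitioned into 12 half-open bins with

$$\mathrm{bin} = n_\mathrm{bins} - \lfloor d_\mathrm{norm}\, n_\mathrm{bins} \rfloor$$

clamped to $[1, n_\mathrm{bins}]$, so bin 12 is adjacent to the CV and bin
1 to the portal vessels; ties at bin edges resolve deterministically toward
the CV side. Twelve bins keep at least one hepatocyte per bin for axes of
12–16 cells.

## Segmentation contract

Cell segmentation operates on a guidance channel: min–max scaled actin
plus min–max scaled Gaussian-blurred mitochondria (default blur sigma 2 µm),
so that boundaries (actin) and cytoplasmic fill (mitochondria) both
contribute. Any function mapping a channel to an integer label map can be
plugged in as a backend — a learned model wrapper, for instance — and
backend failures are reported with the backend's identity. The classical
fallback smooths the guidance channel (sigma 1 px) and extracts cells as
watershed basins of the inverted channel: the bright actin ridges become
basin boundaries without committing to an absolute threshold. A merging
tolerance (default 0.3 on the rescaled channel) absorbs the shallow basins
that organelle signal creates inside a cell. We chose the watershed over a
fixed ridge threshold after observing that in organelle-dense cells the
blurred mitochondrial signal approaches the actin ridge level, so that any
global threshold either fragments dense cells or dissolves ridges; an
absolute-threshold route (`threshold =`) is retained, with hole refilling,
for images where it is appropriate. Cells touching the image border are
excluded by default and a minimum cell area of 100 µm² applies.

Organelles are segmented per channel by Otsu's threshold plus connected
components, with minimum areas of 0.2 µm² for mitochondria and LDs. LD
segments additionally pass an intensity filter that removes objects whose
mean LD-channel intensity falls below a threshold — by default the 25th
percentile of per-object means, or an absolute value. These defaults are
declared package choices: the quantities exist in the workflow this package
implements, but their values are not prescribed anywhere, so they are
exposed in the configuration surface.

## Morphometry

Per-object features follow regionprops conventions: area is the pixel
count times the squared pixel size; eccentricity comes from the second
central moments; solidity is the area over the convex-hull area with the
hull taken over pixel corners, so solid convex objects score exactly 1;
the Feret diameter is the longest distance between any two boundary-pixel
centres (computed exactly via the convex hull). The perimeter estimator is
stated explicitly because circularity depends on it: the outer contour is
traced with Moore 8-connected neighbour following and its length is the
sum of step weights, 1 for orthogonal and $\sqrt{2}$ for diagonal steps
(compiled implementation). Circularity is then

$$C = \frac{4\pi A}{P^2},$$

1 for an ideal disk and smaller for elongated shapes; the same index is
reported as the 2D proxy of mitochondrial sphericity. On a rasterized disk
of 21 px diameter the estimator stays within 5% of the analytic value;
single-pixel contours are degenerate and circularity is reported missing
for them. Contours of very small objects (under roughly 10 px) remain
discretization-limited, which is why the minimum-area filters matter.

Contact metrics per cell: `overlap_pct` is the percentage of LD pixels
also covered by mitochondria pixels (a mitochondria-normalized variant is
switchable), and the per-LD minimal mitochondria distance is the exact
pixel-pair minimum (0 for overlapping objects), summarized per cell as the
mean over LDs, with the minimum also reported. Organelles are assigned to
the cell containing their centroid; centroids on background are rescued to
the nearest cell within 2 µm or dropped with a log message. Organelle
pixels are clipped to their cell for density and contact computation, so
density — organelle area fraction of the cell area — is bounded in
$[0, 1]$; a count-per-area column is exported alongside, since "density"
could reasonably mean either.

## Zonal signatures

Per-bin profiles are means, standard deviations and counts of every
feature over the cells of each bin (the spread of a single-cell bin is
reported as zero; empty bins are kept as missing rows and flagged). For
multivariate views the bins-by-features matrix is z-score standardized —
the variables mix units (µm², counts, percentages), so unstandardized
decompositions would be dominated by scale. PCA orientation is made
deterministic by forcing the largest-magnitude loading of each component
positive. Clustering is agglomerative with complete linkage on Euclidean
distances of the standardized values, the method used for the dendrogram
heatmaps. Condition correlations are Pearson; both layouts are produced —
bin-by-bin correlations of (within-condition standardized) feature vectors
and feature-by-feature correlations of bin profiles — because either
reading of "correlation of organelle features across conditions" is
defensible. Displayed values are rounded to two decimals; computations
keep full precision. The overlap heatmap reports mean percent overlap and
summed overlapping-pixel counts per bin and condition.

## Synthetic zonated lobules

The generator renders what the measurement model assumes: a single-axis
strip of hepatocytes between a PV strip (left) and CV strip (right),
250 µm apart at 0.2 µm/px, with 12–16 cells of jittered widths, 21 µm
strip height and 3 px actin boundaries. Per-bin target curves drive
placement: circular LDs whose rasterized pixel count is matched to the
bin's mean-area target by searching radius and subpixel centre; elliptical
mitochondria whose aspect ratio is calibrated at generation time against
the package's own circularity estimator (so the digital circularity, not
the analytic one, hits the target); total mitochondrial area filled to the
bin's density target within a few pixels. Contacts are realized by sliding
a mitochondrion toward its LD until 15–35% of the LD's pixels are covered;
non-contact organelles keep a 2 px clearance so uncontacted LDs have
strictly positive distances. Channels are constant background (0.05) plus
signal with additive Gaussian noise (sd 0.02 by default; 0 renders
noise-free images whose pixel counts equal the ground truth exactly).
Identical (spec, seed) pairs are bit-identical, and generation restores
the caller's RNG state.

The three presets encode the qualitative dietary contrasts: control chow
(CNTR) with LDs sparse and small periportally, rising sharply in bins
10–12, mitochondrial circularity falling and density rising toward the CV,
and contacts confined to bins 9–12; overnight fasting with high LD counts
and extensive contacts across bins 1–10 (tapering in 11–12) and uniformly
elongated mitochondria; Western diet with large periportal/mid-lobular LDs
shrinking pericentrally, more spherical mitochondria and a low, flat
contact fraction comparable to the pericentral level of controls. Curve
values are package choices representing these dietary contrasts at
realistic magnitudes (mitochondrial section areas around 2 µm², LD areas
0.8–3 µm², densities 8–18%).

What the generator does not emulate: irregular cell shapes beyond jittered
rectangles, intensity gradients within organelles, out-of-focus light,
photobleaching, vignetting, or marker-based axis orientation. Passing the
closure tests therefore demonstrates that the measurement pipeline is
faithful to its own geometric model, not that segmentation of real tissue
is solved — on real images the pluggable learned backend is expected to do
the heavy lifting.

## Moderated statistics

Raw abundance tables (for example multiplexed proteomics reporter
intensities) are normalized in two steps: columns are scaled to the mean
column sum (equal loading), then each feature in each batch is divided by
the batch's pooled-reference abundance, which removes multiplicative batch
effects and turns pooled columns into ones; log2 transformation follows
ratio formation. Quantile normalization maps within-column ranks to mean
order statistics with ties averaged. Precision weights for count data are
deliberately not implemented: the intensities modeled here are not counts,
and applying a count-based mean–variance trend would misstate their
uncertainty; quantile normalization on log2 ratios is the implemented
interpretation.

Row-wise ordinary least squares under a shared design matrix yields
contrast estimates (log2 fold changes), residual variances $s^2$ and
degrees of freedom $d$. Two contrast families cover the diet-by-genotype
workflow: within-genotype WD versus the CD mean, and the
difference-of-differences $(\mathrm{WD}-\mathrm{CD})_{g} -
(\mathrm{WD}-\mathrm{CD})_{\mathrm{Null}}$. Empirical-Bayes moderation
shrinks $s^2$ toward a prior: hyperparameters $(d_0, s_0^2)$ are estimated
by moment matching on $\log s^2$ (digamma/trigamma relations of the
scaled-F model; the trigamma inverse is solved by Newton iteration), and

$$s^2_\mathrm{post} = \frac{d_0 s_0^2 + d s^2}{d_0 + d}, \qquad
t = \frac{\hat\beta}{\mathrm{se}_u \, s_\mathrm{post}}, \qquad
t \sim t_{d + d_0} \ \text{under } H_0.$$

Fixing $d_0 = 0$ reproduces the ordinary t-test and $d_0 = \infty$ the
fully pooled test; the hyperparameters can be fixed explicitly for
verification. Multiple testing uses Benjamini–Hochberg step-up q-values.
Zonation calls combine the p-value (0.05) and linear fold-change (1.2)
thresholds; either conjunction of the two is defensible, so the rule is
switchable with AND — the stricter reading — as the default.
Significance stars are left to a configurable display map rather than
hard-coded, and q-values are always reported directly.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: empty vein regions and
overlapping landmarks are errors; zero axis length is an error; empty
label maps yield empty feature tables; constant features are dropped from
PCA with a warning; zero-variance vectors yield missing correlations with
a warning; features with zero pooled-reference abundance are flagged
missing per batch. The package's own validation runs at desk scale: 12
synthetic axes per condition (about 170 cells each cohort) for pipeline
closure, objects up to 64 px for the exhaustive feature oracles, and
simulations of 1,000–5,000 features for statistical calibration — sizes
chosen so the complete suite re-runs in minutes on a laptop while leaving
every code path exercised.

## Known limitations

2D sections proxy 3D morphology; the package reports section-plane
quantities only. The fallback segmentation is tuned to boundary-labelled
tissue strips and is not a substitute for a trained model on real
micrographs. Perimeter (hence circularity) carries estimator-specific bias
on objects near the minimum-area filters. The correlation and PCA
summaries treat bins as exchangeable samples and make no spatial
autocorrelation correction. Pathway-level interpretation of zonation calls
is out of scope.
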