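---
title: "Delineating and classifying canopy trees from aerial data: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating and classifying canopy trees from aerial data: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`canopyseg` implements a complete individual-tree workflow for tropical
canopies observed with very-high-resolution (VHR) RGB aerial imagery and
discrete-return LiDAR: canopy height modelling, crown delineation by two
competing segmentation paradigms, delineation scoring, texture-augmented
species classification, and nonparametric comparison against field
mensuration.  This vignette documents the models, their assumptions, the
tunable parameters, and the design decisions behind the implementation.

## The canopy height model

Vegetation height is modelled as `CHM = DSM − DTM`.  The digital surface
model (DSM) takes, per grid cell, the maximum elevation of all returns;
the digital terrain model (DTM) takes the mean elevation of
ground-classified returns.  Negative differences are clamped to zero
(heights are physical), and nodata propagates from either input.

Ground classification (`classify_ground()`) approximates the classic
linear-prediction ground filter by iterative locally weighted plane
fits.  A surface is seeded from per-cell lowest points on a coarse grid
(`seed_cell_m`, default 5 m).  Each iteration computes residuals
`r = z − surface` and weights

```
w = 1                          if r <= g
w = 1 / (1 + (a (r − g))^b)    if r >  g
```

with defaults `a = 1`, `b = 4`, `g = 0.05 m`, then refits a weighted
plane per coarse cell from the points of its 3×3 cell neighbourhood.
Returns far above the surface (vegetation) lose their influence
quickly — with `b = 4` a residual of 3 m already has weight below
1/80 — so the surface settles onto the ground.  Three iterations
(`n_iterations = 3`) suffice at the point densities treated here;
returns within `tolerance` (0.3 m) of the final surface are flagged
ground.  On a noiseless inclined plane every point is flagged ground
(the fits are exact); this is asserted in the tests.  The filter assumes
flat-to-moderate terrain: no slope-adaptive weighting is implemented,
and very steep terrain under dense canopy will bias the DTM upward.

Because ground returns under dense crowns are sparse, empty DTM cells
are filled from their nearest occupied neighbours (implemented as
iterative neighbour-mean dilation — for continuous ground surfaces the
difference from exact nearest-neighbour assignment is negligible), and
the gridded surface is smoothed with a 3×3 median filter
(`median_filter3()`), which removes the abrupt cell-to-cell jumps that
sparse seeding produces while never introducing values outside the
local data range.  Edge cells use the neighbours that exist; nodata
cells are excluded from windows and stay nodata.

## Crown delineation

### Multiresolution region merging

`multiresolution_segment()` implements bottom-up object building: every
unmasked pixel starts as a one-pixel object, and adjacent objects merge
while the cheapest merge stays below `scale²`.  The fusion cost of a
candidate merge is

```
f = w_color * Δh_color + (1 − w_color) * Δh_shape
Δh_color  = Σ_b w_b [ n_m σ_m,b − (n_1 σ_1,b + n_2 σ_2,b) ]
Δh_shape  = w_compact * Δh_compact + (1 − w_compact) * Δh_smooth
h_compact = l / sqrt(n)        (contribution n·h per object)
h_smooth  = l / b_bbox         (b_bbox = bounding-box perimeter)
```

where `n` is object size, `σ` the per-band standard deviation and `l`
the object perimeter.  These are the canonical region-merging
heterogeneity definitions for this family of segmenters, adopted here
because the paradigm is standard but rarely restated in applications.
Merges happen by *local mutual best fitting*: a pair merges only when
each object is the other's cheapest neighbour, with ties broken toward
the lowest label, making the algorithm deterministic.  The merge loop
is implemented in C++ (an adjacency graph with pooled sum/sum-of-squares
statistics per object), so a 400×400-pixel scene segments in well under
a second.

Defaults are `w_color = 0.9`, `w_compact = 0.5` and equal band weights.
The `scale` threshold is data-dependent by construction (it is compared
against an absolute heterogeneity increase); for 8-bit imagery of the
kind produced by the scene generator, `scale = 60` merges whole crowns
without crossing crown boundaries.  Before segmentation the scene is
masked to canopy (`mask` argument); we use `CHM >= 2 m`, which is
physically interpretable and independent of the imagery's brightness
calibration.  Bare ground is label 0 and is never segmented.

### Watershed

`watershed_segment()` treats smoothed brightness (or the CHM) as a
topographic relief: bright crown apexes become basin bottoms of the
inverted relief, basins shallower than `h_frac` of the dynamic range
are suppressed, and flooding assigns each surviving basin one label.
Smoothing is Gaussian (`gaussian_sigma_px`, default 2 px); the flooding
itself is delegated to `EBImage::watershed()`, with the package
providing masking, inversion/h-depth handling and label conventions.
With `input = "gradient"` the inverted Sobel gradient magnitude is
flooded instead.  Multiband input is reduced to mean brightness.

The two paradigms deliberately differ in failure mode.  On the smooth
paraboloid relief of a CHM, watershed at default parameters recovers
one segment per disjoint crown (asserted in tests).  On VHR *imagery*,
within-crown brightness variation creates many spurious maxima, and
watershed fragments crowns into small pieces whose widths are biased
low — the directional behaviour the acceptance suite reproduces with a
deliberately over-split run (`gaussian_sigma_px = 1`, `h_frac = 0.01`).
Region merging, which penalises spectral heterogeneity growth rather
than relying on radiometric maxima, keeps whole crowns together.

### Crown geometry and heights

`crown_metrics()` measures, per segment, the range of pixel-centre
projections on the two principal axes of the segment's pixel
coordinates, plus half a cell on each side; crown width is the mean of
the two extents — the airborne analogue of averaging two perpendicular
field-measured crown diameters.  Segments with equal principal
eigenvalues tie-break to the map axes so the metrics are deterministic.
Segments below `min_segment_px` (default 10 px, i.e. 2.5 m² at 0.5 m
cells) are discarded as noise objects.  `crown_heights()` assigns each
crown the maximum CHM value inside its segment — the "brightest pixel"
of the canopy height surface.  `match_to_field()` links field stems to
segments by containment first, then by nearest centroid within
`radius_m` (default 5 m), one-to-one, greedily by distance.

## Scoring delineations

Delineated crowns are scored against reference polygons with the
closeness index

```
D = sqrt(over² + under²),   accuracy% = 100 (1 − mean D)
over  = 1 − area(ref ∩ seg) / area(ref)
under = 1 − area(ref ∩ seg) / area(seg)
```

`over` measures the part of a ground crown its matched segment misses
(crown split across segments); `under` the part of the segment spilling
beyond the crown (segment spanning several crowns).  The area-ratio
formulation is one standard choice among several in the segmentation-
accuracy literature; it is isolated in `over_under()` so an alternative
definition can be swapped in.  Each reference polygon is matched to the
segment of maximal intersection area.  Intersections are computed on
the segment-map pixel grid (reference polygons are rasterised at the
map's resolution using an even-odd point-in-polygon test): exact when
reference and segment share the grid, and accurate to O(cell/width) —
well under a percent at 0.5 m cells for 8–25 m crowns — for smooth
polygons.  No polygon-clipping dependency is required.

## Texture features and feature ranking

`texture_bands()` computes, in a moving window (default 7 px, odd),
first-order occurrence features from the raw window values and the
quantized-level histogram (mean, variance, entropy in bits), and
second-order features from the grey-level co-occurrence matrix (GLCM):
contrast, angular second moment (ASM), co-occurrence entropy,
homogeneity, dissimilarity and correlation.  Grey levels are quantized
to `levels` (default 32) equal-width bins over the band's global range.
Pair counts are pooled over the four unit-direction offsets (and both
directions when `symmetric = TRUE`) into a single normalised matrix per
window *before* features are computed — this follows the operation's
contract and gives rotation-robust features with fewer bands; note that
pooling matrices is not identical to averaging per-direction feature
values for nonlinear features such as entropy.  Image edges use
mirrored padding.  No single window size is canonical; 7 px spans
roughly a third of a small crown at 0.5 m pixels and should be revisited
at other resolutions.

`gain_ratio_rank()` scores each candidate band by gain ratio,

```
GR = [H(class) − H(class | feature)] / H(feature)
```

after equal-frequency discretisation (default 10 bins), which makes the
ranking invariant under monotone rescaling of any feature.  Constant
features get weight 0; GR lies in [0, 1]; ties break alphabetically.
ASM and the entropies are near-monotone transforms of one another
(both measure GLCM concentration), so rankings among them can be close;
when a reduced candidate set is wanted, keeping entropy and dropping
ASM is the conventional de-duplication.

## Species classification

Two supervised per-pixel classifiers share the train/test protocol of
`split_samples()` (stratified random 70/30 by class, seeded).

**Maximum likelihood** (`train_ml()` / `classify_ml()`): per class a
Gaussian with mean `μ_c` and covariance `Σ_c`, discriminant
`g_c(x) = ln p(c) − ½ ln|Σ_c| − ½ (x−μ_c)ᵀ Σ_c⁻¹ (x−μ_c)`, argmax wins.
Priors default to equal — the choice a practitioner makes absent
abundance information — with training-frequency priors available.
Covariances are regularised by `ε·trace/dim` on the diagonal
(`ε = 10⁻⁶`), keeping them positive definite on small training sets.  A
minimum-probability threshold is expressed as a chi-square quantile on
the Mahalanobis term (df = dimension), a dimension-independent
formulation; pixels beyond it are left unclassified (label 0 /
`NA`).

**Spectral angle mapper** (`train_sam()` / `classify_sam()`): each class
is represented by its training-mean spectrum (median optional), pixels
take the class of minimum angle `acos(⟨x, r_c⟩ / (‖x‖‖r_c‖))`.  SAM
decisions are invariant to positive per-pixel scaling (illumination),
which ML decisions are not — both properties are asserted on random
inputs.  SAM discards all magnitude information, which is exactly why
it underperforms ML on classes that differ in brightness as well as in
spectral shape; the acceptance suite reproduces this ordering.

`accuracy_report()` produces the confusion matrix (rows = reference),
overall accuracy, Cohen's kappa from the marginals, and per-class
producer's (recall) and user's (precision) accuracy, reporting 0 for
classes never predicted.  Unclassified predictions count as errors in
`overall_accuracy`; `overall_accuracy_classified` excludes them from
the denominator; both are reported.

## Mensuration statistics

Field/airborne comparisons are deliberately nonparametric, since
residuals of such comparisons are typically heavy-tailed:

* `spearman_rho()`: midranks for ties, Pearson correlation of ranks,
  two-sided p by the t approximation (exact permutation enumeration
  available for n ≤ 8).
* `kruskal_wallis()`: rank-sum H with the usual tie correction; both
  the corrected and uncorrected statistics are reported because
  published values do not always state which variant was used; p from
  chi-square with k−1 df.
* `mood_median()`: 2×k table of counts above / not-above the grand
  median, Pearson chi-square without continuity correction.
  Observations equal to the grand median are dropped by default (one
  standard convention; `ties = "below"` counts them as below), and the
  per-group medians give the direction of any difference.
* `qq_points()`: ordered residuals against standard-normal quantiles at
  plotting positions `(i − ½)/n`, returned as a table, never
  auto-judged.

`compare_report()` bundles the battery such comparisons call for: rho
and RMSE per paired variable, Kruskal–Wallis and Mood across the
field / region-merging / watershed width samples with per-group
medians, pairwise Mood tests, and a per-species summary (mean ±
standard error, with SE = sd/√n, and rho).

## The synthetic scene generator

`generate_scene()` produces the three inputs every stage needs —
imagery, point cloud, ground truth — as a pure function of
`(params, seed)`.  Its defaults are the package's reference study
conditions: a 200 × 200 m stand, 25 trees of 5 canopy species, tree
heights 25–40 m, crown widths ~8–25 m, 0.5 m pixels, 12 returns/m²,
flat-to-gently-undulating terrain (slope 0.001, 0.2 m undulation over
an 80 m wavelength).  The 0.5 m desk-scale pixel (rather than a
centimetre-scale survey pixel) keeps tests tractable while exercising
identical algorithms.

Crowns are ellipses (axis ratio 0.8–1, random orientation) with
paraboloid caps: surface height `h − 0.35·h·ρ²` at normalised elliptical
radius ρ, so the CHM peaks at the crown centre, matching the
"brightest pixel" height-extraction assumption.  Crown width is defined
as the mean of the two axis lengths, the exact analogue of averaging
two perpendicular field diameters.  Stems keep a minimum spacing of
`min_spacing_factor` (default 1.1) times the mean of the two crowns'
major axes — disjoint crowns by default; values below 1 produce
overlapping canopies to stress segmentation.  Placement is by rejection
sampling with a deterministic retry ladder; an impossible configuration
raises an error naming the spacing constraint.

Crown pixels draw from the species' spectral distribution: per-band
mean (8-bit DN), white noise (`spectral_sd`), plus an additive
spatially correlated roughness field (Gaussian, correlation length
1.5 px, amplitude `roughness · 35` DN) emulating sunlit/self-shadowed
foliage clumps — rough canopies show broader, clumpier tonal
distributions at identical mean spectra.  One consequence documented
here deliberately: because roughness broadens the red-band marginal, a
Gaussian ML classifier retains partial (variance-based) separability of
a "texture-only" species pair on raw spectra — confusion is
substantial but not exactly at chance.  The texture-augmented tests
therefore assert substantial confusion plus a strict accuracy gain from
the top-ranked texture band, rather than exact chance-level confusion.
Bare ground is brighter than canopy (background 150/140/125 DN), and
imagery is quantized to 8-bit after adding sensor noise
(`noise_sd = 2` DN).

The point cloud has exactly `round(density·area)` returns at uniform
planimetric positions.  Pulses over a crown return from the crown
surface (σ = 0.10 m) except for a `canopy_gap_fraction` (default 0.15)
that penetrates to the ground and is recorded as return 2 — this is
what makes a DTM under canopy possible at all.  Ground returns follow
the terrain with σ = 0.03 m.

What the generator does **not** emulate — and hence what green tests do
not certify about real data: multi-layer canopies and understory,
crown-shape irregularity and gaps within crowns, anisotropic
illumination (BRDF) and shadows cast *between* trees, georeferencing
error between imagery, LiDAR and field positions, species-dependent
penetration rates, and steep terrain.  Real VHR scenes will need
scene-specific `scale`, masking and texture-window choices, and real
accuracy numbers will be lower than synthetic ones.

`truth_field_table()` adds independent Gaussian measurement error to
heights and widths (field protocols show low systematic but appreciable
random error) and derives DBH from a linear allometry in height and
crown width with lognormal-scale scatter; zero error sds reproduce the
truth exactly, which the tests exploit.

## Numerical choices and degenerate inputs

* All entropies use log base 2 (bits).  GLCM quantization is
  equal-width over the band range; gain-ratio discretisation is
  equal-frequency — the standard pairing.
* The GLCM `correlation` feature is defined as 1 when either marginal
  variance vanishes (constant window).
* Principal-axis ties in `crown_metrics()` (isotropic segments) resolve
  to the map axes; watershed labels are relabelled contiguously in scan
  order; the region-merging tie-break is the lowest label — all three
  make outputs deterministic.
* Constant images: watershed returns a single segment with a warning;
  Kruskal–Wallis on all-identical data returns H = 0 with a warning;
  Mood's test with a degenerate margin returns chi-square 0.
* Raster TIFF I/O stores bands min-max-normalised as float32 with a
  JSON sidecar (libtiff clips float samples outside [0, 1]); roundtrips
  are exact to ~1e-7 relative.  The ESRI ASCII writer is exact at
  printed precision.  Point clouds roundtrip below 1 mm.
* Coordinates are planar meters throughout; CRS strings are carried,
  never interpreted.  Pixel (1,1) is the top-left corner; pixel centres
  sit at `origin + ((c−½)·cell, −(r−½)·cell)`.

## Problem sizes

The test and acceptance workloads use the reference stand above
(400×400 px imagery, 480,000 returns) plus smaller 80 m stands for
property tests; the full pipeline on the reference stand (ground
filter → CHM → both segmentations → scoring → classification →
statistics) completes in well under a minute on one core, and the
entire test suite in a few minutes.

## Known limitations

Beyond the generator's realism limits listed above: the ground filter
is not slope-adaptive; region merging optimises a local (mutual best
fitting) criterion, so it does not globally minimise heterogeneity and
the scale threshold needs scene-specific calibration; segmentation
accuracy uses pixel-grid areas rather than exact polygon intersections;
LAS/LAZ point clouds are not read directly (ASCII XYZ CSV is the
interchange format); and classification is per-pixel — no object-based
majority voting over segments is implemented.
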