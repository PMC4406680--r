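# canopyseg

Individual tree crown delineation and species classification from
very-high-resolution (VHR) aerial imagery and discrete-return LiDAR,
written for forest-structure studies in mixed-species tropical canopies
— the setting where crown outlines are irregular, species are hard to
tell apart spectrally, and field access is limited, so airborne
measurements have to stand in for tape-and-clinometer mensuration.

The package covers the full workflow:

* **Canopy height model.** Ground returns are classified with an
  iterative linear-prediction-style filter (weights
  `w = 1/(1 + (a(r − g))^b)` on residuals above the evolving surface,
  locally weighted plane fits on a coarse grid, 3 iterations), gridded
  to a DTM (per-cell mean of ground returns, 3×3 median smoothed) and a
  DSM (per-cell maximum of all returns); `CHM = DSM − DTM`, clamped at
  zero.
* **Crown delineation** by two paradigms: *multiresolution region
  merging* — bottom-up pairwise merging by local mutual best fitting
  under the fusion cost
  `f = w_color·Δh_color + (1 − w_color)·Δh_shape`, stopped at `scale²` —
  and *watershed* flooding of the inverted (smoothed) brightness or CHM
  relief with h-minima suppression.  Per crown, width is the mean of
  the two principal-axis extents and height the maximum CHM value in
  the segment.
* **Delineation scoring** against reference polygons with the closeness
  index `D = sqrt(over² + under²)`, where
  `over = 1 − |ref ∩ seg|/|ref|` and `under = 1 − |ref ∩ seg|/|seg|`;
  accuracy is reported as `100·(1 − mean D)` percent.
* **Texture and feature ranking.** First-order (mean, variance,
  entropy) and grey-level co-occurrence (contrast, ASM, entropy,
  homogeneity, dissimilarity, correlation) bands in a moving window,
  ranked by gain ratio `GR = [H(C) − H(C|X)] / H(X)` after
  equal-frequency binning.
* **Species classification** per pixel by Gaussian maximum likelihood
  (`g_c(x) = ln p(c) − ½ln|Σ_c| − ½(x−μ_c)ᵀΣ_c⁻¹(x−μ_c)`) and by the
  spectral angle mapper (minimum `acos(⟨x, r_c⟩/(‖x‖‖r_c‖))`), with
  confusion-matrix reports: overall accuracy, Cohen's kappa, producer's
  and user's accuracy per class.
* **Mensuration statistics**: Spearman's rho, RMSE, Kruskal–Wallis
  (with and without tie correction) and Mood's median test, plus QQ
  tables for residual checks — the nonparametric battery for comparing
  airborne-derived with field-measured crown widths and tree heights.
* **A synthetic forest-scene generator** (imagery + point cloud +
  ground truth, a pure function of parameters and seed) so the whole
  pipeline is testable end to end without proprietary survey data.

See the methods vignette (`vignettes/canopy-workflow.Rmd`) for the
models, assumptions, parameter meanings and design decisions.

## Worked example

Simulate a 200 × 200 m stand of 25 canopy trees (heights 25–40 m,
crowns ~8–25 m) observed at 0.5 m pixels and 12 LiDAR returns/m²,
derive the CHM, delineate crowns, and compare against a simulated field
campaign (±1.5 m height, ±1 m width measurement error):

```r
library(canopyseg)

params <- scene_params(n_trees = 25, seed = 42)
scene  <- generate_scene(params)

wf  <- chm_workflow(scene$cloud, cell_size_m = 0.5,
                    geometry = list(origin = c(0, 200),
                                    nrow = 400L, ncol = 400L))
seg <- multiresolution_segment(scene$imagery, seg_params(scale = 60),
                               mask = wf$chm$bands[[1]] >= 2)
crowns <- crown_heights(crown_metrics(seg), seg, wf$chm)
head(crowns[, c("segment_id", "x", "y", "crown_width_m",
                "tree_height_m")], 3)
#>   segment_id         x         y crown_width_m tree_height_m
#> 1          1  9.792222  30.16778      8.791687      27.92598
#> 2          3 20.266820  93.11086     10.807139      36.12399
#> 3          5 26.439655 150.40709      9.757762      25.08258

field <- truth_field_table(scene$truth, height_error_sd = 1.5,
                           width_error_sd = 1, seed = 1)
m <- match_to_field(crowns, field, segmap = seg, radius_m = 5)

spearman_rho(m$crown_width_m, m$pred_crown_width_m)
#> <canopy_stat> spearman_rho = 0.9615  (p = 2.112e-14)
rmse(m$height_m, m$pred_tree_height_m)
#> <canopy_stat> rmse = 1.0415
```

So delineated widths track the noisy field widths at rho ≈ 0.96, and
LiDAR heights sit within ~1 m RMSE of clinometer-style measurements —
the residual being dominated by the simulated measurement error itself.
Scoring the delineation against the true crown outlines:

```r
refs <- truth_to_reference_polygons(scene$truth)
attr(evaluate_segmentation(refs, seg), "aggregate")
#> mean D = 0.053  (accuracy 94.7%)
```

A deliberately over-split watershed run shows the opposite behaviour —
its fragments are significantly narrower than the field crowns (Mood's
median test):

```r
ws <- watershed_segment(scene$imagery,
                        seg_params(gaussian_sigma_px = 1, h_frac = 0.01),
                        mask = wf$chm$bands[[1]] >= 2)
mood_median(list(field = field$crown_width_m,
                 watershed = crown_metrics(ws)$crown_width_m))
#> <canopy_stat> mood_chi2 = 25.9660  (p = 3.475e-07)
```

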