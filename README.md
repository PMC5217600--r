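# speckleflow

Laser speckle contrast imaging (LSCI) analysis for intraoperative cerebral
blood flow monitoring in rodent photothrombotic stroke experiments, with a
physically grounded dynamic-speckle simulator that provides ground truth
for every stage of the pipeline.

## What it does

In a photothrombotic stroke model, a focal clot forms in a branch of the
middle cerebral artery over ~15 minutes of laser illumination while the
cortex is imaged through a cranial window at 50 fps. `speckleflow`
implements the full quantitative chain from those raw speckle frames to
group statistics:

1. **Speckle contrast.** Per-pixel `K = sd/mean` over a sliding window
   (spatial estimator; a temporal estimator is provided for
   cross-validation), with flat-field correction of static reflectance
   and a coherence factor beta calibrated from a static acquisition.
2. **Flow inversion.** The single-exposure speckle model
   `K^2 = beta * { x + x^2/2 * (exp(-2/x) - 1) }`, `x = tau_c / T`,
   links contrast to the speckle correlation time `tau_c` for exposure
   `T`; the model is inverted per pixel (Newton, unique root) and
   relative flow is reported as `1 / tau_c`, assuming flow inversely
   proportional to correlation time.
3. **Motion correction.** Subpixel translational registration by FFT
   cross-correlation with a speckle-suppressing prefilter, iterative
   peak re-centering and two-pass alignment.
4. **Perfusion metrics.** Pixelwise baseline normalization
   `N(x,y,t) = CBF(x,y,t) / CBF(x,y,0)`; the hypoperfused area
   `CBF_50(t)` (ipsilateral pixels with an *over* 50% reduction,
   `N < 0.5`, in mm^2), the hyperperfused area `CBF_+(t)` (`N` above an
   enhancement threshold), and an occlusion-success check (over 85%
   regional decrease in the arterial ROI).
5. **Lesion volumetry.** Threshold planimetry of T2-like MRI stacks and
   TTC-stained section stacks: 3x3 Gaussian smoothing, per-slice
   threshold at 75% of the slice maximum, lesion area times slice
   thickness summed to a volume.
6. **Scores and statistics.** Neurological severity scores (0-18
   composite of motor 0-6, sensory 0-2, beam balance 0-6, reflex 0-4),
   group summaries as mean +/- SEM, Welch or pooled t tests,
   per-timepoint series comparison, and percent differences between
   group means.
7. **Simulation.** Dynamic speckle as band-limited complex Gaussian
   fields with AR(1) temporal decorrelation `exp(-dt/tau_c)` integrated
   over the exposure, occlusion scenarios with a growing reduced-flow
   territory of known area, static vessel-like reflectance for
   registration, motion injection, ellipsoidal lesion phantoms of known
   volume, and NSS cohorts -- so every downstream stage can be tested
   against planted truth.

`run_simulation()` / `run_analysis()` orchestrate a full two-group
(conscious vs anesthetized) experiment end to end; a thin command-line
wrapper lives at `inst/cli/speckleflow.R`.

## Worked example

Plant a 19.5 mm^2 hypoperfused territory (the conscious-group mean) in a
256 px scenario, render raw speckle, and recover the area through the
full contrast -> flow -> normalization -> threshold chain:

```r
library(speckleflow)

cfg      <- scenario_config(target_area_15min = 19.5, seed = 42)
beta_eff <- calibrate_beta(cfg, window = 7)   # static-target calibration
bins     <- render_time_bins(cfg, c(0, 8, 15))
flows    <- lapply(bins, function(b)
  contrast_to_flow(spatial_contrast(flatfield_correct(b)), beta = beta_eff))
ser <- area_time_series(flows[-1], flows[[1]],
                        hemisphere_mask(cfg$image_shape, "left"),
                        times = c(8, 15), pixel_pitch = cfg$pixel_pitch)
ser$cbf50
```

```
calibrated beta (7 px window): 0.882
<area_series> CBF_50, 2 bins
 time_min area_mm2
        8 10.65071
       15 19.42026
planted 15-min area: 19.50 mm^2
```

The hypoperfused area grows along the planted occlusion time course and
the 15-minute endpoint recovers the planted 19.5 mm^2 within half a
percent. The same session's volumetry and statistics:

```r
mri <- make_lesion_phantom(63.7, n_slices = 20, slice_thickness = 1,
                           pixel_pitch = 0.1, seed = 42)
lesion_volume(mri)
#> <lesion_result> 20 slices x 1 mm, total volume 64.19 mm^3

ttest_groups(c(21.1, 18.4, 19.9, 22.5, 17.2),
             c(12.8, 13.9, 11.2, 12.0, 14.1))
#> <group_comparison> Welch t
#>   a: 19.820 +/- 0.941 (n = 5)   b: 12.800 +/- 0.552 (n = 5)
#>   t = 6.4341, p = 0.0004939 *

percent_difference(63.7, 40.1)
#> [1] 58.9
```

A planted 63.7 mm^3 T2-hyperintense lesion is recovered within 1% by the
75%-of-maximum planimetry, and the percent-difference convention
(anesthetic group as denominator) reproduces the published derived
percentages exactly.

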