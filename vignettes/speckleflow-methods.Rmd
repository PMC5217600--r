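---
title: "Models and methods behind speckleflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind speckleflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(speckleflow)
```

`speckleflow` analyses laser speckle contrast imaging (LSCI) recordings
of rodent cortex during photothrombotic stroke induction, and simulates
such recordings with known ground truth. This vignette explains the
models the package implements, the parameters that matter, the numerical
choices made where the design was genuinely open, and what the synthetic
data do and do not establish about real recordings.

## The single-exposure speckle model

Coherent light scattered by moving red blood cells produces a speckle
pattern whose grains blur during a camera exposure: the faster the flow,
the shorter the speckle correlation time $\tau_c$ and the lower the local
contrast $K = \sigma / \langle I \rangle$. For an exponential field
autocorrelation (Lorentzian spectrum), the squared contrast over an
exposure $T$ is

$$K^2 = \beta\left\{ x + \frac{x^2}{2}\left(e^{-2/x} - 1\right)\right\},
\qquad x = \tau_c / T,$$

rising monotonically from $\beta x$ (fast flow) to $\beta$ (static
scatterers). $\beta \in (0, 1]$ is an instrumental coherence factor
(detector-to-speckle size ratio, polarization). `speckle_k2()` evaluates
this forward model with an asymptotic series beyond $x = 10^3$, where the
direct expression cancels catastrophically; `invert_contrast()` solves it
for $\tau_c$ by a damped Newton iteration in $\log x$ (the model is
strictly increasing, so the root is unique; convergence is to $10^{-9}$
relative, typically in four to six iterations). Inversion at $K^2 \ge
\beta$ returns an `Inf` sentinel ("clipped": no resolvable motion) and
non-positive contrast returns `NA`; maps are processed despite bad
pixels, never aborted.

Relative flow is reported as $1/\tau_c$ in arbitrary units, on the
assumption that flow speed is inversely proportional to the correlation
time. Only ratios to a pre-stroke baseline are interpreted downstream;
no absolute velocity calibration is attempted.

## Contrast estimation and the effective beta

`spatial_contrast()` computes `sd/mean` over an odd sliding window
(default 7 px, the usual LSCI compromise between spatial resolution and
estimator variance at 640-px-class sensors) using an integral-image box
filter; the border where the window does not fit is flagged invalid and
excluded from all downstream area sums. Multi-frame bins are averaged in
$K^2$, not $K$: the estimator noise distribution varies with flow level,
so averaging in $K$ would add a flow-dependent Jensen bias that no single
calibration constant could absorb, whereas in $K^2$ the finite-window
losses stay multiplicative.

Two window effects depress measured contrast below the ensemble value:
neighbouring pixels within a window are correlated (the speckle grain
spans ~2 px), and the per-window mean is itself estimated. Both act as a
nearly constant factor on $K^2$, which is exactly what $\beta$ already
represents -- so the package treats them as part of an *effective* beta.
`estimate_beta()` measures it as the mean $K^2$ plateau of a static
(frozen-speckle) acquisition taken with the same optics and analysis
window; `calibrate_beta()` renders that acquisition for a simulated
configuration from independent static patterns (a single pattern has only
as many degrees of freedom as speckle grains and estimates the plateau to
no better than a few percent). With a 7 px window on 2 px speckle the
effective beta is about 0.88.

`temporal_contrast()` (per-pixel `sd/mean` across frames) is an
independent estimator used to cross-validate the spatial one; on
stationary uniform speckle the two agree within estimator noise.

## Flat-field correction

Real cortex is not uniformly reflective: vessels and tissue modulate the
mean intensity. Within a contrast window that modulation masquerades as
speckle variance. `flatfield_correct()` divides every frame by the
smoothed temporal mean of its stack (sigma = 2 px by default -- above the
speckle grain, below vessel scale), the standard flat-field step of
speckle flowmetry. The same correction is applied inside
`calibrate_beta()`, so residual anatomy leakage is absorbed consistently.
With the simulator's default anatomy (30% amplitude at 6 px correlation
length) the residual bias on normalized-flow plateaus measures a few
percent, well inside the tolerances of the recovery tests.

## Motion correction

The cranial window is fixed to the skull, so in-plane translation
dominates animal motion; no rotation or deformation is modelled.
`estimate_shift()` maximizes the FFT cross-correlation of mean-subtracted
frames. Because fully developed speckle decorrelates completely between
frames at 50 fps, frame-to-frame registration locks onto the *static*
anatomy, and a Gaussian prefilter (default sigma 2.5 px in
`align_stack()`) suppresses the decorrelated speckle that otherwise acts
as noise. The subpixel stage fits a least-squares paraboloid to a 5x5
patch around the peak and then iteratively re-centres the moving image by
the current estimate -- at convergence the peak sits on the grid origin,
where the fit is symmetric and the classic pixel-locking bias vanishes.
For static scenes (`prefilter = 0`) the sharp speckle autocorrelation
peak itself is the signal and a three-point parabola per axis is used
instead. `align_stack()` runs two passes by default: frames aligned in
pass one are averaged into a speckle-suppressed reference for pass two,
roughly halving the residual. On simulated jitter up to 5 px the residual
is below 0.3 px per frame.

Subpixel translations themselves (`translate_image()`, also used by
`inject_motion()`) are Fourier phase ramps: the simulator's images are
band-limited by construction, so sinc interpolation is exact, round trips
restore the input to machine precision, and integer shifts reduce to a
circular roll. The boundary is circular; shifts are restricted to less
than 10% of the image size.

## Perfusion metrics

`normalize_to_baseline()` divides each flow map pixelwise by the
pre-stroke baseline map, guarding against division by baseline pixels
below 1% of the baseline median. The hypoperfusion statistic is the area
of ipsilateral pixels with an *over* 50% reduction -- `N < 0.5` strictly,
so exactly 50% is excluded -- converted to mm^2 as pixel count times
pitch squared. The hyperperfusion area counts `N` strictly above an
enhancement threshold whose default, 1.2, imposes a 20% margin: a
threshold of exactly 1 would classify half of all noise-limited pixels as
enhanced. The margin is exposed as configuration because no canonical
value exists for it.

Occlusion success requires an over-85% decrease of the mean normalized
flow over the monitored arterial ROI; the check is computed as
`(1 - mean(N)) > criterion` so the strict boundary is float-exact. The
ROI-mean formulation (rather than per-pixel counting) was chosen as the
natural reading of a regional flow criterion. In the orchestrated
pipeline animals failing the check are excluded from group statistics
with a logged reason.

The hemisphere mask defaults to a half split at the image midline; real
analyses would supply a drawn mask, and the functions accept any logical
matrix.

## Lesion and infarct volumetry

Slices are smoothed with a normalized 3x3 Gaussian (sigma 1 px, mirrored
borders) and thresholded at 75% of the *per-slice* maximum; lesion volume
is the sum of per-slice masked areas times the slice thickness. The rule
is scale-invariant (any global intensity rescaling cancels) and treats
the analysed channel's bright class as lesion -- T2 hyperintensity for
MRI-like stacks, pallor for TTC-like sections (`infarct_volume()`, 3 mm
sections by default).

Two limitations of the relative threshold are worth knowing. On a slice
with no lesion at all, 75% of the background maximum falls inside the
background noise and the rule selects a large spurious area; the phantom
generator therefore always spans the planted ellipsoid across the full
slice range, matching practice (the slices analysed are the
lesion-containing ones). And when a slice's lesion cross-section shrinks
to about a pixel, smoothing pulls its peak below `background/0.75` and
the rule fails similarly -- a 10 mm^3 lesion is recoverable in a 7 x 3 mm
geometry but not as a full-span ellipsoid in a 20 x 1 mm stack. Recovery
across planted volumes of 10-64 mm^3 in resolvable geometries is within
a few percent.

## Scores and statistics

NSS records hold the four category scores (motor 0-6, sensory 0-2, beam
balance 0-6, reflexes/abnormal movements 0-4; total 0-18, higher is
worse); `nss_total()` validates bounds, sums categories per
examiner/trial record and averages. Group values are summarized as mean
+/- SEM (sample sd over sqrt(n)). `ttest_groups()` defaults to the Welch
unequal-variance test -- the safer default when only "t test" is
specified -- with a pooled-variance option; degenerate zero-variance
inputs follow fixed conventions (equal means: t = 0, p = 1). Area time
series are compared bin-by-bin with no multiple-testing correction by
default, matching how such series are conventionally reported, with a
Bonferroni toggle. `percent_difference()` uses the second (anesthetic)
group as denominator and rounds to one decimal; this convention uniquely
reproduces all three published derived percentages (58.9, 28.3, 46.9)
from the printed group means.

## The simulator

Speckle fields are circular complex Gaussian processes synthesized
directly on a disc-shaped Fourier support whose cutoff sets the grain
size (default 2 px, keeping the grain Nyquist-sampled); fully developed
speckle statistics hold by construction. Temporal decorrelation is an
AR(1) field evolution with per-pixel coefficient $\exp(-\delta t /
\tau_c)$ -- the discrete realization of the exponential field
autocorrelation assumed by the contrast model -- and a camera frame
averages $|E|^2$ over `n_substeps` sub-intervals of the exposure
(default M = 64; the renderer refuses $T/\tau_c > M/4$, where
discretization error would be visible, with an "undersampled-integration"
error). Inter-frame gaps are carried in a single exact AR(1) step, so
static speckle stays frozen across frames and fast speckle decorrelates
fully. Measured contrast matches the closed-form model within ~1%
across $\tau_c/T$ from 0.05 to 100. A beta below one is emulated by
affine contrast scaling of the intensity ($I' = 1 + \sqrt\beta(I-1)$,
clamped at zero), which reproduces the model's beta scaling exactly
without simulating its optical origins.

The occlusion scenario plants a disc of reduced flow (residual fraction
0.05 by default -- the near-zero core flow of a complete photothrombotic
occlusion, comfortably beyond the 85% occlusion criterion) whose area
follows a monotone growth curve reaching the configured target at 15
minutes, emulating clot formation over the illumination period. The disc
radius is solved by bisection so the rasterized pixel count matches the
requested area within one perimeter ring; when the target forces the
disc against the hemisphere midline it is clipped and the radius enlarged
so the clipped count still matches. Requests exceeding the hemisphere
raise "scenario-overflow". Baseline $\tau_c$ defaults to 1 ms (with the
5 ms default exposure, a baseline contrast near 0.4, typical of cortical
LSCI); pixel pitch defaults to the 7 mm cranial-window width divided by
the image width; exposure defaults to 5 ms within the 50 fps frame
interval. A static reflectance field (30% amplitude, 6 px correlation,
fixed by the scenario seed) multiplies every frame: it is what makes the
frames registrable, as vessel structure does in real recordings.

Lesion phantoms are ellipsoids of planted volume in noisy uniform
background (per-slice geometry as configured, in-plane axes solved by
bisection to match the volume within a voxel shell). NSS cohorts draw a
latent severity per rat, add examiner/trial noise, and decompose each
rounded observation into integer category scores by largest-remainder
allocation under the category caps, so bounds hold by construction.

Everything is seed-deterministic: identical configuration and seed
reproduce identical outputs bit for bit, and the analysis path contains
no randomness at all (the beta calibration uses fixed internal seeds).

## What the synthetic data do not show

The simulator establishes that the pipeline recovers known truth under
its own forward model. Real recordings differ in ways the phantoms do not
emulate: vascular (not disc-shaped) territory geometry, flow
heterogeneity and penumbra gradients rather than a two-level flow map,
physiological fluctuations and pulsatility, shot and read noise, partial
out-of-plane motion, and MRI/TTC image formation beyond an intensity
contrast. Passing the recovery tests therefore validates the analysis
chain's correctness and calibration, not the biological fidelity of any
particular scenario. The disc geometry in particular is an arbitrary
stand-in; pipeline correctness does not depend on it.

## Orchestration and problem sizes

`run_simulation()` writes a two-group dataset to disk (per-rat speckle
bins as 16-bit TIFF with JSON sidecars, MRI volumes as NIfTI with voxel
geometry in the header, TTC stacks as TIFF + JSON geometry, NSS tables as
CSV, per-rat truth and a manifest as JSON); `run_analysis()` reads it
back and produces the full group report (areas, occlusion flags, volumes,
NSS, t tests, per-timepoint p values, percent differences, every
threshold echoed for provenance). Per-minute analysis bins are
represented by short bursts of frames with the phantom frozen at the bin
time -- contrast statistics converge with tens of frames, so full-rate
rendering between bins would add cost but no information. Default group
structure is 11 + 11 animals with recording to 25 minutes post occlusion;
the test suite and acceptance runs use scaled-down scenes (96-256 px,
6-24 frames per bin, 2-15 mm^2 territories) chosen so that each check's
measurement precision comfortably resolves its tolerance.
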