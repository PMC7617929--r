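---
title: "Methods: motility tracking and symbiosis assay analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motility tracking and symbiosis assay analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(rhizotrack)
```

rhizotrack re-implements, as tested reusable code, the computational analyses
behind a *Rhizobium leguminosarum* bv. *viciae* 3841 motility and symbiosis
study: single-cell capillary video tracking (swimming speed and tumble rate),
swimming-halo dose-response modelling, flow-cytometry gating of nodule
contents into undifferentiated bacteria versus bacteroids, and counting of
stained nodules in root photographs. The raw videos and photographs behind
such studies are rarely deposited, so every stage is validated against a
synthetic-data generator that reproduces the statistical structure each
analysis assumes, with known ground truth. This vignette records the models,
the parameter choices that matter, and the design decisions taken where the
methods were genuinely open.

## The run-and-tumble generative model

`simulate_tracks()` implements the minimal standard planar run-and-tumble
model:

* Each cell has a constant intrinsic speed drawn from
  Normal(`mean_speed`, `speed_sd`), truncated below at 10% of the mean
  (speeds near zero are debris, not swimmers).
* Between tumbles the heading performs rotational diffusion with variance
  `rot_diffusion / fps` per frame interval. The default
  `rot_diffusion = 0.062` rad^2^/s is the classic value measured for
  swimming bacteria during runs; at 10 frames/s it contributes a heading
  jitter of about 4.5 degrees per interval.
* Tumbles arrive as a Poisson process at `tumble_rate`. A tumble redraws the
  heading — uniformly on the circle when `tumble_angle_spread = 0` (the
  default), or with a von Mises spread around the current heading — and is
  recorded as a ground-truth event. Tumbles are instantaneous: at 10
  frames/s a ~0.1 s pause is unobservable, so no pause phase is modelled.
* The field of view is absorbing: a cell whose next position falls outside
  has its record truncated at the exit frame, exactly as a camera loses it.
  The simulation is 2-D; out-of-plane loss in a real capillary is subsumed
  into the same truncation.

Not modelled, deliberately: hydrodynamic interactions, cell-cell collisions,
3-D capillary geometry, photobleaching, and shot-noise camera statistics.
These all matter for real recordings and none of them is exercised by the
recovery tests below — passing those tests shows the measurement chain is
unbiased for this generative model, not that it is robust to everything a
microscope can produce.

The wildtype generative parameter sets used throughout
(`rlv_motility_params()`) are the published per-condition statistics: mean
speed 44, 38 and 41 um/s (SD 7, 6, 7) and tumble rate 0.11, 0.14 and 0.08
events/s on glucose, pyruvate and succinate respectively.

## Rendering

`render_video()` draws each in-view cell as an isotropic Gaussian spot
(`psf_sigma` = 1.5 px, peak `spot_amplitude` = 6000 counts) on a constant
background (1200 counts) with additive Gaussian read noise (`noise_sd` = 600
counts), quantized to 16-bit integers. The defaults give a peak
signal-to-noise of 10:1, typical of bright-field bacteria at 40x. The
calibration default of 0.2 um/pixel is plausible for a 40x objective on a
1440 x 1080 sensor; it is an explicit configuration value everywhere, never
assumed. Stacks round-trip bit-exactly through 16-bit multi-page TIFF with a
JSON sidecar carrying `fps`, `pixel_size_um`, dimensions and seed.

## Spot detection

`detect_spots()` follows the de-facto standard chain for near
diffraction-limited particles: large-scale background smoothing (Gaussian,
scale `4 * bandpass_high`) and subtraction; difference-of-Gaussians band-pass
at (`bandpass_low` = 1, `bandpass_high` = 3) px; thresholded local maxima
with a `min_separation` = 5 px exclusion radius (equal-intensity ties keep
the smaller (y, x) — determinism); intensity-weighted centroid refinement in
a 7 px window. Coordinates are 0-based, pixel centres at integers, x =
column, y = row.

The default `threshold` = 1200 counts is derived from the noise model: white
read noise of 600 counts has a band-passed standard deviation of ~143
counts, while a default spot's band-passed peak is ~2950 counts; 1200 sits
at ~8 sigma of noise and ~2.5x below signal, so false maxima are negligible
and detection efficiency is effectively 100%. (At permissive thresholds the
noise maxima do link into spurious tracks, which corrupts every downstream
statistic — the threshold is a load-bearing default.) Measured localization
accuracy on rendered spots is < 0.01 px RMSE noiseless and ~0.18 px at the
default 10% noise.

## Track linking

`link_detections()` solves each frame-pair correspondence as an optimal
assignment: minimise the summed squared displacement over matched pairs,
plus `(max_disp * gap)^2` for every unmatched track head and `max_disp^2`
for every unmatched detection, with pairs beyond the gate forbidden. Because
any allowed match is cheaper than leaving both ends unmatched, the optimum
is a maximum-cardinality matching of minimal squared displacement. The
solver is an O(n^3) shortest-augmenting-path assignment on the augmented
square cost matrix (compiled); a brute-force enumeration oracle in the test
suite confirms exact optimality on random gated instances. The default gate
`max_disp = ceil(1.5 * mean_speed / fps / pixel_size)` (33 px under the
defaults) is derived from configuration, never hard-coded.

Unmatched tracks persist `memory` = 1 frame and then terminate; bridged
frames are linearly interpolated and flagged `is_gap`. `filter_tracks()`
then drops tracks shorter than 10 frames (1 s at 10 fps) and tracks with net
displacement under 5 px (immobile debris).

**Contested assignments.** Position-only linking (no motion model — a
deliberate non-goal) cannot distinguish two cells that pass within a gate
radius of each other: whenever the swapped pairing has lower squared cost,
identities exchange and both tracks acquire a sharp kink. On simulations
these forged kinks produced false tumble events at ~0.1/s at realistic
densities — the same order as the true tumble rates — while single-cell
fields produced none. Linking therefore flags every match that had an
alternative in-gate candidate on either side (`is_contested`), and the
tumble detector censors those intervals exactly as it censors
gap-interpolated ones. The speed estimate in `track_metrics()` likewise
excludes contested steps. This is standard measurement hygiene: ambiguous
encounters are discarded, not guessed.

## Tumble detection and rate estimation

`detect_tumbles()` flags trajectory vertices whose turning angle exceeds
`turn_threshold`, optionally requiring an instantaneous speed drop
(`speed_drop_fraction`; default 0 because simulated tumbles are
instantaneous redraws with no pause — enable it for real data). Flagged
vertices closer than `min_run_frames` = 3 merge into one event at the frame
of maximal turning.

Two defaults need justification:

* `smooth_window = 1` (no position smoothing). A centred window-3 moving
  average rounds a single-frame corner across two intervals: a true 90
  degree reorientation yields a maximum per-interval turn of ~37 degrees.
  At 10 frames/s smoothing therefore destroys the very signal the detector
  needs; it remains available for noisier, higher-rate real data.
* `turn_threshold = 15` degrees, set at ~3 sigma of the per-interval heading
  jitter during runs (sqrt(0.062 / 10) = 4.5 degrees from rotational
  diffusion, plus ~1.3 degrees from localization noise at default SNR).
  The trade-off is explicit: false events from run jitter occur at
  ~2 * pnorm(-threshold / sigma) per interval (~0.01/s at 15 degrees),
  while genuine tumbles with |reorientation| below threshold are invisible
  — a fraction threshold/180 (~8%) under uniform reorientation. Raising
  the threshold buys little (jitter false positives are already rare) and
  costs detection linearly.

**Exposure, not duration.** A rate needs a denominator of time in which an
event *could have been observed*. A track of m points has m - 2 interior
vertices at which a turn is measurable; vertices adjacent to gap-interpolated
or contested intervals are censored. `track_metrics()` therefore reports
both the raw span (`duration_s`) and the analysable exposure (`exposure_s` =
usable vertices / fps), and computes `tumble_rate_per_s` over the exposure.
Using the raw span would bias the rate low by the censored fraction plus one
edge interval per track (5-10% under the default geometry).

**Population estimate.** `summarize_population()` reports the
exposure-weighted mean of per-track rates — equal to pooled events over
pooled exposure — rather than the unweighted per-track mean. The reason is a
selection effect inherent to absorbing fields of view: a cell that tumbles
turns, and a cell that turns stays in view longer, so track exposure and
tumbling are positively coupled. Conditioning on a short track selects
ballistic, tumble-free crossings. On simulations at the default geometry the
unweighted mean came out ~35% below truth while the pooled estimate matched
the predicted detection fraction; binned by exposure, sub-0.5 s tracks
carried essentially zero events. The per-track SD is still reported as the
dispersion measure, and is strongly zero-inflated (SD > mean) whenever rate
x exposure < 1, as expected for per-track presentations of rare events.

With these choices the end-to-end pipeline recovers generative speeds within
~2% and tumble rates within ~10-20% (dominated by the sub-threshold miss
fraction) across the three published parameter sets — inside the 5% and 25%
recovery targets the package tests enforce.

## Problem sizes

Recovery runs simulate independent 512 x 512 px fields ("batches") of 12
concurrent cells for 3 s each. At 0.2 um/px the field is ~102 um across, so
a 44 um/s swimmer resides ~1 s; 12 cells per field keeps close encounters —
and hence contested censoring — limited. The test suite uses 120 batches
(1440 swimmers) per condition; the acceptance script uses 200 batches (2400
swimmers, roughly 2400-2700 kept track-seconds) for the conditions carrying
tumble-rate targets and 60 for the speed-only condition.
At these sizes the Poisson standard error of a pooled tumble rate is ~5% and
the standard error of a mean speed is ~0.2%.

## Halo dose-response models

`fit_four_pl()` fits the standard four-parameter log-logistic
f(x) = c + (d - c) / (1 + exp(b (ln x - ln e))) by Levenberg-Marquardt least
squares, with d initialized at the largest per-concentration mean, c at the
smallest, e at the geometric mid-concentration, and the slope multi-started
over b in {±0.5, ±1, ±2}; e is optimised on the log scale so it stays
positive. The sign convention makes b > 0 mean "diameter decreases with
concentration", matching halos shrinking at higher carbon. Parameter
confidence intervals are curvature-based (delta method for e) and therefore
approximate — adequate for ribbons, not for formal inference.

"Linear where appropriate" is operationalized as selection by small-sample
corrected information criterion with Gaussian likelihood from the RSS
(k = 5 for the 4PL including the error variance, k = 3 for the line), ties
and non-converged sigmoids falling back to the line. On 500 noisy linear
simulations the sigmoid is falsely selected in well under 10% of runs. The
non-motile baseline is the control-strain mean + 2 SD — a simple, explicit
operationalization of "maximum non-motile diameter". Replicates are treated
as independent; plate-level random effects are out of scope.

## Cytometry gating

Instrument-software gates are replaced by explicit, reproducible parameters:
a fluorescence threshold separating constitutively labelled cells from
debris, then a linear boundary `a * fsc + b * ssc >= c` (a, b >= 0) whose
upper-right side is the bacteroid class — bacteroids are larger (forward
scatter) and more granular (side scatter) than undifferentiated bacteria.
Boundary equality deterministically goes to the bacteroid side.
`collect_events()` mirrors the acquisition rule of reading until 5000
reasonable (finite, non-negative) events. `summarize_nodule_sample()` scales
class counts to cells per gram:
count x dilution x (resuspension / analysed volume) / nodule mass. Event I/O
is plain CSV; native cytometer binary formats, compensation and automated
gate learning are out of scope.

## Nodule counting

`segment_nodules()` thresholds in hue/saturation/value space (hue ranges may
wrap for magenta stains), applies morphological closing (disc radius 2 px),
labels 8-connected components, optionally splits touching blobs by watershed
on the distance transform, and keeps regions with area in
[`min_area`, `max_area`]. Two presets ship for the two stains used on
doubly-marked roots: `"xgal"` (blue-green) and `"magenta"`. The synthetic
root images place non-merging stained ellipses (centre separation >= 1.5x
the maximal radius) on a textured root-coloured background; on 100 such
images the count is within 1 of truth in >= 95%. Touching-nodule clumps
beyond pairwise overlap, colour deconvolution of double stains on one root,
and root-architecture tracing are not attempted.

## Numerical and degenerate-input conventions

* All generators accept a `seed` and are bit-reproducible; `NULL` leaves the
  caller's RNG untouched (generation runs under a locally restored seed).
* Flat halo responses return a flagged degenerate fit rather than an error;
  fewer than 5 distinct concentrations returns a non-converged 4PL with an
  explanation (the linear model then wins selection by construction).
* 4PL convergence: relative function tolerance 1e-10, up to 200 iterations
  per start; the best-RSS converged start wins.
* Assignment ties in linking are broken by the deterministic order of the
  augmenting-path solver; detection ties by (y, x) order.
* Empty inputs (blank frames, empty stacks, zero-event samples, zero-nodule
  images) produce empty, correctly-typed results, with warnings where a
  result row is still emitted.

## Known limitations

* The tumble detector's accuracy budget assumes the generative model's
  uniform reorientation; distributions concentrated at shallow angles would
  raise the miss fraction and the 25% recovery bound would not hold.
* Contested-interval censoring discards exposure near encounters; at
  densities far above ~1 cell per (3 x gate)^2 the surviving exposure and
  the speed estimate both degrade.
* Per-track tumble SDs mix Poisson counting noise with true between-cell
  variability; the package reports, but does not decompose, them.
* The halo CIs ignore parameter-transform curvature beyond the delta method
  and any replicate correlation.
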