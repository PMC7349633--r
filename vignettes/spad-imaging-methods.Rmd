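---
title: "Methods: multispectral plant segmentation and SPAD mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multispectral plant segmentation and SPAD mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spadspec)
```

`spadspec` turns 25-band spectral image cubes of a field crop into
per-pixel SPAD (leaf greenness) maps. This vignette records the models
the package implements, the assumptions they rest on, and the numerical
and design choices made where the procedure left room.

## Sensor model and data layout

The reference imager is a snapshot-mosaic sensor: a 5×5 tile of spectral
filters repeats across the pixel grid, so one raw frame interleaves 25
bands between 666 and 945 nm (two of them adjacent but distinct, at 887
and 888 nm; bands are therefore always addressed by *exact* wavelength).
`mosaicToCube()` de-interleaves a raw frame; each band image is 1/5 of
the raw resolution in each direction (409 × 217 for the reference
sensor) at 10-bit grayscale. The tile-position→band assignment is not
fixed by the sensor documentation we model, so the profile defaults to
row-major order within the tile and can be overridden in the profile
file. Coordinates are row-major with origin at the top-left; indices
follow R's 1-based convention.

## Reflectance calibration

Both grayscale and reflectance are linear in radiance, so a per-band
affine map `R = a·G + b` suffices, fitted by ordinary least squares on
the four panels of a standard board (nominal reflectances 1.0, 0.75,
0.5, 0). Assumptions: panels are Lambertian and uniform within the
averaged rectangles, and illumination is constant between board capture
and scene capture (drift compensation — re-calibrating on a cadence — is
the acquisition system's concern, not this library's; one model per cube).
Calibrated reflectance is **not clipped**: small negatives occur when
`b < 0` and clipping them would bias masked means. They are preserved,
counted and reported.

## Segmentation: MDVI–OTSU–CDL

The modified difference vegetation index `MDVI(α) = I_888 − α·I_681`
exploits the sign structure of vegetation spectra: chlorophyll
absorption keeps red reflectance low while leaf structure keeps the NIR
plateau high, so plants score positive. Spectrally flat materials (soil,
polyethylene mulch film, the board) score `R·(1 − α)`, increasingly
negative as α grows; α trades background suppression against erosion of
dimmer leaf pixels. The default α = 2.5 is the operating point selected
for field potato scenes; `alphaSweep()` re-evaluates the canonical
candidate list 0.5–3.0 against a reference mask.

Numerical choices, in pipeline order:

* **Rescaling.** Otsu thresholding needs a discrete histogram, and the
  index is real-valued (and partly negative), so it is min–max rescaled
  to 256 integer levels (the 8-bit convention), rounding half-up
  (`floor(x + 0.5)`; R's `round()` is banker's rounding and would break
  the half-up contract). A constant index image is flagged rather than
  rescaled.
* **Otsu.** Exhaustive maximization of the between-class variance over
  thresholds 0..254 via cumulative histogram sums; ties take the lowest
  threshold; foreground is *strictly greater* than the threshold (plants
  sit at the top of the index range). A constant image is a degenerate
  error.
* **Median filter.** 3×3 binary median (majority vote) with edge
  replication; the window size is a free parameter (odd, ≥ 3) since the
  procedure fixes none. A single pass is applied — idempotence is not
  assumed, only regression-tested on fixtures.
* **Connected-domain labeling.** Components of the pixel-adjacency graph
  (8-connectivity default, 4 available) are found via `igraph`; only the
  maximal-area domain is kept. Equal-area ties keep the domain whose
  first pixel in raster order comes first, making the stage
  deterministic. This stage is what removes weeds and neighboring
  plants, which are spectrally indistinguishable from the target; its
  documented failure mode is a weed patch larger than the plant, which
  wins the area contest (covered by a test).
* **Stage order.** Segmentation runs on the *calibrated* cube in the
  pipeline (correction precedes plant extraction in the processing
  order); the chain itself is value-kind agnostic and can be run on raw
  grayscale cubes directly.

Accuracy is intersection-over-union against a reference mask, in
percent. The reference mask is any file the user supplies; the package
does not model how it was drawn.

## Chemometrics

**SPXY split.** Calibration/validation partitioning maximizes coverage
of the joint predictor–response space: Euclidean distances in X and in y
are each divided by their maximum and summed; the most distant pair
seeds the calibration set and the sample maximizing its minimum distance
to the set is added until the set holds `ceiling(n·cal/(cal+val))`
samples. The ceiling makes a 100-sample table split 67/33 at the default
2:1 ratio. Selection depends only on distances, so permuting the input
rows relabels but does not change the chosen points (up to exact ties,
which are broken by index).

**PLS1.** Mean-centered NIPALS with a single response; predictors are
not autoscaled by default because reflectances share one scale (a flag
enables autoscaling). The latent-component count is chosen by
leave-one-out RMSECV, ties toward the smaller count, bounded by
`min(n − 1, p, 15)`. One NIPALS pass per left-out sample yields the
whole component path, so LOOCV costs n fits, not n·k. At full rank the
collapsed coefficients reproduce ordinary least squares (tested against
the normal equations at 1e-8).

**UVE.** The procedure this package models prescribes judging each
wavelength by the stability of its PLS regression coefficient, with a
fixed reliability-index cutoff of 1.0 — but not how the index is
computed. We jackknife: refit with each calibration sample left out,
collect the coefficient vectors `b⁽ⁱ⁾`, and set

&nbsp;&nbsp;&nbsp;&nbsp;`RI_j = mean_i(b⁽ⁱ⁾_j) / ((n − 1) · sd_i(b⁽ⁱ⁾_j))`

i.e. the mean coefficient over the standard deviation of its jackknife
*pseudo-values*. The naive ratio `mean/sd` over leave-one-out values
grows like `√n` times a t-statistic (leave-one-out estimates differ only
by single-sample influences), so a fixed cutoff would select everything
at realistic n; the pseudo-value scaling is sample-size-free, which is
what makes a constant threshold of 1.0 meaningful across datasets. A
coefficient with zero jackknife spread and nonzero mean gets infinite RI
and is always selected. Classic noise-augmented UVE — append as many
artificial noise columns as real ones and cut at the maximal |RI| among
them — is available behind `noiseAugment = TRUE`. In `runTrain()` the
component count used for the jackknife is itself chosen by LOOCV on the
full spectrum first; if no wavelength clears the cutoff, elimination is
skipped with a message rather than failing.

**Metrics.** `R² = 1 − SSE/SST`, `RMSE = sqrt(SSE/n)` (divide by n, not
n − 1), `RPD = Std/RMSE` with Std the sample standard deviation of the
measured values unless a reference Std is supplied. Grades: good
(RPD > 2), middle (1.4 ≤ RPD ≤ 2), poor (< 1.4). Degenerate cases are
errors, not NaNs: constant measured values (SST = 0), and perfect
predictions (RMSE = 0, RPD undefined).

## SPAD mapping

The shipped `publishedSpadModel()` carries the ten printed coefficients
and intercept 43.828 of the published UVE–PLS regression, verbatim. Note
a documented discrepancy in the source material: the printed selected-
wavelength list contains 706 nm, while the regression equation contains
827 nm and no 706 nm term. The shipped model follows the equation; the
package does not resolve the conflict. Predictions are
`Y = Σ c_λ R_λ + intercept`, applied per pixel inside the mask and never
clamped (only the rendering clamps, for display). Because the model is
linear, the masked mean of the map equals the prediction of the masked
mean spectrum exactly — a property the tests assert. Rendering uses a
fixed 256-entry blue→green→yellow lookup built from the RGB ramp,
channel-wise monotone, with background (mask 0 / SPAD 0) pinned to the
blue endpoint and a default display range of 0–60 SPAD.

## The synthetic-scene generator

`generateScene()` emulates the content of a field view: soil everywhere,
a mulch-film strip, residual-straw patches, the four-panel board, a weed
patch, a partially visible neighboring plant, and the target plant, all
painted back-to-front at the profile's 25 wavelengths. Signatures are
piecewise-linear templates with per-scene jitter chosen to match the
qualitative field spectra — vegetation low in red (< 0.15) and high on
the NIR plateau (> 0.5), film uniformly ≥ 0.6, soil ≤ 0.2 — which is
exactly what the MDVI's sign structure needs. Object fractions mirror a
plausible frame (plant ≈ 17 %, film ≈ 3 %, board ≈ 1 %) so that the
vegetation/background split dominates the index histogram the way it
must for Otsu to be usable at all. Two constructions make the noise-free
contracts exact rather than approximate:

* the plant blob is the fixed point of the 3×3 binary median, so the
  segmentation chain's single median pass leaves the ground-truth mask
  unchanged and the clean-scene accuracy is exactly 100 %;
* the grayscale model's default slope `1.6/2^bitDepth` represents the
  board's quarter-level reflectances as exact integers, so the fitted
  calibration is exactly collinear on a noise-free board (full scale
  sits at reflectance 1.6 to leave headroom for noise and the SPAD
  field).

A radial SPAD field (default 52 at the plant center falling to 44 at the
rim, consistent with upper leaves being greener) is embedded by
adjusting the 935 nm band so the published model inverts it exactly on
the noise-free cube. Per-pixel Gaussian reflectance noise and 10-bit
quantization sit on top. Each scene draws from a single generator seeded
once; the caller's RNG state is saved and restored.

`generateSpectraDataset()` draws reflectance vectors from a plant-like
base spectrum plus 3 smooth Gaussian-bump latent components and
independent per-band noise (SD 0.08), and sets
`SPAD = intercept + w·R + ε` with weights (−40, 30, 40) on 681, 888 and
935 nm and ε of SD 1.5 SPAD units — spreads chosen so SPAD spans roughly
the agronomic 17–53 range with a mean near 36. With `nLatent = 0` the
bands are independent, making non-informative bands pure noise; that is
the configuration used for the variable-selection checks.

What the generator does **not** emulate: canopy geometry and shadows,
illumination gradients, BRDF effects, sensor PSF and crosstalk between
mosaic filters, and spectrally realistic continuous variation within
objects. Passing tests therefore demonstrate the correctness of the
algorithms and their contracts, not field-level accuracy figures; the
published accuracy tables require the original field images and are out
of scope here.

## Problem sizes and runtime

The test-suite and acceptance checks run at deliberately desk-sized
scales: 64 × 64 scenes (one 217 × 409 I/O round trip), 16 × 16 rasters
for the 100-image Otsu and 100-mask component-labeling oracle sweeps,
n = 100–200 spectra tables, 20 UVE replicates, and 5 parameter-recovery
replicates at n = 150. The full suite completes in well under a minute
on one CPU.

## Known limitations

* One plant per frame by design: the largest-domain heuristic cannot do
  multi-plant instance segmentation and loses to a larger weed patch.
* The fixed UVE cutoff of 1.0 is a convention; with the pseudo-value
  scaling an informative band whose jackknife t-statistic is below
  ≈ `√n` can fall just under it on unlucky samples (the parameter-
  recovery test exercises exactly this regime and is therefore stated as
  a mean over seeded replicates).
* The grayscale→reflectance map is assumed affine and stable within a
  cube; illumination drift between board captures is not modeled.
* Reading third-party multi-page TIFFs assumes pages are already in the
  profile's wavelength order; only cubes written by the package carry a
  sidecar asserting value kind and normalization.
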