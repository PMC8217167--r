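---
title: "Histogram-based nitrogen diagnosis from canopy RGB photographs"
author: "canopyN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Histogram-based nitrogen diagnosis from canopy RGB photographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopyN)
```

## The problem and the method

Leaf nitrogen (N) status drives chlorophyll content, canopy color and
fractional ground cover in cereals, and phone photographs of the canopy are a
cheap, nondestructive window onto it. The classical approach summarizes a
color-index image by a single number — the index-image mean value (IIMV) over
the vegetation component — and regresses leaf N content or grain yield on it.
The mean, however, only reflects hue: two canopies with the same average
greenness but very different ground cover are indistinguishable, and ground
cover is itself a strong N signal.

canopyN implements the histogram alternative. Six per-pixel color indices are
computed from the 8-bit R, G, B channels:

* ratio indices `GR = G/R` and `GB = G/B`,
* normalized intensities `NRI = R/(R+G+B)`, `NGI = G/(R+G+B)`,
  `NBI = B/(R+G+B)`,
* the normalized green-minus-red index `GMRN = (G−R)/(R+G+B)`, which
  highlights vegetation against soil.

The index-image histogram (IIH) — per-bin pixel percentages over the index's
fixed range — is bimodal for a partly covered canopy: the left mode (peak a)
collects soil pixels, the right mode (peak b) vegetation pixels. The height of
peak b rises and peak a falls as coverage grows with N supply, while the
position of peak b tracks hue; the histogram therefore carries both color and
growth information, which the mean cannot. Informative histogram regions are
selected by correlating each bin's percentage with the target across samples,
inside a window centered on the vegetation peak of the cohort template
histogram, and the selected bins feed a small multilayer perceptron (one
10-unit logistic hidden layer, one linear output) trained by
Levenberg–Marquardt (LM) least squares — one network per target (leaf N
content in % dry mass; yield in kg/ha). The package's evaluation harness runs
both feature families through an identical protocol (per-stage 60/30
stratified split, identical training configuration) and reports MAPE and RMSE
on training and validation data.

## Pipeline and the objects involved

1. `readCanopyImage()` / `readSampleTable()` load photographs (PNG/JPEG/TIFF)
   and the cohort table into `CanopyImage` objects.
2. `computeIndex()` produces an `IndexRaster` with a validity mask: pixels
   with a zero denominator (pure black for the sum-based indices, `R = 0` for
   G/R, `B = 0` for G/B) are masked invalid and excluded everywhere
   downstream, rather than clamped to a fabricated value.
3. `segmentVegetation()` thresholds GMRN — Otsu's bimodal split by default, a
   fixed threshold on request — giving the `VegetationMask` that IIMV
   averages over.
4. `indexHistogram()` + `detectPeaks()` give `HistogramFeature`s;
   `binCorrelations()` + `selectRegion()` give a `BinSelection`;
   `buildFeatureMatrix()` assembles the design matrix for either family.
5. `fitDiagnosisModel()` trains the LM-MLP (multi-start), `runComparison()`
   executes the whole protocol, `cmdSimulate()`/`cmdFeatures()`/
   `cmdDiagnose()` wire it to directories on disk.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| `nBins` | 256 | display-histogram granularity of common raster tools; fixed equal-width bins over each index's theoretical range keep bins comparable across samples, which bin-wise correlation requires |
| GR/GB histogram range | [0, 5] | the ratios are unbounded above; a fixed range (out-of-range pixels clipped into end bins) is needed for comparable bins; canopy values rarely exceed 3 |
| `smoothWindow` | 5 bins | moving-average smoothing before peak detection; soil/crop modes are tens of bins wide |
| `minSeparation` | 20 bins | soil and crop modes of GMRN sit ≈ 0.2 index units apart (≈ 26 bins); closer maxima are treated as one mode |
| `window` | 41 bins | width of the selection window around the template's vegetation peak; spans the crop mode with margin |
| `rMin`, `kMin` | 0.5, 8 | correlation filter inside the window, with a top-`kMin` fallback so the network always has a modest input set relative to 60 training samples |
| `nHidden` | 10 | the diagnosis architecture: one logistic hidden layer of 10 units, one linear output |
| LM schedule | `mu0 1e-3`, ×10 / ×0.1 | the standard damped Gauss–Newton schedule; damping overflow (mu > 1e10) is the usual convergence exit |
| scaling | min–max to [−1, 1] | inputs and target; unscaled yields (~6000 kg/ha) would swamp the sigmoid dynamics |
| `earlyStopFraction`, `maxFail` | 0.15, 6 | inner early stopping (below) |
| `restarts` | 5 (`fitDiagnosisModel`), 3 (`runComparison`) | LM on a nonconvex loss is init-sensitive; restarts differ only in the seeded initialization, and the comparison protocol uses 3 because the multi-start benefit saturates quickly at this cohort size |

## Numerical and design choices

**Masking, not clamping.** Invalid pixels propagate as `NA` + mask through
histograms (counts over valid pixels only) and means. An image with no valid
pixel is an error, not a silent zero.

**Peak assignment.** After smoothing, local maxima are ranked by height; the
two tallest maxima at least `minSeparation` bins apart become peaks a (left)
and b (right). A single mode is assigned by its position relative to the range
midpoint; a flat histogram yields no peaks and a flag. Zero-height plateau
bins are never maxima.

**Selection without leakage.** The template histogram, its peaks, and the
bin-target correlations are computed on the training split only and frozen
(serialized to JSON with exact bin edges) before any validation sample is
touched.

**Zero-variance bins.** A bin constant across samples gets correlation 0 by
convention rather than NaN, so empty histogram regions can never be selected
by noise.

**Inner early stopping.** An unregularized 10-unit LM fit interpolates 60
training samples exactly (training MAPE 0.0%), and the interpolating nets
generalize poorly. Standard neural-network fitting tools therefore hold a
fraction of the training data out of the optimized loss and stop when that
holdout stops improving; canopyN does the same (15% holdout, 6 tolerated
failures, best-holdout weights returned; `earlyStopFraction = 0` disables it
and optimizes the training loss to convergence, which is also what the
optimizer-correctness tests use). The holdout is carved from the training
split only — the 30-sample validation set remains untouched test data.

**Multi-start selection.** Restart fits are compared by holdout loss when
early stopping is active, by final training loss otherwise; the chosen seed is
recorded in the model artifact.

**Split construction.** `splitSamples()` stratifies by cultivar × N rate with
proportional largest-remainder allocation, guaranteeing every stratum appears
in training; strata smaller than 2 are pooled with a warning. The comparison
protocol sorts each stage's samples by id before splitting and fitting, so
results are invariant to input row order.

## What the synthetic generator emulates — and what it does not

No field photographs accompany the method, so the package ships a generator
(`generateCohort()`) reproducing the statistical structure the method relies
on, with defaults calibrated to a winter-wheat N trial: 6 cultivars × 5 N
rates (0, 120, 180, 240, 360 kg N/ha) × 3 replicate images = 90 samples per
stage.

* **Leaf N** follows a saturating response `3.0 + 0.95·(1 − exp(−N/150))` %
  plus cultivar offsets (sd 0.25), plot-level variation (sd 0.15) and
  measurement error (sd 0.10), spanning ≈ 2.3–4.5%.
* **Yield** follows a quadratic response with optimum near 225 kg N/ha
  (curvature 0.016, maximum 6800 kg/ha) fitted to the trial's per-rate mean
  yields, plus cultivar offsets (sd 300) and noise (sd 200) — rising steeply
  from the unfertilized level and declining mildly past the optimum.
* **Pixels** are a two-population mixture: soil around RGB (130, 105, 85) and
  vegetation around (80, 125, 65) at the reference leaf N of 3.5%, with
  greenness gaining 12 and redness losing 8 channel units per leaf-N percent.
  These place the soil and crop GMRN modes near −0.08 and +0.17, matching the
  whole-frame index means a partly covered vs fully covered wheat canopy
  prints.
* **Coverage** rises logistically with latent leaf N: ≈ 0.20–0.65 at the
  low-coverage ("reviving") preset, 0.50–0.92 at the high-coverage
  ("jointing") preset, constant at 0.45 in the "color_only" preset used to
  isolate the hue channel of information. Vegetation is spatially clustered
  by thresholding a Gaussian-smoothed noise field, so canopies are patchy
  rather than salt-and-pepper.
* **Cameras.** Every image receives a random white-balance perturbation
  (per-channel log-normal gains, sd 0.04) emulating phone auto color tuning;
  `applyCameraTransform()` additionally applies explicit gain/gamma/offset
  transforms for cross-brand experiments.

What it does **not** emulate: real leaf geometry and specular highlights,
shadows, mixed soil types, growth-stage-specific canopy architecture, or
cultivar × N interactions (one cultivar collapsing at zero N, as field trials
sometimes show). Passing tests on this generator demonstrate that the
pipeline recovers the signal structure the method assumes — not that it
reaches any particular accuracy on real field photographs.

**Problem sizes.** The shipped tests and the acceptance script use the full
90-sample cohorts at 96 × 96 px (protocol checks run 10 cohort seeds;
plumbing checks use 18-sample cohorts at 48–64 px). Image size affects only
histogram smoothness, not the protocol; 96 px keeps a full 10-seed comparison
under half a minute.

## The constructive IIMV-vs-IIH argument

`equalMeanDistinctCoveragePair()` builds two noiseless images whose
whole-frame GMRN means agree to better than 1e-3 while their vegetation
coverages differ by ≥ 0.2 (vegetation greenness is solved analytically to
compensate the coverage difference, mixing two adjacent achievable
green-minus-red levels to hit the target mean). Their histograms differ by
more than a percentage point in many bins: coverage is invisible to the mean
and obvious to the histogram. The cohort-level counterpart: under the default
coverage-varying scenario the IIH model's median validation MAPE is at or
below the IIMV model's for both targets, and under the constant-coverage
scenario the gap collapses — the histogram's advantage is exactly its access
to coverage.

## Known limitations

* The MLP is deliberately small and the LM trainer dense; hundreds of inputs
  or thousands of samples would call for a different optimizer.
* MAPE is undefined at zero targets; targets are required positive.
* Otsu segmentation assumes a bimodal GMRN distribution; a fully closed
  canopy (no soil mode) degrades to a hue split, which is why IIMV can be
  computed over the whole frame (`useVegetationMask = FALSE`) as well.
* Bin selection uses linear per-bin correlation; a target nonlinear in the
  bins (yield near its optimum N rate) can under-select, which the top-`kMin`
  fallback mitigates but does not remove.
* JPEG input is supported but lossy; archival pipelines should prefer PNG, as
  the package's own writers do.
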