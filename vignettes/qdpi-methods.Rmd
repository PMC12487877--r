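---
title: "Methods behind qdpi: quantifying and tracking injectable NIR fluorescent markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind qdpi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qdpi)
```

## The problem

Markerless pose trackers for freely moving mice are limited by the supply of
hand-labeled frames. Injectable near-infrared quantum-dot (QD) markers offer a
way out: small subdermal or intra-articular fluorescent deposits act as
physical fiducials visible through skin, so keypoint labels can be generated,
corrected and quality-controlled by machine. `qdpi` implements the analysis
side of that workflow: everything from the interleaved reflectance/fluorescence
video to quantified marker brightness, longevity and spread, sub-pixel marker
localization, automated construction of machine-labeled keypoint datasets,
sample-efficiency curves, multi-camera triangulation with physical-unit error
conversion, and histological colocalization. It does not train trackers or
segment cells — it consumes their outputs.

## Data model and conventions

Image coordinates are `x = column`, `y = row`, 0-based, origin at the
top-left pixel center; frame indices in keypoint tables are 0-based and index
the demultiplexed fluorescence stack. Recordings are 3-D arrays
`(frame, row, col)` of non-negative intensities at a declared bit depth (8 or
16 bit; the acquisition depth is treated as a free parameter and both are
supported). Everything tabular — keypoint predictions, session summaries, QC
reports, triangulated points — flows as tibbles so results chain with the
pipe.

Illumination is temporally multiplexed: each cycle holds one IR reflectance
exposure and one NIR fluorescence exposure separated by dark gaps. The
default cycle is 10 / 1 / 23 / 1.5 ms (a 2 / 1 / 8 / 6 ms fast variant is
provided). `demultiplex()` assigns every frame to its channel by within-cycle
slot; a trailing partial cycle is dropped with a warning rather than an error
because real recordings end mid-cycle. Display frames for labeling blend 90%
fluorescence with 10% reflectance, saturating at the bit depth.

## Fluorescence quantification

Brightness is summarized per session in four steps:

1. **Rolling background subtraction.** A per-pixel background is estimated
   over nonoverlapping 1500-frame blocks and subtracted; negatives clamp to
   zero. The block statistic is the per-pixel **median** by default — robust
   to a bright spot passing through a pixel for a minority of the block —
   with mean and min selectable. A short final block uses its own frames.
2. **Per-frame maximum** over (optionally mask-restricted) pixels.
3. **Session summary**: the mean and the 95th percentile (linear
   interpolation, R's type-7 quantile — stated because percentile
   definitions differ) of the per-frame maxima.
4. **SNR** either as the ratio of marker-session means to control-session
   means, or as the per-frame standard deviation of all pixels averaged over
   frames (population SD, divisor `n`). The per-frame SD could alternatively
   be taken over axis marginals; the all-pixels form is the default and the
   marginal variant is exposed via `marginal = TRUE`.

**Longevity** is the first post-injection day on which a session summary
falls below the 99th percentile of per-frame maxima pooled across all
vehicle/blank control sessions (one pooled threshold per rig, matching a
single control band); traces that never cross are censored at their last
imaged day.

**Spatial spread** uses the full 2-D autocorrelation of every 200th
background-subtracted frame (computed by FFT without mean removal, since the
input is already background-subtracted), each map normalized to 1 at zero
lag and averaged. A bivariate axis-aligned Gaussian is fitted by least
squares; its SDs estimate the spread. For a single Gaussian spot of width
sigma the autocorrelation is a Gaussian of width sigma * sqrt(2) — the package
tests verify this identity at sigma = 1, 2 and 4 px. All-zero frames have
undefined normalization and are skipped with a warning.

## Sub-pixel spot localization and keypoint refinement

A tracker prediction is refined to the fluorescence center within a 10 px
radius:

1. crop a square of half-width `radius` around the prediction (clipped at
   frame borders) and restrict to the disk of that radius, so a refined
   center can never move farther than the search radius;
2. threshold the crop. The binarization threshold before contour grouping is
   a free choice: the default is Otsu's threshold computed within the crop,
   with an absolute floor of 10 a.u. so noise-only crops yield no component;
3. keep the 8-connected component whose (unweighted) centroid is nearest the
   prediction. Ties break by larger integrated intensity, then lower label —
   stated for determinism;
4. estimate the center by least-squares bivariate Gaussian fit (default) or
   intensity-weighted center of mass. The Gaussian fit needs at least 6
   pixels of support; when it fails, or its center leaves the search disk,
   the center of mass of the selected component is used instead.

The Gaussian fit is initialized with the offset at the crop minimum, the
amplitude at the range, the center at the peak pixel, and sigma from the
supra-half-maximum pixel count (`sqrt(n_half / pi) / 1.1774`). Raw second
moments were rejected for initialization: a noise floor inflates them toward
the crop radius, which makes the model locally indistinguishable from its
offset and the Jacobian singular. A short ladder of fallback widths (1.5, 3,
crop/6) guards the rare remaining failures. On symmetric noiseless spots the
fit and the center of mass agree to 1e-6 px; on noisy spots (sigma 1.5-3 px,
peak SNR >= 5) the fitted center is accurate to well under a quarter pixel
RMSE.

## The quality-control cascade

`run_cascade()` applies the published filter stages in fixed order — the
order is part of the method, not configurable:

1. **Jump**: a keypoint moving more than 30 px (L2, strict) relative to
   either neighboring detection of its track is excluded. Track endpoints
   compare to their single neighbor. Note a teleported detection necessarily
   also perturbs its neighbors' displacements, so one bad detection typically
   excludes three records.
2. **PCA pose outliers** (standard 10-keypoint config only): pose vectors of
   complete frames are decomposed by PCA; the component count `k` is the
   smallest that explains at least 90% of the variance (equivalently, drops
   the cumulative mean squared reconstruction error by 90%). Frames whose
   reconstruction MSE exceeds `median + 5 * (1.4826 * MAD)` — and exceeds a
   numerical floor of 1e-6 px² — are excluded. The outlier rule itself is a
   design choice, exposed in `qc_config()`. A 3-MAD rule was considered and
   rejected: with Gaussian landmark noise it flags about 1% of perfectly
   clean frames, which is incompatible with using the surviving set as
   training labels; at 5 MADs the false-flag probability is negligible while
   genuine pose outliers sit orders of magnitude above the threshold. Only
   complete frames enter the decomposition; incomplete frames pass through
   unflagged.
3. **Visibility**: confidence must exceed 0.2.
4. **Validity**: a visible keypoint needs a fluorescence peak of at least 75
   a.u. at confidence 0.7, scaling linearly to 25 a.u. at confidence 1.0,
   and must lie within 5 px of the nearest fluorescence center at 0.7,
   scaling to 15 px at 1.0. Scores below the anchor clamp to the anchor's
   thresholds, since the scale is defined only between the anchor and 1.
5. **Drop budget**: a frame may drop (visible minus valid) at most 0
   keypoints when 3 or fewer are visible, 3 when 10 are visible, linear and
   floored to an integer in between (the floor is the conservative choice).
6. **Pairwise distance**: frames with any valid keypoint pair farther apart
   than 300 px (strict) are excluded.

The knee-joint variant anchors the confidence scaling at 0.5 and skips the
PCA stage (two keypoints span no useful pose subspace).

Each stage records machine-readable flags; surviving records carry none.
Loosening any single threshold never shrinks the surviving set, with one
documented interaction: loosening the jump threshold can complete a frame
that the PCA stage then excludes wholesale, so jump monotonicity holds per
stage and at cascade level with PCA off.

## Sample-efficiency curves

Tracker error versus training-set size is fitted with the decay power law
`y = a (x + 1)^b + c` (and a saturating form `y = a (1 - (x + 1)^(-b)) + c`
for metrics that grow). Fitting is nonlinear least squares with multi-start
initialization over the exponent (b0 = -0.5 or +0.5, jittered by factors 1/4
to 4, plus a swapped-offset start); constant data leave the exponent
unidentifiable and are flagged degenerate. Uncertainty comes from a
case-resampling bootstrap over (frame count, error) pairs — the resampling
unit is a design choice — reporting per-x 2.5/97.5 percentiles and the median
curve; bootstrap refits start from the full-data estimate. The frames needed
to reach an error threshold `t` invert the decay form,
`x = (a / (t - c))^(-1/b) - 1`, rounded **up** so the threshold is
guaranteed; thresholds at or below the asymptote `c` return `Inf`. The pixel
thresholds corresponding to 2 mm and 1 mm on the standard optics (4.9 and
2.45 px) are treated as configuration inputs rather than derived constants,
because they do not follow unambiguously from the pinhole parameters alone.

## Multi-view geometry

Calibrations (intrinsics, radial-tangential 5-coefficient distortion,
extrinsics) are consumed from JSON; world units are fixed to millimeters.
Observations are undistorted to normalized coordinates (fixed-point
inversion of the distortion polynomial) and triangulated by the direct
linear transform with the singular-value solution; an optional one-step
reprojection refinement is off by default. Per view the package reports
reprojection error, the Euclidean distance from the camera center to the
point — "distance to the camera" is taken as distance to the camera center,
with the axis-depth variant available through the camera-frame depth — and
the angle between the optical axis and the camera-to-point ray. Geometry is
flagged degenerate when all viewing rays are within about 0.06 degrees of
parallel. Pixel errors convert to millimeters via the pinhole footprint
`error_px * pitch * distance / focal_length`, and the optical Nyquist limit
is twice the one-pixel footprint.

## Histology quantification

Otsu's threshold is computed on a 256-bin histogram over the image's own
range (16-bit images therefore rescale to 256 bins — stated for
reproducibility), maximizing between-class variance over all cut points;
foreground is strictly above threshold. Intracellular enrichment is the mean
QD intensity over cell-ROI pixels divided by the mean over the complement;
the default pools ROI pixels, with a per-ROI-means variant exposed because
the averaging order is ambiguous in general. Colocalization Otsu-thresholds
the marker and nucleus channels and reports the ratio of QD intensity sums
within the two masks — sums, not pixel counts, because intensity carries the
signal. Overlapping mask pixels count in both masks by default; an exclusive
option drops the overlap from both. Both ratios are invariant to positive
rescaling of the QD channel.

## The synthetic generator

Every analysis stage is testable against generated data with full ground
truth; all randomness derives from one integer seed and outputs are
bit-reproducible. The generator emulates:

- **Recordings**: an interleaved stack following the illumination schedule; a
  bright moving body ellipse on reflectance frames; Gaussian marker spots
  (default sigma 3 px, FWHM = 2.3548 sigma ≈ 7 px, inside the reported 6–15 px
  spot range) of amplitude 150 a.u. on a 10 a.u. background with Gaussian
  read noise (SD 2) and optional Poisson shot noise, quantized to the bit
  depth. Session-to-session amplitude decays as `2^(-day / half_life)`; the
  default half-life of 5 days is a phenomenological choice placing crossing
  days in the reported single-digit-to-tens range — the study reports
  crossing days, not a decay law.
- **Keypoint predictions**: truth plus Gaussian jitter, with confidence
  `clamp(1 - error / err0 + noise)` so the cascade's confidence-scaled
  thresholds are meaningfully exercised, plus fluorescence-evidence columns
  and labeled injected violations.
- **The QC benchmark**: 100 frames of 10-node pose motion whose three
  structural modes (x-translation, y-translation, tail stretch) follow
  distinct Fourier harmonics of the window. Harmonics make the modes exactly
  uncorrelated and each carries well over 10% of the pose variance, so the
  90% rule always retains all three; the tail stretch legitimately exceeds
  the 300 px pairwise limit at its peaks and is reconstructed — not flagged —
  by PCA. One injection per rule is placed so that it triggers exactly its
  own rule, and ground-truth labels are recomputed from the final table with
  one-line rule oracles.
- **Camera rigs**: five pinhole cameras on a pentagon 304.8 mm from the
  arena center (8 mm lens, 5.7 um pixels), exact calibrations, and projected
  3-D trajectories with optional pixel noise.
- **Histology fields**: scattered cell ROIs at a configured enrichment
  (default 3.7) over background, a marker region inside a host cell and a
  nucleus region outside all cells, with the marker area sized so the
  marker/nucleus QD-sum ratio matches the configured colocalization ratio
  (default 1.8); channel foregrounds are far above background so Otsu
  recovers the masks. Realized ("true") ratios are recorded from the
  noiseless construction.

What passing tests do **not** show about real data: the generator renders
isotropic Gaussian spots on flat backgrounds — no skin scattering, fur
occlusion, motion blur, autofluorescence gradients, or tracker-specific
error structure; keypoint confidence is tied to true error by construction,
which real trackers only approximate; and histology masks are geometric. The
tests certify the algorithms, not the biology.

## Problem sizes and runtime

The shipped test suite runs at desk scale by design: recordings of 25-50
cycles at 96 x 96 px (10,000 frames at 32 x 32 for the demultiplexing
accuracy check), 1,000 spot fits for the localization RMSE, 100-frame QC
benchmarks, 50-replicate fitting studies, 100-resample bootstraps, and
512 x 512 histology fields. The full suite completes in well under a minute
per module on one CPU.

## Known limitations

- The background model is blockwise constant; slow continuous drifts within
  a 1500-frame block are not removed.
- The Gaussian spot model is axis-aligned; strongly elongated or merged
  spots bias the fitted center toward the component centroid fallback.
- The DLT minimizes algebraic, not reprojection, error; the optional
  refinement step mitigates but bundle adjustment is out of scope.
- The cascade's PCA stage needs enough complete frames to span the pose
  subspace; short clips fall back to a warning and no PCA filtering.
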