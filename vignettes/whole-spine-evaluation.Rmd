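---
title: "Methods: preprocessing and lesion-wise evaluation of whole-spine axial T2w segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: preprocessing and lesion-wise evaluation of whole-spine axial T2w segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spineval)
```

## The problem

Axial T2-weighted spinal cord protocols for multiple sclerosis acquire the
cord in two or three independently planned stacks ("chunks") covering the
cervical, thoracic and lumbar regions, because a single whole-spine
acquisition is impractically long. The voxels are highly anisotropic —
around 0.6 mm in-plane with 3–4 mm slices — and each chunk carries its own
scanner-space affine. Everything downstream of a segmentation model must
cope with this geometry: chunks have to be merged for whole-spine
morphometrics, per-chunk predictions have to be combined into one
per-patient verdict before lesion counting, and curvature of the cord is a
nuisance variable some pipelines remove by "straightening".

`spineval` implements that machinery: stitching, invertible straightening,
region-based overlapping labels, and a lesion-wise evaluation protocol
with explicit empty-mask conventions — together with a synthetic phantom
that stands in for patient data in every test.

## Data model and conventions

All images and masks are `anat_volume` / `binary_mask` objects: a 3D array
plus a 4×4 affine mapping **0-based voxel indices to world millimetres at
voxel centers** (the NIfTI convention), in the RAS+ world frame.
Orientation codes name the anatomical direction each voxel axis points
toward (`"RPI"`: Right, Posterior, Inferior); `reorient()` permutes and
flips axes without moving any voxel in world space. Two global numeric
rules hold everywhere:

* voxels mapping outside a source field of view take the fill value 0
  (geometric operations run *before* intensity normalization, so 0 is
  background, not an extreme Z-score);
* any binary mask that passes through linear interpolation is binarized
  at a fixed threshold of 0.5. The threshold is deliberately not
  configurable.

## Stitching

`plan_stitch()` follows a four-step corner-point scheme: (i) the eight
corner voxel centers of each chunk are computed; (ii) candidate rotations
are taken from the chunks' own direction-cosine matrices and the one
minimizing the axis-aligned bounding volume of all corner points is
selected — a finite, deterministic search rather than a continuous
optimization; (iii) chunks are resampled onto the common grid (per-axis
spacing = minimum over chunks) and per-chunk occupancy maps are stored;
(iv) overlaps are blended with weights that ramp linearly from the chunk
interior to zero at its superior–inferior boundary and are renormalized to
sum to one wherever at least one chunk is present.

Alignment relies entirely on scanner-space affines; registration between
chunks is a declared non-goal. Chunks separated by a world gap larger than
`gap_tol_mm` (default 10 mm) trigger a warning and the gap voxels keep the
fill value — this mirrors what suboptimal scan planning produces in
practice.

Two open parameters are ours: the exact blending profile (we use a linear
ramp whose default width is the number of shared slices between adjacent
chunks) and the mask-stitching mode (default: blend linearly, then
binarize at 0.5, consistent with the global rule; a `nearest` mode copies
the dominant chunk's voxels instead).

## Straightening

The straightening transform is a documented simplification of
template-free cord straightening: each axial slice is **rigidly translated
in-plane** so the cord centerline lands on the vertical reference axis
through the mean in-plane centerline position. The centerline is the
per-slice cord-mask centroid smoothed with a moving local-linear fit
(order-1 Savitzky–Golay, default window 5 slices ≈ 16.5 mm); a plain
moving average was rejected because its shrinking edge windows bias the
curve inward exactly where the cord ends. The inverse field is stored
explicitly as the negation of the forward field, so forward∘inverse is
zero *by construction* — the property the evaluation protocol depends on
when predictions made in straightened space are brought back to native
space.

Per-slice rigid translation is area-preserving, exactly invertible, and
cannot create the nonlinear lesion-size distortions that full curvature
warps introduce; it intentionally does not reproduce any specific external
tool's B-spline machinery. One numerical consequence is worth stating:
binarizing a bilinearly shifted mask at 0.5 quantizes each slice's
translation to the voxel grid, so centroids of *binary* straightened masks
sit up to exactly half an in-plane voxel from the reference axis. The
transform's own accuracy is therefore measured on the soft
(pre-binarization) cord, whose partial-volume-weighted centroids land on
the axis to well under half a voxel.

After straightening, the cord occupies a narrow vertical column;
`crop_to_cord()` optionally reduces the in-plane field of view to the
cord's bounding box plus a margin, emulating the reduced field of view of
straightened scans. Binarization happens last, after any cropping.

## Region-based labels and the loss

`build_region_labels()` reframes the two-class task as two *overlapping*
binary channels forming a hierarchy: channel 1 = cord ∪ lesion, channel 2
= lesion. `dice_bce_loss()` scores per-channel sigmoid outputs with

$$ L = \tfrac12 \sum_{c} \Big[ 1 - \frac{2\sum p_c y_c + s}{\sum p_c + \sum y_c + s} + \mathrm{BCE}(p_c, y_c) \Big] $$

with additive smoothing $s = 10^{-5}$ and probabilities clipped to
$[\varepsilon, 1-\varepsilon]$, $\varepsilon = 10^{-7}$, **in the log
terms only** — clipping inside the Dice sums would make an all-empty
channel score a spurious Dice of $s/(n\varepsilon + s)$ instead of 1.
Channels are averaged unweighted, and BCE is a voxel mean; sums versus
means over channels and voxels are framework-internal choices that we fix
and document here. At decode time the hierarchy is restored by forcing
lesion voxels into the cord mask (lesion sensitivity is the study
priority), rather than letting the cord channel gate lesions away.

## Evaluation protocol

Lesion-wise metrics are computed **once per patient** on stacked chunk
masks, not averaged over chunks. `stack_chunks()` zero-pads every chunk
symmetrically in-plane to the largest in-plane shape and concatenates
along the slice axis in cranio-caudal order; overlapping anatomy is
deliberately not de-duplicated, and the output carries a nominal
axis-aligned affine — stacking is bookkeeping, not geometry. The toy
three-chunk configuration in `scripts/acceptance.R` shows why the
distinction matters: chunk-wise recalls 0.5, 1, 1 average to 5/6 ≈ 0.833,
while the stacked protocol gives 3/4 = 0.75.

Lesions are 3D connected components, 26-connectivity by default
(configurable; the convention is not dictated by the protocol itself). A
ground-truth lesion is detected when predicted voxels cover at least 10 %
of **its** volume — the denominator is the GT lesion, the boundary is
inclusive, and coverage aggregates all predicted components. A predicted
component is a false positive iff it shares no voxel with any detected GT
lesion. Both choices close open corners in the written criterion and are
exercised against a brute-force set-operation oracle in the tests.

Empty-mask conventions: when GT and prediction are both empty, Dice, NSD
and the lesion-wise scores are 1 and the count difference 0 — correctly
predicting "no lesion" is a success, and skipping such cases would bias
every false-positive-sensitive metric upward. When exactly one side is
empty, similarity scores are 0 and counts follow their definitions; either
situation sets `empty_case_flag`.

NSD uses boundary voxels (mask voxels with a background 6-neighbor, volume
edges counting as background) as surface points in world mm, symmetric
fraction within a tolerance (default 1.0 mm — the tolerance is not fixed
by the protocol and is configurable). RVE is the signed percentage volume
error. Detection rates are binned by GT lesion volume into half-open bins
with edges 10, 50 and 200 mm³; the first two edges are the published ones,
the third is this package's default and configurable. Empty bins are
reported as absent, never as rate 0.

## The phantom

`make_phantom()` emulates exactly the features the machinery above needs
and nothing more: a tubular cord (radius 4 mm) around a sinusoidal
centerline (amplitude 6 mm, period 180 mm — gentle thoracic-like
curvature), hyperintense ellipsoidal lesions elongated along the slice
axis and placed strictly inside the cord, Gaussian intensity noise, and
a typical clinical acquisition geometry of 0.6 × 0.6 × 3.3 mm voxels on
a 64 × 64 × 144 grid (≈ 47 cm of spine, anisotropy 5.5×). Lesion volumes
are drawn log-normally (meanlog = log 45, sdlog = 0.8, truncated to the
law's 1st–99th percentiles and a 3-voxel floor) so that all detection-rate
bins are populated; the law is a stand-in chosen to put most mass in
10–200 mm³, not a fit to any cohort. Lesions are laid out along the cord
with at least a one-slice clearance, so the generated component count
equals `n_lesions` by construction. `split_into_chunks()` cuts the phantom
into cranio-caudally numbered chunks sharing an exact number of axial
slices, optionally with small per-chunk in-plane rotations (resampled from
the phantom, emulating independent scanner planning; disabled by default
so round trips are exact). `degrade_prediction()` manufactures predictions
with a known error structure — deleted lesions, spurious components,
boundary jitter — for exercising the metrics.

What the phantom does *not* model: MR physics (no bias field, no k-space
artifacts), vertebrae/CSF anatomy, lesion texture, inter-rater ambiguity,
and the real anatomical variability of cords and lesions. Passing the test
suite therefore demonstrates that the geometry and the metric definitions
are correct, not that any segmentation model performs well on clinical
data.

## Numerical choices and degenerate inputs

* Resampling is pull-based trilinear or nearest-neighbour through the
  composed affine map, implemented in C++; identity grids reproduce the
  input to machine precision.
* Stitch weights are validated to sum to 1 wherever any chunk is present;
  tie-breaks in the bounding-box rotation search go to the first chunk's
  rotation.
* Lesion matching ties (two predicted components covering a GT lesion
  equally) resolve to the larger overlap, then the smaller predicted id.
* Constant images cannot be Z-scored (error); empty cord masks cannot
  yield a centerline (error); single-slice centerlines cannot define a
  transform (error); RVE is undefined for an empty reference (error).
* Every stochastic operation takes an explicit seed and restores the
  caller's RNG state; identical specs yield bit-identical phantoms.

## Problem sizes used in the tests

The test suite runs the full pipeline on the default 64 × 64 × 144
phantom (stitch and straighten round trips), and the metric-oracle
property on 200 random mask pairs of up to 16³ voxels — sizes chosen so
the whole suite completes in well under a minute while still exercising
every code path at realistic anisotropy.

## Known limitations

* Straightening is per-slice rigid; it removes in-plane centerline offset
  but not cord tilt within a slice, and it is not a diffeomorphic
  curvature unwarp.
* `stack_chunks()` requires a shared in-plane orientation and resamples
  nothing; chunks on genuinely different in-plane grids must be resampled
  first.
* The bounding-box rotation search considers only the chunks' own
  direction cosines; a grid rotated against all chunks is never selected,
  by design.
* NSD uses voxel-center surface points rather than sub-voxel surface
  meshes; values for coarse masks depend on that representation.
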