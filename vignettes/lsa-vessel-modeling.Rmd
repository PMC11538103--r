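---
title: "Segmenting and modeling small cerebral vessels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting and modeling small cerebral vessels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Lenticulostriate arteries (LSAs) are sub-millimetre perforating vessels that
branch off the middle cerebral artery. On high-field time-of-flight MR
angiography (TOF-MRA) they appear as faint bright threads, 0.2-1.5 mm in
diameter, a few voxels wide at typical acquisition grids
(0.23 x 0.23 x 0.36 mm^3 and similar). Quantifying their number, length,
diameter and curvature is informative in cerebral small-vessel disease, but
manual annotation is slow and variable. `lsatrace` implements a composite
framework for this task: intensity standardization and bias correction, a
small-patch 3D convolutional network (SP-CNN) that classifies the *center
voxel* of a cubic patch, random-forest-scored cylinder tracking of
centerlines, rule-based screening of false branches, and piecewise cubic
Bezier modeling with per-point diameters and agreement statistics.

Because real 7-T patient volumes cannot be redistributed, the package ships
a synthetic phantom generator with exact ground truth (masks, centerlines,
radii, bifurcations). Every stage is trained and validated on phantoms; the
test suite and `scripts/acceptance.R` are entirely phantom-based.

## Preprocessing

Stages run in the fixed order bias correction, denoising, isotropic
resampling, intensity standardization (`preprocessVolume()`).

* **Bias field.** The multiplicative inhomogeneity is estimated as a
  degree-3 polynomial surface fitted by least squares to log intensities
  over normalized coordinates, normalized to unit geometric mean and divided
  out; the output mean is preserved within 1 %. Volumes containing
  non-positive values are shifted positive for the log fit and shifted back.
  A polynomial surface is a deliberately transparent estimator: the phantom
  generator produces exactly this class of smooth low-order fields, and on
  such fields the fit reduces the background coefficient of variation by
  more than half (verified in the tests).
* **Denoising.** A separable mean filter (default 3^3) is the default;
  kernel 1 is the identity and constant regions are unchanged. A full 3D
  moving median is available for salt-and-pepper-like noise. Learned
  denoisers are out of scope.
* **Resampling.** Trilinear interpolation onto an isotropic grid
  (default 0.10 mm; useful range 0.10-0.20 mm, trading small-vessel detail
  for memory and time). Masks resample nearest-neighbor so they stay
  binary. Physical extent is preserved within one target voxel and voxel
  (1,1,1) keeps its physical position.
* **Standardization.** "Standardized" intensity is defined here as the
  linear map of the robust window (0.5th-99.5th percentile) onto [0, 255],
  clipped. The robust window guards against hot voxels; per-volume
  standardization was chosen (over a fixed global scale) so the thresholds
  below stay meaningful across scanners. The operation is idempotent, and a
  constant volume maps to the midpoint with a flag.

## Pre-screening and the SP-CNN

On the standardized scale, the background threshold `tBg = 80` and the
large-vessel threshold `tV = 120` bracket the grayscale band where
small-vessel voxels live (`intensityInterval()`). Voxels at or above `tV`
form the large-vessel mask, voxels at or below `tBg` the background; only
the band in between is classified by the network. The three sets partition
the grid. The phantom generator's default intensities (background 60, small
tubes 100, large vessel 200) are chosen so this band has the same meaning on
synthetic data.

The SP-CNN (`buildSPCNN()`) is a small 3D network over cubic patches
(default 25^3 voxels): stacked blocks of 3D convolution (kernel 3, stride 2,
zero padding 1), batch normalization and ReLU, with one 2^3 max-pool after
the first block; the feature-map count (default 128) is held constant
through the downsampling steps; two dense layers end in a single sigmoid.
A patch is labeled positive iff its center voxel is vessel, and patches are
normalized to [0, 1] by the min/max of the training split (an evaluation set
must therefore reuse the training bounds — `makeTrainingPatches(normBounds=)`).
Training (`trainSPCNN()`) minimizes summed cross-entropy with Adam (initial
learning rate 1e-4, batch 25, at most 80 epochs with an early stop at 40)
under a plateau schedule that multiplies the rate by 0.1 after 10 epochs
without test-loss improvement, never below 1e-8.

The engine is implemented directly in vectorized R (im2col convolution with
precomputed gather indices, `rowsum()` scatter for the backward pass);
gradients were verified against finite differences. `featureMaps` is the
scale knob: 128 is the full-size network, 16 trains in minutes on one CPU
with the same architecture. The exact block count and dense widths are not
architectural constants of the method; three conv blocks and a 256-unit
hidden layer are the defaults, with the scaled test configuration using 3
blocks / 32 units at patch 13. The classification threshold on the sigmoid
(0.5) is exposed in `segmentVolume()`, as is the choice between merging the
large-vessel mask into the output (default) or returning small vessels only.

## Tracking

Centerlines are traced by stepping cylinders (height 3 voxels) through the
segmentation mask. Each candidate step is described by five features
(`computeStepFeatures()`): the vessel fraction of the cylinder volume, the
variance of edge distances from the end-face center along in-plane rays, the
turning angle against the previous axis, the vessel count in the 5^3
end neighborhood, and the three eigenvalues of the Gaussian-scale
(sigma = 1.5 voxels — the working resolution interpretation of an
unitless scale) Hessian of the original image averaged over the two
endpoint 11^3 neighborhoods. A bright tube yields two large negative and one
near-zero eigenvalue, which is what makes this feature discriminative.

A random forest (`ranger`, 2,000 trees at full scale, each tree on its own
bootstrap resample; 500 trees in the desk-scale tests) classifies steps as
valid/invalid. Training examples come from phantoms: valid steps lie on
ground-truth centerlines aligned with the local direction and at least one
step height away from tube endpoints; invalid steps are off-vessel
cylinders (40 %), overshoots past tube tips (20 %), and on-vessel cylinders
with perpendicular axes (40 %). A 0.2 train fraction leaves the bulk for
out-of-sample accuracy reporting.

The step search enumerates the 26-neighbor directions within the turning
cap (default 60 degrees) and a radius grid (0.5-1.5 x the current radius),
and scores each candidate by forest probability minus a weighted
minimal-path-style energy: a curvature penalty `lambdaCurv * f3^2` minus a
centeredness term (minimum ray clearance over the measured radius). If the
best score falls below the stop threshold (0.5) the branch terminates. The
accepted step then takes the *measured* local radius (mean ray distance) —
the score alone cannot identify the radius, since a thin cylinder inside a
thick vessel looks as valid as a correctly sized one — and its endpoint is
recentered onto the centroid of the perpendicular mask cross-section, which
keeps the trace on the medial axis (mean offsets stay below one voxel on
noise-free phantoms).

**Seeds.** With a large-vessel mask present, seeds are placed where
small-vessel components abut it, pointing away — emulating tracking that
starts at the parent-artery origins. On phantoms without a large vessel,
one seed per component is placed at a geodesic endpoint (double
breadth-first search), recentered into the lumen. This phantom-mode seeding
is a documented deviation from anatomical seeding.

**Bifurcations.** At each accepted step a spherical shell (radius 2 x the
local radius) is intersected with the mask; 26-connected components on the
shell are counted, the one pointing backwards is the inflow, and two or
more outgoing components signal a bifurcation. Because the shell fires up to
a shell radius early and the perpendicular cross-section only splits
*after* the junction, the junction itself is localized as the clearance
maximum: candidate points along the incoming axis are recentered and the
point with the largest inscribed sphere wins (junctions are locally the
thickest points of the tree). The branch terminates there and each outgoing
component spawns a child of order parent + 1, with its own measured radius.
Children are exempt from the revisit filter for their first two steps, since
they necessarily re-cross the claimed junction region. Visited-voxel
claiming plus the per-branch and per-tree caps guarantee termination.

The shell parameters (factor 2, thickness ~0.75 voxel) and the energy
weights (`lambdaCurv = 0.5`, `lambdaEnergy = 0.2`) are configuration
defaults chosen at LSA scale and exposed in `trackingConfig()`. The forest
sees single-step features, not a history window.

## Screening

Three rule-based filters, applied in order (`screenBranches()`), then branch
orders are recomputed from the surviving parent links:

1. **Duplicates** (repeated tracking): if one branch's points lie within a
   voxel of another's for at least `overlapThreshold` (0.7) of their number,
   the longer branch is kept (earlier id on ties); a partial retracer's
   novel tail is re-attached as a child at the divergence point, so true
   secondary branches discovered via a duplicated stem survive.
2. **Artifacts**: branches lying at least half inside the artifact zone
   (large-vessel mask dilated by 1 mm) are removed when also implausible —
   tortuosity (path/chord) above 2.0 or mask support below 0.8.
3. **Noise**: branches shorter than 2 mm or with mask support below 0.8 are
   removed; children re-parent to their grandparent, and orphaned short
   remnants are dropped.

The filters only remove or re-link branches, never add points, and the
composite is idempotent (verified over seeded fixtures). The rules and
thresholds operationalize the three stated failure modes; they live in
`screeningConfig()` and are serialized with pipeline results for audit.

## Modeling and morphometry

Screened tracks are interpolated by piecewise third-order Bezier segments
with Catmull-Rom tangents: the curve passes through every tracked point
with C1 joints. Arc length uses adaptive polyline refinement (relative
tolerance 1e-4); curvature comes from the analytic first and second
derivatives. Diameters are measured per arc-length station as the
equivalent-circle diameter `2*sqrt(A/pi)` of the mask cross-section in the
plane perpendicular to the local tangent (nearest-neighbor sampling at
half-voxel resolution, connected region containing the centerline point),
median-filtered with window 3; mask-based cross-sections were chosen over
intensity full-width-half-maximum because tracking operates on the mask
(FWHM could be added as an alternative). Stations outside the mask inherit
the nearest in-mask diameter and are flagged.

`morphometry()` reports one row per branch (order capped at 3 for
reporting, as primary/secondary/tertiary) with length, mean/min/max
diameter and mean curvature, plus per-order counts.
`compareModels()` matches branches greedily by mean closest-point distance
(threshold 1 mm, exposed), samples "key points" at arc-length-proportional
stations including both endpoints — key points are not defined in the
method's public description, and proportional stations make the offset
statistic reproducible and dense — and reports point offsets, signed length
and mean-diameter differences, Pearson correlations, and Bland-Altman mean
difference with 1.96 SD limits. Manual-style per-branch diameters are
summarized as the per-branch mean. Tube meshes for visualization carry the
local diameter as a per-vertex scalar.

## Evaluation metrics

`diceCoefficient()` implements `DSC = 2TP / (2TP + FP + FN)` (empty vs
empty defined as 1). `hausdorffDistance()` is the symmetric max-min
distance between the voxel point sets in physical mm — the printed formula
of the source method typesets summation signs inside the max/min, but its
own `HD = max(h, h)` form implies the standard directed Hausdorff, which is
what both this implementation and the brute-force oracles compute.
`fpFnRates()` reproduces the framework's printed definitions verbatim — FP
over ground-truth *vessel* voxels and FN over ground-truth *background*
voxels, which differ from the sensitivity/specificity convention — and
`conventionalRates()` provides the textbook variants under distinct names.

## The phantom generator

`phantomSpec()` describes bright tubes (polyline control points with
linearly interpolated, possibly tapering radii) on a darker noisy
background, an optional low-order polynomial multiplicative bias field, and
an optional bright large vessel. A voxel is ground-truth vessel iff its
center lies within the local radius of a tube centerline (hard,
unambiguous labels for the metric oracles); intensities are antialiased by
2x-per-axis supersampling, so tube rims show realistic partial-volume
gradation. Noise is additive Gaussian. With no bias field the output is
tagged `standardized` (the generator works directly on the 0-255 scale);
a bias field invalidates that scale, so such volumes are tagged `raw`.

Study conditions: background 60, small tubes 100, large vessel 200 place
the tissue classes around the (80, 120) band. Branching angles are drawn
uniformly from 30-70 degrees, child radii shrink by 0.75 per generation
from an 0.4 mm stem, matching published LSA morphology scales. The noisy
phantom condition uses `noiseSd = 10` (contrast-to-noise 4 for tubes over
background), the value the rendering contract itself is exercised at; the
threshold-baseline superiority property is additionally checked at
`noiseSd = 15`. Training-patch sampling density along vessels is exposed as
a `stride` (default: every vessel voxel is eligible) since the original
protocol does not state it.

What the phantoms do *not* emulate: flow saturation and pulsation physics,
anatomical context (the circle of Willis), intensity inhomogeneity beyond
low-order polynomials, and correlated acquisition noise. Passing phantom
tests therefore demonstrates the machinery recovers known geometry under
controlled degradation — not clinical-grade performance on patient data.

## Problem sizes and numerical choices

The desk-scale study conditions used throughout the tests and the
acceptance script: 50-70 voxel grids at 0.1 mm, an 18-orientation training
phantom, 1,000 training patches (400 positive / 600 negative) at patch 13
with 16 feature maps and 20 epochs, a 500-tree step forest on 1,000 labeled
steps, and 20 seeded screening fixtures. Ties in the greedy branch matching
break toward the first minimum; degenerate inputs (constant volumes, empty
masks, single-class training data) either pass through flagged or raise
errors as documented per function. All randomness flows from one seed
through named substreams (`deriveSeed()`), so every pipeline stage is
individually reproducible and the end-to-end rerun is byte-identical.

## Known limitations

* No direction-cosine handling: grids are axis-aligned, physical
  coordinates are `origin + (index - 1) * spacing`.
* The SP-CNN engine is CPU-bound R; the full 128-map, 25^3-patch
  configuration is faithful but slow to train — the scaled configuration is
  the supported desk setting.
* Tracking assumes the mask is largely connected along a vessel; gaps from
  discontinuous flow signal terminate branches rather than being bridged
  (screening, not inpainting, is the recovery mechanism).
* Anatomical seeding from the internal carotid origins is emulated by
  large-vessel abutment; on data without a bright parent vessel the
  skeleton-endpoint fallback changes where primary branches start.
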