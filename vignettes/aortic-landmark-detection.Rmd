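---
title: "Probability-map detection of aortic landmarks from CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probability-map detection of aortic landmarks from CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortamark)
```

## The measurement problem

Planning a transcatheter aortic valve implantation (TAVI) requires five
anatomical points from a contrast-enhanced cardiac CT: the basal attachment
("hinge") points of the three aortic valve leaflets — left-coronary (LCC),
non-coronary (NCC) and right-coronary cusp (RCC) — and the origins of the
two coronary arteries, the left and right coronary ostia (LCO, RCO). The
three hinge points define the aortic annular plane (AAP) used for device
sizing; the perpendicular distances from that plane to the ostia (the
*coronary heights*) quantify the risk of coronary obstruction. Manual
annotation takes minutes per patient and varies between operators.

`aortamark` implements an automated detection chain built around per-voxel
probability maps: a detector assigns each voxel a probability of belonging
to each of the five landmark classes (plus background), three detectors
tuned to different spatial scales are fused by averaging, and a
deterministic postprocessing step turns each fused class map into one 3D
point. The geometry and statistics layers then derive the clinical
measurements and the agreement statistics used to validate them.

## Pipeline and parameters

An end-to-end run (`runDetection()`) performs, in order:

1. **Isotropic resampling** to 1.0 mm voxels (`resampleIsotropic()`).
   Values are interpolated with a cubic Catmull–Rom spline — an
   interpolating cubic kernel, so lattice-coincident samples are preserved
   exactly — with mirror boundary handling. The output shape is
   `ceiling(extent / target)`, which never crops anatomy; the HU scale is
   untouched.
2. **ROI extraction**: a 128³-voxel cube is cropped around a supplied
   centre (`cropCentered()`). At validation time the centroid of the
   reference landmarks is used, mirroring protocols that centre on the
   annotated ground truth; for unseen patients an explicit `roiCenter`
   must be given — there is deliberately no silent default. Out-of-volume
   voxels are filled with −1024 HU (air).
3. **Intensity normalisation**: HU clipped to [−1024, 2048] and mapped
   linearly to [0, 1] (`normalizeVolume()`). The fixed window keeps
   contrast-enhanced blood (~300–500 HU) and calcium (700–1500 HU)
   separable and is identical across patients.
4. **Per-radius prediction**: one detector backend per sphere-radius tag
   (3, 5 and 7 mm), matching label masks built with those radii
   (`generateSphereMask()`; class codes LCC = 1 … RCO = 5). The
   `DetectorBackend` contract only requires per-class probabilities,
   summing to one per voxel, on the input grid.
5. **Fusion**: the three per-class maps are averaged elementwise and
   renormalised per voxel (`fuseProbabilityMaps()`). Renormalising after
   the mean keeps the result a probability field regardless of the
   backends' calibration.
6. **Postprocessing** (`detectLandmarks()`): per class, voxels with
   p > 0.5 are selected and clustered by single-linkage hierarchical
   clustering with a 1.1 mm Euclidean threshold; from the largest cluster,
   the unweighted centroid of the voxels with p > 0.9 is the predicted
   point.
7. **Geometry** (`deriveMeasurements()`): the AAP is fitted through the
   three predicted hinge points and the two ostium heights are the signed
   perpendicular distances to the plane.

The constants — 1.0 mm target spacing, 128³ ROI, radii (3, 5, 7) mm,
thresholds 0.5/0.9, link distance 1.1 mm, window/stride 64/32 — live in a
single serialisable `RunConfig` object.

### Why single linkage, and why 1.1 mm

A distance-threshold criterion only produces the intended behaviour under
single linkage: two voxels belong together iff they are connected by a
chain of steps each ≤ 1.1 mm. On a 1 mm isotropic grid this is exactly
6-connected (face-adjacency) component labelling, because face neighbours
are 1 mm apart and diagonal neighbours √2 ≈ 1.41 mm. The test suite checks
this equivalence against an independent union-find oracle and a BFS
connected-components oracle on randomized voxel sets. The threshold is
treated as inclusive (a link of exactly 1.1 mm merges); clustering operates
on world-mm coordinates, which coincide with voxel indices at 1 mm
spacing.

Ties for the largest cluster go to the cluster containing the most
probable voxel, then to the one containing the lexicographically smallest
voxel index — both choices are arbitrary but deterministic. If no voxel in
the winning cluster exceeds 0.9, the centroid of the whole cluster is used
and a `fallback` flag is raised in the diagnostics; a class with no voxel
above 0.5 is an explicit failure (an error naming the class), never a
silent zero.

### The surrogate backend

Training a full 3D segmentation CNN is out of scope here; the package
instead ships a *surrogate* backend that emulates a trained three-model
ensemble well enough to exercise every downstream stage. For radius tag
*r*, class *c* scores
$s_c(v) = \exp(-\lVert x_v - \tilde x_c\rVert^2 / (2\sigma^2))$ with
$\sigma = r/2$, where $\tilde x_c$ is the true landmark jittered by
isotropic Gaussian noise (default sd 0.5 mm, drawn independently per class
and per radius tag from the seed); the background scores a constant 0.05,
and probabilities are the normalised scores. The jitter sd controls how
"good" the emulated model is; 0.5 mm gives fused-map localisation errors
around half a millimetre, comfortably inside the accuracy regime reported
for trained detectors, and `jitterSd = 0` gives a noise-free oracle whose
residual error is pure discretisation (≤ half a voxel diagonal).

Because the surrogate's output depends only on world coordinates and its
seed, whole-volume prediction and sliding-window prediction (64³ windows,
stride 32, overlap-averaged) are provably identical; the pipeline
therefore predicts whole-volume by default and the equivalence is a test.
A trainable backend can be added by implementing one S4 method
(`predictProbabilities`) against the same contract.

## The phantom generator

Real TAVI CT cannot ship with a package, so `generatePhantom()` renders a
synthetic contrast-enhanced aortic root with exactly known landmarks. All
random parameters are drawn once from a seed into a `PhantomSpec` and
recorded there, making every rendering bit-reproducible. Defaults emulate
clinical acquisitions:

* grid 160³ at 0.7 mm (so 1.0 mm resampling is genuinely exercised;
  clinical in-plane pixel spacing is ≈0.5 mm and slice thickness ≈0.8 mm);
* annular radius ~ U(10, 14) mm (20–28 mm diameter), annular plane tilted
  up to 20° from axial at a random azimuth;
* hinge points on that circle at 90°/210°/330° ± U(−10, 10)° jitter —
  exactly coplanar and equidistant from the centre by construction;
* ostium heights ~ U(10, 20) mm perpendicular to the plane, bracketing
  typical clinical medians (≈16–17 mm), at in-plane radial offsets of
  0.55–0.85 annular radii above their cusps;
* contrast-filled lumen ~ N(350, 30) HU inside a tilted tube with a sinus
  bulge (1.35 → 1.15 annular radii), soft tissue ~ N(40, 10) HU outside;
* Poisson(3) calcific deposits of U(700, 1500) HU and 1.2–2.5 mm radius
  scattered near the hinge points (aortic stenosis calcification);
* additive Gaussian noise (sd 20 HU) and, when enabled, Gaussian motion
  blur of sd 1.5 mm along one axis.

`generateCohort()` assigns motion blur to 40% of cases and doubled noise
to another 40%, the artefact mix reported for clinical TAVI cohorts, and
writes volumes as int16 HU NIfTI (the clinical storage convention) plus
landmark JSON and a manifest CSV.

What the phantom does *not* model: valve leaflets, anatomically shaped
calcification, coronary arteries (only their ostial positions), metal
artefacts, and contrast-timing variation. Passing the synthetic
end-to-end bounds therefore demonstrates that the *pipeline* — fusion,
clustering, centroid extraction, plane geometry — is correct and
well-conditioned under realistic noise, spacing and geometry; it says
nothing about the accuracy of any particular trained detector on real
patients, which is exactly why the detector is a pluggable contract.

## Statistics

`summarizeDistances()` reports landmark errors as median (LQ–UQ) using
inclusive linear-interpolation quartiles (`stats::quantile` type 7);
quartile conventions differ across software, so the choice is fixed and
tested against a hand-rolled sort-and-interpolate oracle. A Shapiro–Wilk
p-value per group records (non-)normality, which motivates the
nonparametric summaries. `pairedDifferenceTest()` reports mean ± sd of
paired differences with a two-sided Wilcoxon signed-rank p-value (zeros
dropped; exact distribution for n ≤ 25 without ties, else normal
approximation with continuity correction; all-zero differences give p = 1
by convention). `blandAltman()` uses bias ± 1.96·sd (sample sd) limits,
and `correlationR2()` squares the Pearson coefficient. The 0.05
significance convention is recorded in the reports, not hard-coded into
any decision.

## Numerical choices and edge cases

* World frame RAS+ as in NIfTI; 0-based voxel indices; the origin is the
  centre of voxel (0,0,0). NIfTI-1 stores the transform in float32, so
  file round-trips preserve geometry to single precision (~1e−6 relative);
  values round-trip bit-identically at the default float64 datatype.
* Rotation angles compose as R = Rz·Ry·Rx, applied identically to images
  and points (`randomSimilarityTransform()`, uniform ±3% scale and ±3°
  per axis by default).
* Cubic interpolation can overshoot; probability-valued volumes are
  clamped back to [0, 1] after resampling.
* Sphere masks resolve overlaps by nearest landmark centre, ties to the
  lower class code; boundaries are inclusive (≤ radius).
* `ProbabilityMaps` validity checks per-voxel normalisation on a
  deterministic voxel stride (full check up to ~256k voxels) so that
  constructing a 128³ six-class field stays cheap; tests verify the full
  sums independently.
* Degenerate inputs fail loudly: collinear hinge points, landmark sets
  with missing classes, all-background probability maps, empty point sets.

## Problem sizes used in the shipped checks

The synthetic validation used throughout the package documentation runs
100 phantoms at 160³ × 0.7 mm with the default artefact mix and surrogate
jitter 0.5 mm — 500 landmark instances per run. With that configuration
the pooled median error is ≈0.6 mm and no landmark exceeds 4.0 mm;
per-class medians are within ≈0.5–0.8 mm, and predicted ostium heights
agree with truth with r² > 0.95 and Bland–Altman limits within ±1.2 mm
(numbers as computed by `scripts/acceptance.R` and the test suite; they
vary slightly with the seed). Unit tests use smaller grids (41³–96³)
chosen so that every geometric property is exercised without slack.

## Known limitations

* The surrogate backend needs the true landmarks; it validates the
  pipeline, not a detector. Plugging in a trained model is the intended
  path to processing unseen patients, together with an explicit ROI
  centre or a whole-volume sliding window.
* Oblique (non-orthonormal direction) NIfTI volumes are rejected rather
  than silently resliced; gantry-tilt correction and multi-phase (4D)
  series are out of scope, as is full DICOM ingestion.
* `cropCentered()` requires isotropic input — it is a post-resampling
  step by design.
* Sub-voxel accuracy is limited to what an unweighted centroid of
  high-probability voxels can deliver; no continuous refinement is
  attempted.
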