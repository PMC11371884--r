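---
title: "Ray-cast joint-gap features and condylar seating assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ray-cast joint-gap features and condylar seating assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condylecast)
```

## The problem

Three-dimensional virtual surgery planning for orthognathic surgery assumes
that the mandibular condyles sit correctly in their glenoid fossae on the
planning CBCT. When a condyle is displaced ("incorrectly seated"), a
maxillary-first bimaxillary plan inherits the error. `condylecast`
implements an automated screen: paired condyle/fossa label volumes are
converted into a fixed-width vector of joint-gap measurements by ray
casting, and a small feed-forward network labels the joint.

This vignette explains the model, its assumptions, the tunable parameters,
and the numerical and design choices, in the order the pipeline runs.

## Coordinate contract and inputs

All geometry is metric. A `label_volume` stores a 3D integer grid
(0 background, 1 condyle, 2 fossa), a per-axis voxel spacing in mm, and the
world position of voxel (0,0,0); voxel indices are 0-based and address
voxel *centers*, so world = origin + index · spacing. One volume holds one
joint (the upstream segmentation, out of scope here, already localizes each
TMJ). The superior axis — the direction toward the fossa — defaults to the
third array axis and is overridable per file; scanner exports are assumed
axis-aligned, which is why the hemisphere is not re-oriented per patient.

NIfTI files go through RNifti. MetaImage (`.mha`) support is a small
built-in reader/writer: the format is an ASCII header plus a raw block, and
writing spacing/origin as `%.17g` text makes `.mha` the only format here
that round-trips doubles bit-exactly (NIfTI headers are 32-bit float).

## Direction set

The ray directions are `n` quasi-uniform unit vectors on the superior
hemisphere. The default construction is a spherical Fibonacci lattice with
superior components `z_i = 1 − i/n` (uniform in `z` is uniform in area on
the sphere) and azimuths advancing by the golden angle. This was chosen
over a clipped subdivided icosahedron because the lattice realizes *any*
count exactly — the count fixes the classifier input width, so `n = 198`
must be hit exactly, while icosphere subdivision only admits counts
`10·4^s + 2` before clipping (a `clipped_icosphere` construction is
included for tessellation-fidelity experiments). The lattice always
contains the superior pole, so `n = 1` degenerates to the superior axis
without a special case. The 1 mm reference radius of the hemisphere is
carried for provenance only: rays are parameterized by direction, so the
radius cannot affect any measurement.

## Ray casting

From the condyle centroid (mean world coordinate of condyle voxel centers)
one ray is cast per direction using incremental grid traversal
(Amanatides–Woo) with exact face-crossing parameters, implemented in C++
because training re-casts every joint every epoch. Labels are categorical,
so no interpolation is applied: the condyle exit is the *first*
condyle→non-condyle face crossing and the fossa entry the *first*
subsequent crossing into fossa — the minimal-gap reading; later re-entries
are ignored. The gap is the Euclidean distance between the two crossings
(equal to the along-ray parametric distance, in mm). Degenerate inputs are
errors, not silent values: a centroid falling outside the condyle mask
(possible for strongly concave masks) and a casting in which *all* rays
miss the fossa both raise immediately.

Rays that miss the fossa are imputed with a value bounded by the min/max of
that extraction's computed gaps: the midpoint at inference (determinism at
predict time) and seeded uniform draws during training (mild
regularization). The bounds are recomputed per joint per extraction — after
any perturbation — never globally.

### Accuracy and the cap rim

Against the closed-form line–sphere solution on sphere phantoms, measured
gaps are accurate to within one voxel diagonal (≈ 0.69 mm at 0.4 mm
voxels), and halving the voxel size halves the bound. One caveat is
inherent to voxelized set boundaries: where a ray's analytic fossa entry
lies within the rasterization's angular jitter of the fossa cap edge
(about `asin(√3/2 · spacing / R_inner)` ≈ 2.8° at defaults), the voxel-limit
gap is discontinuous — the ray may skim past the jagged rim and enter the
shell visibly later, or miss it entirely. Accuracy statements and tests
therefore apply to rays interior to that margin; rim rays are legitimate
inputs downstream (they are simply features), but no pointwise analytic
comparison is meaningful for them.

## Augmentation

Two mechanisms, both training-only:

* **Mirroring.** Each training joint is flipped along the left–right axis
  once per fold (static doubling, emulating the contralateral joint).
  With the origin kept fixed the flip *is* the reflection through the
  volume's own mid-sagittal plane. Mirrored copies inherit their source's
  fold, so they can never leak into validation.
* **Rigid perturbation.** Every epoch, each training joint's hemisphere is
  translated by Uniform(±2 mm) per axis and rotated by Uniform(±10°) per
  Euler angle (fixed order X·Y·Z), and features are re-cast from scratch.
  Uniform rather than Gaussian sampling because the bounds are stated as a
  range; the Euler order is a fixed convention since only "all directions"
  is specified. The ±2 mm emulates residual centroid uncertainty, the ±10°
  head tilt during scanning. Streams are keyed by (seed, epoch, joint id),
  so schedules replay exactly.

Validation features always use zero perturbation and midpoint imputation:
evaluation must be deterministic, and nothing suggests test-time
augmentation.

## Classifier

Input width `N` (= direction count), hidden layers 192–128–64–32 with
ReLU, then batch normalization (momentum 0.8), then dropout (rate 0.25) —
BN before dropout, after the activation — and a single sigmoid output.
The positive class is the *incorrectly* seated joint throughout, so
sensitivity measures detection of seating problems.

Training: Adam (β₁ 0.9, β₂ 0.999, ε 10⁻⁷) under a cyclic triangular
learning rate between 5·10⁻⁵ and 5·10⁻⁴ with a step size of 2000
*optimizer iterations* (the standard cyclic-LR unit), decaying variant
(`triangular2`: amplitude halves each full cycle) by default with plain
`triangular` available; binary cross-entropy with class weights
`n_total / (2 n_c)` entering as per-sample loss multipliers; batch size
32; 1000 epochs by default. The batch-norm momentum convention is
normative here: `running ← 0.8·running + 0.2·batch` per update, with
ε = 10⁻³ in the variance. Features are fed as raw mm distances; an
optional z-scoring flag exists but is off by default. The loss trace is
returned in full, and training is bit-reproducible from the seed (weight
init, shuffling, dropout masks, and — through the feature provider —
perturbations and imputation all derive named streams from it).

Prediction runs in inference mode (running BN statistics, no dropout) and
thresholds the confidence at 0.2, *inclusive* (≥ 0.2 → incorrect). The low
cutoff trades precision for sensitivity, appropriate for a screening tool
whose false alarms cost a re-read while misses corrupt a surgical plan.

## Label fusion and evaluation

Reader votes (odd count; even counts are rejected rather than tie-broken)
fuse by strict majority; unanimity is tracked because joints without
reader consensus are known to be harder for both humans and the model.
Evaluation uses stratified k-fold splits (per class, a seeded shuffle
dealt round-robin — class counts per fold differ from perfect
stratification by at most one), a pooled confusion matrix over validation
folds plus per-fold matrices, the six standard metrics with zero
denominators reported as undefined rather than 0, and AUC via the
Mann–Whitney rank formulation with midranks (tie-safe), with trapezoidal
ROC integration retained as an independent cross-check. Pooled metrics are
the primary view, with per-fold AUCs and their mean also reported.

`recover_confusion_matrix` inverts rounded sensitivity/specificity back to
the unique integer confusion matrix by exhaustive search — the bridge
between printed 2-decimal metrics and exact counts; it refuses ambiguous
or empty solution sets. Rounding for such comparisons is half-up,
not banker's.

## Synthetic phantoms

Clinical CBCT segmentations are not redistributable, so the generator
builds analytic stand-ins: a condyle ball displaced by a known vector
under a spherical-shell fossa cap (inner radius 7 mm, thickness 2 mm,
polar coverage 80°, condyle radius 5 mm, 0.4 mm voxels — gap 2 mm when
concentric, matching the order of magnitude of a healthy TMJ joint
space). Spheres beat anatomical meshes here because every ray has a
closed-form gap, giving the ray caster an exact oracle.

A dataset draws displacement magnitudes from two disjoint ranges —
0–0.5 mm labeled correct, 1.5–3.5 mm labeled incorrect, ±10% jitter on
both radii — with 85/35 class counts by default. Correct-class directions
are uniform on the sphere; incorrect-class directions are confined to a
30° cone about the inferior axis, the clinical picture of a condyle
sagging out of its fossa. The cone is also geometric necessity: at the
jitter extremes a *laterally* displaced condyle intersects the fossa cap
rim, and overlapping solids have no well-defined gap (both the spec
constructor and the rasterizer reject them). The ground-truth label is
defined by the generating range, mirroring the clinical definition of an
off-center condyle.

What passing tests on these phantoms shows: the geometry pipeline is
metrically correct, the training loop learns, and the full protocol
(mirroring, per-epoch perturbation, stratified folds, pooled metrics)
recovers a *separable* class structure near-perfectly. What it does not
show: performance on real anatomy — real condyles are not spheres, real
displacement distributions overlap, and reader labels are noisy. The
synthetic recovery result is an upper bound and a correctness check, not a
clinical claim.

## Problem sizes and numerical choices

The shipped tests run the full protocol at 120 phantoms × 198 rays with
200-epoch training per fold — enough on the separable synthetic task for
the confidences to polarize so the 0.2 screening cutoff is not the
limiting factor; the 1000-epoch default is intended for real data — and
smoke-scale
variants (10 joints, 64 rays) for determinism checks. Key tolerances:
unit norms and rotation orthogonality to 1e−9; rasterization accuracy to
one voxel diagonal with the cap-rim margin above; AUC cross-checks to
1e−9. Mirror symmetry of features holds to 1e−9 mm rather than bit-exactly
(floating-point summation order in the centroid). Derived seeds are kept
below 2³¹ by a multiplicative hash over (master seed, stream name,
context), so every stream is independent, named, and replayable.

## Known limitations

* Anatomical realism of the phantoms is deliberately absent (no cortical
  thickness, no condylar neck, no noise); the generator cannot emulate
  reader disagreement either.
* NRRD input is not supported (no reader available); convert to NIfTI or
  MetaImage.
* The tessellation of the original 198-vertex reference hemisphere is not
  reconstructable; the Fibonacci lattice is a stated, deterministic
  substitute whose effect on classification is untested.
* Whether cached geometry could replace per-epoch re-casting is untested;
  this implementation re-casts, which is exact but costs most of the
  training time.
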