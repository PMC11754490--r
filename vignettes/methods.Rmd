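---
title: "Coronary calcium scoring on non-gated chest CT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coronary calcium scoring on non-gated chest CT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The Agatston score quantifies coronary artery calcium (CAC) as a
cardiovascular risk marker. It was defined for dedicated ECG-gated cardiac
CT, but non-gated chest CT — acquired in enormous volumes for lung
screening — images the same calcium, blurred by cardiac motion and
embedded in a full thorax with bone, noise and extra-cardiac calcium.
`cacscore` implements an automatic scoring pipeline for that setting. The
organ-segmentation step is deliberately a *contract*: production systems
obtain heart/aorta/fat masks from a trained segmentation model, and any
such model's masks can be injected from files. The package ships a
density/geometry reference backend that fulfils the contract on digital
phantoms, so the entire downstream pipeline is testable without clinical
data or a trained network.

## Coordinate and data conventions

Volumes are 3D arrays `(x, y, z)` with axial slices along the third axis
and **slice 1 the most superior slice** — the territory-splitting rule
iterates craniocaudally, so slice order is semantic. Spacing is
`(sx, sy, sz)` in mm. HU values are clamped to `[-1024, 4000]` after
rescale calibration. Masks always live on the same grid as the volume they
describe; all morphology happens after any grid standardization, so masks
are never resampled independently of the volume. NIfTI volumes are taken
as stored (the package does not reorient from the header); DICOM series
are sorted by descending patient-z so the convention holds by
construction.

In-plane standardization (`standardize_grid`) resizes slices to a square
target (512 is the common clinical format) while preserving physical
extent exactly (`dim × spacing` invariant); HU is interpolated bilinearly,
mask-like content with nearest neighbour. The pipeline config default is
`target_in_plane = NA` (keep the native grid): resampling is a
deliberate, visible choice because it blurs lesion boundaries and
therefore slightly perturbs scores; on phantoms, whose ground truth is
defined on the native grid, it would turn an exact oracle comparison into
an approximate one.

## Preprocessing operators

Morphological dilation/erosion use ball structuring elements under the
metric implied by the connectivity (4/8 in-plane, 6/18/26 in 3D);
millimetre-sized operations (fat shell, corridor closing) use exact
Euclidean balls computed with an anisotropic distance transform, so a
10 mm radius means 10 mm both in-plane (0.7 mm pixels) and across slices
(2.5 mm spacing).

Anisotropic smoothing is Perona–Malik diffusion, applied per axial slice
(slice thickness is several times the pixel size, so inter-slice diffusion
would mix unrelated anatomy). Conductance is `exp(-(g/K)^2)` with
`K = contrast_scale` (default 30 HU), `n_iter = 5`, `step = 0.2`
(stability requires `step <= 0.25`, which also gives a discrete maximum
principle: no new extrema). These are engineering defaults — the method
description names the operator but no parameters. One property worth
stating precisely: Perona–Malik preserves *any* structure whose gradient
is far above `K`, including a single bright voxel. "Edge-preserving noise
removal" therefore means noise-scale fluctuations (tens of HU) are
flattened while high-contrast structure — edges *and* calcium — is kept;
a 500 HU spike is indistinguishable from a 500 HU edge to any local
conductance. Because of this, and so that smoothing can never alter a
score, the pipeline applies diffusion only to the segmentation input;
**scoring always reads raw HU** (config default `smooth_iter = 0`
disables it entirely).

## Segmentation backend and epicardial fat

The reference backend thresholds a soft-tissue window (default
`[-300, 300]` HU — below bone, above lung/fat's lower reaches), labels 3D
components, discards every component touching the body-wall shell (the
chest wall), takes the largest remaining component as the heart and closes
it with a 3 mm ball (which also fills holes left by >300 HU calcium), and
picks the largest remaining component spanning ≥ 3 slices as the aorta.
This is valid on phantoms and phantom-like data; it makes no claim on
clinical CT, where the backend seat belongs to a trained model.

Epicardial fat is recovered from the heart mask: voxels inside the adipose
window (default `[-190, -30]` HU, the literature-standard window; the
method description says only "a fixed range of density") within a shell
`heart ⊕ 10mm \ heart ⊖ 10mm` around the heart boundary, with components
under 10 voxels discarded. An empty result is legal.

## Territory splitting

The aorta's axial cross-section changes shape craniocaudally: circular
(ascending), elliptical, then semi-elliptical before disappearing. Shape
classification uses second-moment axis ratio (elliptical at ratio ≥ 1.25)
and solidity (semi-elliptical below 0.9 — a concave/notched section;
a half-ellipse is convex, so concavity rather than "half-ness" is the
operational criterion). The first elliptical slice is the reference; the
localization slice lies `offset_mm` below (default 10 mm — "a few
millimetres" made concrete; at 2.5 mm slices that is 4 slices). If no
slice classifies elliptical the pipeline can fall back to the
maximum-area aorta slice (flagged in the report) rather than abort
scoring on classifier noise; the fallback is on by default in the
pipeline config and an explicit error when calling the function directly.

No published geometric rule exists for splitting the heart into artery
territories; the package's concrete realization is angular sectors around
the per-slice heart centroid, oriented by the in-plane aorta centroid:
measuring counter-clockwise from the heart→aorta axis, RCA takes
`[-100°, 80°)`, LAD `[80°, 200°)`, LCX the remaining `[200°, 260°)`. The
rule is deterministic, translation-equivariant (both centroids move with
the image) and configurable. Slices above the localization slice
contribute only the AORTA label. The left main artery is not a region;
its calcium falls into the LAD/LCX sectors — a documented limitation.

## Calcium cascade choices

* Threshold **≥ 130 HU inclusive** (the standard Agatston convention; the
  method text writes both "130 as a threshold" and ">130", and the
  inclusive reading is the established one).
* The 2D opening uses a **2×2 square** structuring element: a centred
  radius-1 element erodes a 2×2 component to nothing, which would
  contradict the cascade's sensitivity floor (components ≥ 4 voxels per
  slice must survive). A 2×2 opening removes isolated pixels and thin
  specks while keeping any 2×2 block.
* The volume/peak filter is a **joint (AND)** condition — remove only
  components that are both small (< 3 voxels) and faint (peak < 160 HU).
  The source text is ambiguous between AND and OR; AND is the
  lesion-preserving reading and both thresholds are configurable.
* Bone: components > 10,000 voxels are dilated by 3 voxels in 3D; every
  component the dilation touches is removed with it. Ribs far from the
  spine are smaller than the merge threshold and survive to this point;
  they are eliminated by the cardiac mask instead — which is the intended
  division of labour between the two stages.
* Recovery restores **whole candidate components** that retain at least
  one surviving voxel; components wiped out entirely stay excluded. This
  bounds every stage between the final mask and the candidate mask.
* The cardiac mask is **heart ∪ aorta**: ascending-aorta calcium is
  scored (reported separately, never in the coronary total), and a
  heart-only mask would delete it.
* Attribution is by majority territory label over the component's voxels;
  ties break by overlap count then the fixed order AORTA < RCA < LAD <
  LCX, making reruns deterministic. Components with no labelled voxel at
  all cannot be attributed and are dropped.

## Scoring conventions

Density weights use half-open bins `[130,200) → 1, [200,300) → 2,
[300,400) → 3, [400,∞) → 4` (the published table prints touching
endpoints; half-open is the standard resolution, so 200 HU weighs 2).
The per-component maximum is taken per **slice**-component (classic
Agatston), not per 3D lesion. No slice-thickness normalization is applied
and no minimum-area floor beyond the noise cascade (the classic 1 mm²
floor is deliberately absent). CAC-DRS grades follow 0 / 1–100 / 101–400 /
401–1000 / >1000 on the total rounded to the nearest integer; the source
document's abstract prints different boundaries (1–99, 100–400) than its
methods section — the methods-section mapping is implemented and the
conflict is not silently harmonized. Whether aortic calcium should ever
enter a reported total is left as a reporting decision; the package never
adds it to `total`.

## The phantom: what it does and does not emulate

The generator rasterizes HU compartments — air (-1000), body soft tissue
(40), lung (-800), myocardium (40), epicardial fat (-100), aortic blood
(55), bone (spine 1000, ribs 700) — plus calcium lesions with controlled
per-slice area, slice span, plateau HU and a single peak voxel, then adds
seeded Gaussian noise. Geometry scales with the field of view; the default
grid is 256 × 256 × 60 at (0.7, 0.7, 2.5) mm, chosen so a full pipeline
run takes a few seconds and a 20-phantom validation batch minutes on one
CPU. The aorta follows an explicit shape schedule (circular → elliptical
→ notched/semi-elliptical → absent), so the first elliptical slice is a
spec field the splitter must recover. Lesions sit mid-shell in the
epicardial fat at known angular positions; the spine exceeds the
bone-merge threshold and carries adjacent small flecks the bone stage must
merge away; ribs sit in the chest wall below the merge threshold.

Because per-lesion voxel sets and their noise-free HU are known exactly,
the expected Agatston score is computable analytically
(`expected_agatston`), and on noise-free phantoms the full pipeline must
reproduce it exactly (the tests allow ±1 voxel-area per slice-component).
The phantom does **not** emulate CT physics: no partial-volume blur at
lesion edges, no beam hardening, no motion artifact, no reconstruction
kernel texture, and its organs are ideal ellipsoids/tubes. Passing the
phantom suite therefore demonstrates the correctness of the *algorithmic*
chain — thresholds, morphology, component logic, territory geometry,
arithmetic — not clinical segmentation accuracy, which is a property of
whatever backend fills the segmentation seat.

## Evaluation statistics

Cohen's kappa is unweighted (ordinal grades notwithstanding, matching the
statistic named in the source study; a linear-weighted variant would be a
natural extension). The 95% CI uses the Fleiss–Cohen–Everitt asymptotic
standard error with normal bounds clipped to [-1, 1]; a seeded
subject-resampling bootstrap (2,000 resamples) is provided as a
cross-check and the tests require the two to agree closely. Degenerate
marginals (chance agreement 1) leave kappa undefined and are reported as
`NA` with an explanatory note, never coerced. All per-grade ratios with
zero denominators are likewise `NA`, never 0 — on sparse grades a silent
zero would masquerade as a measured value. Presence/absence metrics
binarize totals at "any calcium" (> 0).

## Problem sizes used in validation

The shipped validation runs 20 randomized phantoms (256 × 256 × 60) for
oracle equality, bone exclusion and lesion retention; a 50-phantom
noise-free batch (25 calcium-free, 25 with lesions in every coronary
artery) for presence/absence; the 25 calcium-free phantoms again at 20 HU
noise for cascade specificity (the noise arm asserts specificity, whose
denominator is the calcium-free group); and 200 random 5×5 tables against
brute-force tallies for the agreement machinery. Sizes were chosen so the
whole suite runs in well under half an hour on a single CPU while keeping
the phantom grid at the default study conditions.

## Known limitations

* The reference segmentation backend is a phantom-grade stand-in; clinical
  use requires injecting masks from a trained model.
* No motion-artifact handling; blurred lesions below 130 HU are invisible
  to any threshold-based cascade.
* LMCA calcium is attributed to LAD/LCX sectors.
* Sector boundaries are a geometric idealization of coronary territories;
  they are configurable but not patient-specific.
* Scores on thin-slice (1.0–2.5 mm) non-gated reconstructions are not
  rescaled to the 3 mm gated convention; absolute values are therefore
  not directly interchangeable with gated scores.
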