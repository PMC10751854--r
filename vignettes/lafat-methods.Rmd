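---
title: "Quantifying left atrial intramyocardial fat from cardiac CT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying left atrial intramyocardial fat from cardiac CT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Epicardial adipose tissue can infiltrate the underlying atrial myocardium,
and the extent of that infiltration in the left atrium (LA) is of interest in
atrial fibrillation. On contrast-enhanced cardiac CT the LA wall is the thin
compartment between two surfaces: the endocardial shell, which bounds the
bright contrast-filled blood pool, and the epicardial shell, which separates
the wall from surrounding epicardial fat. Fat attenuates X-rays less than
muscle, so intramyocardial fat (inFAT) appears as wall voxels of reduced
radiodensity. `lafat` quantifies it in four stages:

1. **Wall thickness (LAWT).** At each endocardial vertex, thickness is the
   Euclidean distance to its projection on the epicardial shell, displayed
   with the conventional colour scale (red < 1 mm, 1 mm &le; yellow < 2 mm,
   2 mm &le; green < 3 mm, 3 mm &le; blue < 4 mm, purple &ge; 4 mm; boundary
   values fall in the upper bin).
2. **Wall mask.** A voxel belongs to the wall when its center lies inside the
   epicardial and outside the endocardial shell. The LA appendage, the mitral
   valve and the pulmonary veins beyond 5 mm from their ostium planes are
   excluded.
3. **Fat classification.** Wall voxels with HU in [-194, -5] are inFAT;
   [-194, -50] is dense inFAT and (-50, -5] fat-myocardium admixture
   (a partial-volume mixture of fat and myocytes). Volumes are voxel counts
   times the voxel volume; per-class mean HU is the arithmetic mean. Six
   normalised metrics divide each class volume by the LA cavity volume and by
   the segmented wall volume.
4. **Regional distribution.** The epicardial shell is parcellated into 19
   anatomical segments; each segment reports its inFAT volume, its share of
   total inFAT (relative inFAT percentage) and its share of total wall
   volume (regional volume percentage).

A cohort layer compares the per-patient metrics across control, paroxysmal
AF and persistent AF groups with the standard battery: Shapiro-Wilk-gated
descriptive summaries, one-way ANOVA or Kruskal-Wallis omnibus tests,
Bonferroni-corrected pairwise post-hoc tests, chi-squared for categorical
variables, and BMI-adjusted ANCOVA.

## Key parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `infat_low` | -194 | HU | lower inFAT bound |
| `dense_high` | -50 | HU | dense / admixture boundary |
| `infat_high` | -5 | HU | upper inFAT bound |
| `exclusion_mm` | 5 | mm | retained PV collar beyond the ostium plane |
| `antrum_mm` | 5 | mm | geodesic antrum width on the atrial body |
| `band_mm` | 8 | mm | carina / ridge geodesic half-width |

The HU thresholds and the 5 mm PV exclusion are the published parameters and
are echoed into every report (`config_echo.json`) as an audit trail.

### The -50 HU boundary

Both fat subranges are conventionally quoted inclusive at -50 HU, which
would double-count that value. `lafat` assigns -50 HU to the *dense* class,
making the subranges an exact partition of [-194, -5]: the conservation
identity `inFAT = dense + admixture` then holds as exact voxel arithmetic on
every input, which the tests assert. Only voxels with HU exactly -50.0 are
affected; on noisy data this is a measure-zero choice.

## Geometry engine

No mesh toolkit is assumed: the package carries its own small geometry
kernels (C++):

* **Scanline voxelization.** Shell meshes are mapped into voxel-index space
  and rays are cast along the x index axis; crossing parity classifies every
  voxel center in a row at once. A fixed sub-voxel jitter (~1e-4 voxel)
  keeps rays off vertices and edges, making the watertight test exact and
  deterministic. An independent generalised-winding-number oracle verifies
  the voxelizer voxel-for-voxel in the tests.
* **Point-to-triangle distance** (exact closest-point, used for LAWT), with
  centroid-radius early rejection.
* **Ray-parity point-in-mesh** for shell containment validation.

"Projection to the epicardial shell" is implemented as the nearest point on
the epicardial surface. A `normal_ray` mode (first intersection along the
outward vertex normal) is provided; both coincide on concentric shells. The
nearest-point definition is symmetric, robust to normal noise, and makes the
minimum distance unique even in medial situations where the foot point is
not. Mean LAWT is area-weighted by barycentric vertex areas, so it is
invariant to mesh density.

The LA cavity volume is mesh-derived (divergence theorem on the endocardial
shell) rather than voxel-derived: it is a property of the shell and is then
independent of the voxel grid.

## Parcellation

The published 19-segment scheme is semi-automatic, with manual anchors in
commercial software. Here the manual step is externalized into the landmark
file (four PV ostium loops, appendage ostium loop, mitral annulus loop,
explicit ostium planes) and everything downstream is deterministic:

* **Bands.** PV antra are the retained 5 mm ostium collars plus faces within
  5 mm geodesic distance of the ostium loop (Dijkstra on the mesh edge graph
  with exact edge lengths); the carinae are the bands within 8 mm of both
  ipsilateral PV loops; the ridge is the band between the LSPV antrum and
  the appendage boundary.
* **Wall sectors.** The remaining faces are classified in an anatomical
  frame (left / posterior / superior axes taken from the landmark file, or
  derived from the loop geometry): the posterior wall is bounded by the
  superior edges of the superior PV ostia, the inferior edges of the
  inferior ones and the medial edges of the two PV columns; the floor lies
  below it down to the annulus; the septal wall is medial-right; the left
  lateral wall lies between the anterior wall and the left floor; the
  anterior wall (including the roof) takes the rest.
* **Sub-splits.** The internal split lines of the posterior (1-4) and
  anterior (8-11) walls are not defined beyond a figure in the source
  scheme; a 2x2 equal split at the region midlines (and a left/right floor
  split) is adopted as this package's convention.

Because every face is assigned by a total decision rule, the labels
partition the retained shell by construction — there is no flood fill and
hence no leak failure mode. All ingredients (geodesic distances, frame
axes, loop coordinates) are equivariant under rigid motion, which the tests
assert by rotating mesh + landmarks together. Comparisons against derived
boundaries use a 1 nm tolerance: symmetric meshes can place face centroids
exactly on a boundary, where raw floating-point comparison would not be
rotation-stable.

Wall voxels inherit the segment of the nearest labeled epicardial face
center (ties to the lowest face index), so segment wall volumes sum exactly
to the total wall volume.

## The synthetic phantom generator

Patient scans are not distributable, so validation runs on phantoms with
known ground truth. Three shapes are provided, all star-shaped about the
origin: concentric spheres, ellipsoid shells and an LA-like geometry
(ellipsoid body ~30x28x26 mm, four posterior PV funnels of ~6 mm radius and
12 mm length, an antero-superior appendage stub, and a mitral annulus
marker). HU levels default to contrast blood pool +350, myocardium +40,
epicardial fat -100, air -1000, with additive Gaussian noise (default SD
10 HU) — typical CT angiography values; the published analysis constrains
only the fat ranges. A 3 mm epicardial fat layer outside the epicardial
shell verifies that extra-shell fat is never counted.

Tissue compartments are voxelized from the shell meshes — the same geometry
the mapping stage receives, mirroring the clinical situation where the wall
is shell-defined — while the analytic surfaces provide ground-truth volumes
(e.g. a 20 mm sphere cavity is exactly 33.51 mL) and exact membership
oracles. The voxel grid is centered so that voxel centers sit at
half-integer multiples of the spacing: no center can fall exactly on an
integer-radius sphere, which keeps boundary classification unambiguous.

Fat deposits grow by accreting wall voxels in order of distance from a seed
voxel (equivalent to breadth-first ball growth in this geometry), restricted
to voxels at least 0.6 voxel clear of either shell and preferring the target
segment, so blobs are connected, compact and contained. The recorded true
volume is the voxel count times the voxel volume (within one voxel volume of
the request). Default deposit HU ranges are dense U(-85, -70) and admixture
U(-30, -22), centred near the per-class mean radiodensities reported for
this tissue (~-77 and ~-23.5 HU). The admixture band is only 45 HU wide, so
a deposit cannot sit 3 noise SDs from both of its boundaries at 10 HU noise;
the defaults keep ~2 SDs of clearance, for which the expected
misclassification leak is ~1-3% of deposit volume — well inside the 5%
recovery tolerance the tests use. A single seed fixes noise, deposit HU and
cohort draws, making every phantom bit-reproducible.

The cohort generator draws per-patient metric tables from per-group
distributions: volumes are log-normal parameterised by group medians and
IQRs, radiodensities and covariates Gaussian, with the default effect
specification encoding a 30/30/20 three-arm cohort in which persistent AF
carries the highest fat burden, controls the lowest, and controls have lower
BMI. A null specification (all groups sharing the control distributions) is
used for type-I-error calibration.

**What the phantoms do not emulate:** CT physics (beam hardening, motion,
streak artifacts), anatomically realistic atrial shape variation, spatially
correlated noise, and the partial-volume blur of a real point-spread
function. Passing the phantom suite therefore demonstrates correctness of
the geometry, classification and statistics, not robustness to acquisition
artifacts; voxel-center membership with no sub-voxel fraction integration is
the documented counting rule, as in the source analysis, where partial
volume is an interpretive concept rather than an algorithmic correction.

## Statistics

Normality is gated per group by Shapiro-Wilk at 0.05 (the dichotomy is
stated in the source methodology without naming a test; the gate is
overridable per metric). Pairwise post-hoc tests after Kruskal-Wallis are
two-group Kruskal-Wallis tests — equivalent to Mann-Whitney up to tie
handling — matching the stated wording rather than Dunn's test, with
Bonferroni multiplier 3 capped at 1. ANCOVA is `metric ~ group + BMI` with
type-II sums of squares (`car::Anova`); a zero-variance covariate is dropped,
reducing the model exactly to one-way ANOVA, and covariates collinear with
the group factor raise an error. Calibration is asserted empirically: the
Kruskal-Wallis type-I error over 2000 seeded null cohorts of n = (30, 30, 20)
must lie in 0.05 +/- 0.02.

## Numerical conventions and degenerate inputs

* Voxel indices are 0-based and map to voxel *centers* through the NIfTI
  affine; all geometry I/O is in mm world coordinates.
* Meshes are validated as closed 2-manifolds and re-wound to outward
  orientation (positive enclosed volume) on read.
* Coincident shells are legal (zero thickness, empty wall); an endocardial
  vertex strictly outside the epicardium is a geometry error naming the
  vertex.
* An empty fat class reports volume 0 and *missing* mean HU (0 HU is a valid
  tissue value); zero total inFAT makes relative percentages missing with a
  warning; an empty wall mask is an error for regional volume percentages
  and for normalisation.
* Walls thinner than two voxels warn (partial-volume regime) but proceed.

## Problem sizes

The test and acceptance workloads use a 0.5 mm grid for the concentric
sphere analyses (~10^6 voxels), a 1.0-1.25 mm grid with subdivision-5 shell
meshes (20480 faces) for the LA-like phantom, and 2000 replicates for the
null-calibration study. These sizes keep every analytic check well inside
its stated tolerance (mesh deviation from the analytic sphere is ~4e-3 mm at
subdivision 5) while the full suite runs in about a minute.

## Known limitations

* The wall sectors rely on a landmark-derived frame; grossly atypical PV
  anatomy (e.g. a common left trunk) would need hand-edited landmark loops.
* Sub-voxel partial-volume fractions are not integrated; thin walls
  (&lt; 2 voxels) under-sample the compartment.
* The epicardial shell is an input: segmentation error propagates directly
  into the fat metrics, as it does in the clinical pipeline.
* Regional group comparisons average per-patient percentages within groups;
  pooling volumes across patients would weight large atria more and is not
  implemented.
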