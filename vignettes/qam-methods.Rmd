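---
title: "Quantitative ablation margins: model, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative ablation margins: model, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qamr)
```

## The problem

After thermal ablation (microwave or radiofrequency) of a liver tumor, the
single most important determinant of local tumor control is whether the
ablation volume covered the whole tumor with a sufficient rim of necrosis —
the *ablation margin*. The accepted minimal target is 5 mm, with 10 mm
preferred. Conventional assessment compares pre- and post-ablation CT
side-by-side or fused, and reports a margin read off a single 2-D slice at
the largest tumor diameter; that is subjective and reader-dependent.

`qamr` implements a volumetric, quantitative alternative. Given binary
segmentation masks of the tumor and the ablation zone — co-registered and
resampled to one voxel grid — it measures a signed Euclidean distance from
*every* tumor-surface voxel to the ablation boundary and reports the whole
distribution: percentiles, traffic-light coverage classes, and a histogram in
1 mm substrata. A dedicated algorithm handles subcapsular tumors, for which a
circumferential margin is physically impossible.

## The computation pipeline

For one case the pipeline is:

1. **Load** tumor, ablation and (optionally) liver masks from NIfTI; enforce
   the registration contract (identical grid shape and voxel spacing; no
   resampling is ever performed). Values are thresholded at `> 0.5`, and
   genuine label images are rejected as non-binary.
2. **Crop** all masks to the union bounding box plus a background pad
   (default 2 voxels). This is purely a speed optimization: with a pad of at
   least 2 voxels the surface extraction and all relevant distances are
   realized inside the box, so the output is bit-identical to the uncropped
   computation (this is asserted by tests, not just claimed).
3. **Extract surfaces** as the mask minus its morphological erosion by the
   face-connectivity (6-connected) structuring element, with out-of-grid
   treated as background. This contour is exactly one voxel thin and, unlike
   26-connected erosion, retains corner voxels along sharp edges.
4. **Signed distance map** of the ablation: an exact Euclidean distance
   transform (see below) signed negative on ablation background.
5. **Subcapsular exclusion** (optional): tumor-surface voxels strictly closer
   than a threshold (default 5 mm) to the liver surface are removed from the
   distribution — from the *denominator*, not set to zero.
6. **Margins**: the signed map sampled at the remaining tumor-surface voxels.

All distances are voxel-center to voxel-center, in millimetres, with full
support for anisotropic spacing; there is no sub-voxel surface
interpolation. Margins are therefore lattice-valued (square roots of
weighted sums of squared integers), which matters when comparing summaries
across percentile conventions.

## The distance transform

No installed R package offers a 3-D exact Euclidean distance transform with
anisotropic sampling, so `qamr` implements the separable lower-envelope
algorithm (Felzenszwalb–Huttenlocher) on squared distances in C++. It is
*exact* — not a chamfer approximation — and the test suite verifies it
voxel-for-voxel against an all-pairs brute-force oracle on dozens of random
blob cases, isotropic and anisotropic, asserting equality rather than
tolerance. The tests use dyadic voxel spacings (0.5, 0.75, 1.25, 2.5, 3 mm —
typical CT values), for which the distance arithmetic is exact in binary
floating point; that is what makes the invariance assertions (cropping,
whole-voxel translation, axis mirroring, spacing covariance) meaningful at
the bit level.

## Sign conventions: two readings of "distance to the ablation"

Outside the ablation the margin is unambiguous: the negative distance to the
nearest ablated voxel. Inside, two conventions coexist in the field, and
`qamr` implements both via the `interior` argument:

* `interior = "surface"` (default): distance to the nearest
  ablation-*surface* voxel. The contour is the zero set, so a tumor surface
  that coincides with the ablation surface yields margins of exactly 0, and
  every margin equals the minimum surface-to-surface distance. This is the
  convention under which the brute-force oracle equivalence and the
  closed-form concentric-sphere limit hold exactly.
* `interior = "background"`: distance to the nearest *non-ablated* voxel
  (the classic signed distance transform). This reads the interior margin as
  the depth of necrotic tissue between the tumor boundary and untreated
  tissue; contour voxels then carry one voxel step rather than 0.

The two differ by roughly one voxel inside the ablation and are identical
outside. The published reference distributions for the sphere phantoms
shipped with this package are reproduced exactly under `"background"`
(see below); the package default remains `"surface"` because its zero-set
semantics (coincident surfaces give zero margins) compose more cleanly
with surface-distance oracles. The same convention switch applies to the
liver distances of the subcapsular exclusion.

## Subcapsular tumors

A tumor abutting the liver capsule cannot have a 5 mm margin toward the
capsule, so an unadjusted margin distribution under-reports the achieved
coverage. The exclusion algorithm removes from the analysis every
tumor-surface voxel strictly closer than `exclusion_threshold` (default
5 mm, configurable to the treatment target) to the liver surface.
"Strictly" resolves the boundary case at exactly the threshold distance,
which lattice distances rarely hit. Excluded voxels are dropped from the
denominator — class fractions and percentiles are computed over included
voxels only — rather than recorded as zero-margin, since keeping them at 0
would deflate the distribution with values that carry no information about
coverage. The liver segmentation should extend at least the threshold
distance beyond the tumor; violations produce a warning. A tumor lying
entirely within the exclusion shell (e.g. a sub-5 mm subcapsular lesion)
raises a structured error rather than returning an empty distribution:
for such lesions the metric is simply not applicable, a documented
limitation of the approach.

## Reporting

`summary()` reports the minimum, quartiles and maximum of the margins, the
three traffic-light classes — orange `x < 0` (uncovered), yellow
`0 <= x < 5` (covered, insufficient margin), green `x >= 5` (sufficient) —
and the substrata histogram with bins of 1 mm centered on integer
millimetres (`[k - 0.5, k + 0.5)`). Class bounds, bin width and the
percentile method (linear interpolation, the default, or nearest rank) are
configurable. Class fractions are always computed from raw margins, never
aggregated from bins, because the bins at 0 and 5 mm straddle the class
boundaries.

Percentiles can optionally be computed at a quantized reporting resolution
(`quantize_mm`). The reference tables for the sphere phantoms report their
quartiles and maximum at the 1 mm substrata resolution while printing the
raw minimum at two decimals; `summary(fit, quantize_mm = 1)` reproduces
that behavior. Raw percentiles remain the default.

For 3-D review, `project_margins()` colors every ablation-surface voxel
with the margin of its nearest included tumor-surface voxel (spacing-aware;
ties resolved to the smallest margin, so uncovered tumor always shows
through), and `write_surface_vtk()` exports the result as legacy ASCII VTK
polydata with `qam_mm` and `qam_class` point data. The projection rule is a
definition made by this package: the projection used in published figures
of this metric is not specified mathematically, and nearest-included-voxel
assignment with pessimistic tie-breaking is the choice that makes orange
surface regions correspond to actually uncovered tumor.

## The sphere phantoms

Because clinical masks cannot ship with a package, validation rests on
programmatically generated sphere phantoms: a voxel is foreground iff its
center lies in the closed ball (sizes are diameters; centers in physical
mm). Two named cases reproduce the published reference outputs of this
metric:

* **T1.6** — a 10 mm tumor, 15 mm ablation displaced in x and y, on a 1 mm
  isotropic 64³ grid; 222 tumor-surface voxels, partially uncovered.
* **T2.2** — a 10 mm subcapsular tumor internally tangent to a 40 mm liver
  sphere, fully covered by a 15 mm ablation shifted 1.5 mm away from the
  capsule.

The reference description of T1.6 states a shift of "5 mm in x and y";
taken literally (offset (5,5,0), norm 7.07 mm) this contradicts the
reference table for the case, whose minimum of −2.23 mm and negative-class
fraction of 27.93 % require a net center offset near 4.2 mm. An exhaustive
search over offsets (0.125 mm steps) and distance conventions shows that an
offset of exactly **(3, 3, 0) mm** with `interior = "background"` reproduces
the published distribution *exactly* — all three class percentages
(27.93 / 62.16 / 9.91 = 62/138/22 of 222 voxels) and the minimum −√5 — and
that no offset does so under the surface convention. The T2.2 geometry was
pinned the same way: the published percentages (98.2 → 95.88 and
1.80 → 4.12) correspond to exactly 4 voxels at ≥ 5 mm and 125 of 222
excluded, which the tangent liver sphere with a 1.5 mm ablation shift
reproduces exactly; the split is robust over liver diameters from 25 to
66 mm, and 40 mm is used. These pinned values are the package defaults for
the two named phantoms and are asserted in the acceptance tests.

```{r t16}
fit <- qam(phantom_case_T16(), interior = "background")
summary(fit)
```

## What the phantoms do and do not show

The sphere phantoms exercise every code path — partial coverage, full
coverage, exclusion, anisotropy (in the blob tests) — with analytically
checkable geometry. They do not emulate irregular clinical ablation shapes,
segmentation noise, registration error, or the tissue shrinkage that
follows microwave ablation; passing them demonstrates correctness of the
geometry and bookkeeping, not robustness to imperfect clinical input. In
particular, registration accuracy is a prerequisite of the metric, not
something it can detect.

## Numerical and design choices

* **Foreground threshold** `> 0.5` after load: robust to float-stored masks
  while rejecting genuine label images.
* **Out-of-grid is background** everywhere; the crop pad of ≥ 2 voxels makes
  cropping provably output-invariant.
* **0-based indices** in all file outputs; R-internal indices are 1-based.
* **Ties and zeros**: a tumor-surface voxel on the ablation contour gets +0
  (only background voxels are negated) and falls in the `[0, 5)` class.
* **Percentile method**: linear interpolation between closest ranks by
  default, matching the common default of scientific computing
  environments; nearest-rank is available because lattice-valued data make
  the choice visible.
* **Problem sizes** in tests: blob oracle cases up to 32³ voxels (50 seeded
  cases), phantom grids 64³. These sizes keep the whole suite under a
  minute while the oracle remains a genuinely independent O(n·m)
  computation.
* **Determinism**: every computation is deterministic given inputs and
  configuration; the only randomness in the package is the seeded blob
  generator for tests.

## Limitations

* Margins are voxel-center distances; sub-voxel (mesh-based) surface
  distances are out of scope by design.
* The exclusion volume addresses the liver capsule only; an analogous
  exclusion near major vessels (heat-sink effect) would be a future
  extension.
* Very small subcapsular tumors (< 2× threshold) cannot be scored at all —
  the all-excluded error documents this rather than silently returning
  nothing.
* The package does not register, fuse or segment images.
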