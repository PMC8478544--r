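---
title: "Segmenting and quantifying atherosclerotic plaque in contrast-enhanced microCT: methods and design"
author: "aortamorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting and quantifying atherosclerotic plaque in contrast-enhanced microCT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortamorph)
```

## The problem

Atherosclerosis studies in hyperlipidemic mouse models (classically the
ApoE-knockout on a high-fat diet) need plaque burden measured along the whole
aorta. Histology is the reference but is destructive, slow, and samples the
vessel sparsely. Ex vivo microCT of phosphotungstic-acid (PTA) stained aortas
gives an isotropic three-dimensional attenuation map (voxels of about 10 µm,
values in linear attenuation, cm⁻¹) in which arterial wall, plaque, and lumen
are separable by attenuation: PTA renders the dense wall strongly radiopaque,
plaque intermediately, and the empty lumen remains dark.

`aortamorph` implements a semiautomatic five-step workflow over such volumes:

1. **Manual contouring.** The operator draws the outer aortic contour on a
   sparse set of axial slices (typically ~10 over the specimen). Everything
   downstream is automatic except an optional lumen check.
2. **Wall/lumen segmentation.** A fixed threshold µ = 6.0 cm⁻¹ inside the
   interpolated region of interest (ROI) drafts the wall; the ROI's inner
   boundary layer closes gaps; the cavity inside the closed boundary is the
   lumen.
3. **Manual lumen verification**, exposed here as scripted voxel-patch edits.
4. **Plaque segmentation.** Gaussian smoothing (σ = 0.8 voxel, kernel
   radius 1) followed by a 2.0 cm⁻¹ threshold inside the lumen, refined by
   morphological opening (radius 1, minimum component volume 2% of the
   total), then closing (radius 3). Lesions are the plaque voxels in face
   contact with the wall.
5. **Quantification.** Volumes by voxel counting; surfaces by iso-surface
   triangulation; wall thickness by a distance-transform local-thickness
   algorithm; per-slice stenosis and lesion length.

The scalar outcomes follow the ratio definitions

$$\mathrm{plaque\ volume\ fraction\ (\%)} = 100\cdot\frac{V_{plaque}}{V_{lumen}},\qquad
\mathrm{lesion\ surface\ fraction\ (\%)} = 100\cdot\frac{S_{lesion}}{S_{lumen}},$$

and per axial slice

$$\mathrm{stenosis\ (\%)} = 100\cdot\frac{A_{plaque}}{A_{lumen}},\qquad
\mathrm{lesion\ length\ (\%)} = 100\cdot\frac{L_{lesion}}{P_{lumen}}.$$

The *lumen* here is the anatomical lumen bounded by the inner wall surface:
it contains the plaque, so all fractions stay within 0–100%. The lesion, a
quasi-planar one-voxel sheet, is assigned half of its triangulated mask
surface (one side only).

## Conventions and the grid contract

* Axis 1 of every array is the axial (cranio-caudal) axis; a "slice" is a
  plane perpendicular to it.
* Voxels are isotropic; physical position = 0-based voxel index ×
  `voxel_size` + origin (voxel-center convention).
* Attenuation is always in cm⁻¹. `read_volume(units_scale = )` is the single
  calibration point: integer-encoded scanner exports are mapped to cm⁻¹ at
  load time and every threshold downstream assumes calibrated values.
* Threshold comparisons are inclusive (`>=`), used consistently for both
  thresholds.

## Parameters

All tunables live in `seg_params()`; the defaults are the workflow's
published operating point and are recorded in every run manifest.

| parameter | default | unit | role |
|---|---|---|---|
| `wall_threshold` | 6.0 | cm⁻¹ | wall draft threshold inside the ROI |
| `shell_erosion` | 2 | voxel | in-plane ROI erosion; the residue closes wall gaps |
| `lumen_close_distance` | 5 | voxel | closing radius removing plaque-induced lumen voids |
| `plaque_sigma` | 0.8 | voxel | Gaussian width before the plaque threshold |
| `plaque_support` | 1 | voxel | kernel truncation radius (3³ kernel, renormalized) |
| `plaque_threshold` | 2.0 | cm⁻¹ | stained-tissue threshold inside the lumen |
| `opening_distance` | 1 | voxel | plaque opening radius (removes speckle and the partial-volume rind) |
| `min_component_fraction` | 0.02 | – | components below this fraction of the post-opening plaque volume are dropped |
| `closing_distance` | 3 | voxel | plaque closing radius (fills internal gaps) |

"Distance = n voxels" always means a Euclidean ball of radius n, realized by
thresholding an exact squared Euclidean distance transform, so structuring
elements are isotropic in 3D rather than axis-biased crosses or cubes.

## Algorithmic choices worth knowing about

**ROI interpolation.** Sparse contours become a dense ROI by shape-based
interpolation: each bounding contour is rasterized (pixel centers inside or
on the polygon, even-odd rule), converted to a signed Euclidean distance
field (negative inside), the two fields are blended linearly in fractional
slice position, and the blend is thresholded at ≤ 0. This avoids any vertex
correspondence between slices, is exact on contoured slices, and is monotone:
enlarging both bounding contours can only grow intermediate slices. Linear
blending in slice position is our documented choice.

**The ROI shell is eroded in-plane.** The boundary-closure shell is
`roi \ erode(roi, 2)` computed per axial slice with a 2D disc, not with a 3D
ball. The contours are drawn per slice and the shell must be a ring on
*every* contoured slice; a 3D erosion would consume the first and last two
slices of any ROI outright, capping the vessel and triggering the
degenerate-ROI check on every run. All other morphology is 3D. If the
in-plane erosion empties a slice where the ROI is nonempty, the ROI is too
thin to segment and the pipeline aborts with a degenerate-ROI error rather
than silently producing a shell-only "lumen".

**Lumen extraction and containment.** The cavity is the largest 6-connected
component of `roi \ boundary` (deterministic raster-order labeling, ties to
the smallest label). After void closing, the lumen is re-intersected with
the in-plane-eroded ROI. This guarantees the invariant *lumen never touches
the ROI border* (formally `lumen ⊆ erode(roi, shell_erosion − 1)`) even when
the closing's dilation half would otherwise spill into the shell across a
branch gap.

**Why void filling works — and when it cannot.** A highly stained plaque
core that crosses the wall threshold is carved out of the lumen draft. If
that void is *enclosed* (stained core surrounded by sub-threshold plaque
tissue), a closing of radius 5 fills any void of diameter below 10 voxels.
A hypothetical plaque whose *entire* cross-section exceeded the wall
threshold would leave a boundary-open bite instead, and no closing can fill
a wide bite that is open to the complement — that situation is exactly what
the manual lumen-verification step (step 3) exists for. The `confounded`
phantom level models the enclosable case: a 6.5 cm⁻¹ spherical core inside a
3.5 cm⁻¹ plaque.

**Set-algebra composition.** The aorta mask is `wall_draft ∪ lumen` and the
final wall is `aorta \ lumen` — exact boolean operations, asserted by the
tests, never approximate. Draft voxels inside the lumen (stained plaque
confounded with wall at threshold time) are thereby assigned to the lumen.

**Plaque refinement order.** Opening first (erosion removes the one-voxel
partial-volume rind along the wall and isolated speckle), then the
minimum-volume component filter on the *post-opening* total (26-connectivity,
so thin plaques are not split), then closing. The refined plaque is
re-intersected with the lumen so closing cannot push plaque into the wall.

**Surfaces.** `mask_surface()` triangulates the 0.5 iso-surface with
marching tetrahedra on the translation-consistent Kuhn cube decomposition —
the mesh is closed and 2-manifold by construction (the test suite checks the
Euler characteristic of a digitized sphere is exactly 2). Triangulating the
*raw* binary staircase overestimates a sphere's area by ~27% regardless of
resolution, so the binary field is first smoothed with a σ = 1.0 voxel
Gaussian; at that width the estimator's residual bias on digitized spheres
falls below half a percent and the error decreases with radius (measured
−2.1%, −0.31%, +0.25% at radii 10/20/40 voxels). Objects thinner than the
kernel (for which the smoothed field never reaches 0.5 — e.g. one-voxel
lesion sheets) fall back to the raw binary triangulation, which is accurate
for flat sheets precisely because their facets are axis-aligned. Slice
perimeters use the identical scheme in 2D.

**Wall thickness.** Model-independent local thickness: the thickness at a
voxel is the diameter of the largest sphere that fits inside the wall and
contains the voxel, computed from the Euclidean distance transform with
sphere radii `EDT − 0.5` (center-to-boundary rather than center-to-center)
followed by inscribed-sphere propagation in decreasing radius order. A
one-voxel sheet therefore reports exactly one voxel of thickness, and a
five-voxel slab is recovered within one voxel.

**Per-slice lesion length.** The lumen iso-contour is intersected with a
contact band (lesion voxels dilated in-plane by 1.5 voxels, since the
sub-voxel contour runs about half a voxel outside the outermost lumen
voxels); the summed length of contour segments whose midpoints fall in the
band is the lesion length. This 2D definition is our documented
approximation; a half-annulus plaque yields a lesion length fraction within
a few percentage points of the analytic 50%.

## The synthetic phantom

No scans ship with the package; `phantom_spec()` / `generate_phantom()`
build a curved-tube stand-in with analytic ground truth, and all recovery
claims in the test suite are measured against it.

The phantom is a tube whose cross-section in every axial plane is a circle
(lumen radius 0.25 mm, wall 0.08 mm at 10 µm voxels by default — a mouse
aorta scale), with a straight or arc centerline. Wall-attached plaques are
circular-segment prisms: a plaque of depth *d* occupies the region of the
lumen disc beyond a chord at distance *r − d* from the center, so its
cross-sectional area is the closed-form circular segment
$A = r^2\arccos(h/r) - h\sqrt{r^2-h^2}$, $h = r - d$, and its volume is the
axial integral of that area (exact for constant depth, trapezoid-integrated
at 1/512 resolution for tapered depth). Attenuation classes (background 0.2,
lumen 0.5, plaque 3.5, wall 8.0 cm⁻¹) straddle the two thresholds; they are
synthetic fixture constants, not measured PTA values. Partial volume is
emulated by Gaussian blur, noise by additive i.i.d. Gaussians with a fixed
seed; ground truth is the *pre-blur* crisp geometry, so recovery errors
honestly include partial-volume effects. Branch ostia are modeled as angular
wall gaps in the attenuation image only (the anatomical ground-truth wall is
intact).

`phantom_suite()` pins five documented difficulty levels with fixed seeds:
`clean`, `blurred` (σ = 0.8), `noisy` (σ = 0.8 plus noise sd of 5% of the
wall attenuation), `branch` (60° gap closed by the ROI shell), and
`confounded` (the stained-core scenario above). The test suite requires
clean lumen/plaque volumes within 5% of the closed forms, blurred/noisy
within 10%, a measured-vs-analytic regression over a plaque-depth sweep with
slope in [0.9, 1.1] and r² ≥ 0.95, exactly zero plaque on the plaque-free
tube, and zero lumen leakage on the branch phantom. The per-slice
manual-agreement design (14 sections, three simulated manual repeats with
2 percentage-point noise, r² ≥ 0.9) uses an axially *tapered* plaque: with a
constant-depth plaque every section has the same stenosis and a correlation
coefficient against noisy repeats is undefined by design; the taper gives
the sections the stenosis spread that a real validation set has.

What the phantom does **not** emulate: beam hardening, cone-beam and ring
artifacts, stain diffusion gradients, collapsed or folded specimens,
non-circular cross-sections, and wall-attached plaques whose entire body
exceeds the wall threshold. Passing the suite therefore demonstrates
correctness of the algorithms under the stated imaging model, not
performance on any particular scanner's data.

## Validation statistics

`agreement()` implements the classic method-comparison pair: ordinary least
squares of method B on method A (the reference method on the x-axis — an
explicit convention, since regressing the other way changes the slope) plus
Bland-Altman bias and limits of agreement at bias ± 1.96 sd of the
differences (the multiplier is an argument for labs that prefer exactly two
standard deviations). `paired_pipeline_validation()` averages repeated
manual measurements per slice before comparison, mirroring how repeated
manual contouring is usually consolidated. A one-way ANOVA wrapper
(`group_compare()`) covers simple group contrasts of per-specimen outcomes;
full study-level modeling is out of scope.

## Reproducibility

`run_pipeline()` has no stochastic step: reruns on identical inputs produce
byte-identical CSV reports, and each run writes a JSON manifest with every
parameter and the MD5 checksums of its inputs. The only randomness anywhere
is phantom noise, governed by the seed stored in the `phantom_spec`.

## Numerical edge cases

* Empty drafts pass through refinement as empty; an empty lesion has zero
  surface; empty lumens are a hard error for fractions.
* All closings/openings run in a padded bounding box so structuring elements
  are never clipped at array borders; outside the array, dilation finds
  nothing and erosion sees no background.
* Component labeling is seeded in column-major raster order, so "largest
  component, ties to the smallest label" is deterministic.
* NIfTI stores voxel sizes as 32-bit floats; sizes are snapped to 7
  significant digits on read (mask sidecars carry the exact value).

## Problem sizes

The suite phantoms run at 128³ voxels (1.28 mm³ at 10 µm) — large enough
that a 25-voxel lumen radius and 8-voxel wall are realistically resolved,
small enough that the full acceptance sweep (seven pipeline runs plus the
brute-force oracle comparisons) completes in well under a minute per
phantom on one CPU. Unit tests use 48–96-voxel grids with the same geometry
scaled to a 20-voxel lumen radius.

## Known limitations

* The workflow assumes a *closed manual outer contour* near the true outer
  wall; a margin much larger than `shell_erosion` voxels lets the lumen leak
  between the wall and the shell at branch gaps. The phantom's contour
  generator uses a 1-voxel margin for this reason.
* The wall-thickness map underestimates nominal thickness by up to one voxel
  for even-thickness walls (a property of center-to-boundary distances on a
  voxel grid) and is further reduced near the axial ends of the analyzed
  range, where inscribed spheres are clipped.
* Lesion length is a band-intersection approximation; strongly folded lumen
  contours could over-count contact segments.
* Anisotropic voxels are rejected rather than resampled.
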