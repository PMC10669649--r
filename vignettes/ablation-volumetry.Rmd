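---
title: "Ablation-zone volumetry from serial sections: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ablation-zone volumetry from serial sections: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(necrovol)
```

## The measurement problem

After an ablative treatment (for example an ethanol-gel injection or a
heated probe applied to the cervix), the question is how deep and how large
the induced zone of necrosis is. The organ is cryosectioned serially —
thin sections of thickness $t$ cut at regular intervals, discarding a
spacing $s$ between consecutive sections — and each section is stained
with a viability stain (NADH-diaphorase): metabolically active tissue
turns blue, necrotic tissue and any polymer deposit remain unstained
(white/gray). Bright-field images of the sections are then segmented, and
two endpoints are computed from the per-section necrotic areas $A_i$
(mm$^2$) and the count $N$ of sections containing necrosis:

$$V \;=\; \sum_{i=1}^{N-1} A_i\,(t+s) \;+\; A_N\, t
\qquad\qquad
D \;=\; N\,t + (N-1)\,s .$$

Each of the first $N-1$ sections stands for the full slab of tissue down
to the next section ($t+s$, 0.52 mm at the default $t = 0.02$ mm,
$s = 0.5$ mm); the final section contributes its own thickness only.
Since 1 mm$^3$ = 1 µL, areas in mm$^2$ and lengths in mm give volumes in
µL directly. `stack_geometry()` carries $t$, $s$ and the pixel
calibration; `necrosis_volume()` and `necrosis_depth()` generalize the
printed constants to any geometry.

Two conventions in these formulas were genuinely open and are worth
stating. First, the thickness-only weight is assigned to the *last*
section in sectioning order, exactly as the formula is written; assigning
it to the first instead would change the volume by $(A_1 - A_N)\,s$.
Second, $N$ counts every section whose measured necrotic area exceeds an
inclusion threshold (default 0.01 mm$^2$), contiguous or not; the
threshold suppresses speck-level false positives that would otherwise
inflate $N$ and hence the depth. Both choices are parameters of
`summarize_necrosis()` rather than hard-coded behavior.

### Hemi-section ("top half") endpoints

When only one side of the organ is treated, a fair comparison against a
whole-organ therapy restricts the measurement to the treated half. For
each slice, `top_half_areas()` takes the area centroid of that slice's
tissue mask, draws a horizontal line through the centroid row, and counts
necrotic pixels strictly above it (row 1 renders as the 12 o'clock side).
The centroid is computed per slice rather than from a single reference
section: that makes the split robust to missing or damaged sections, at
the cost of letting the split line move slightly from slice to slice. The
same depth and volume formulas are then applied to the top-half areas. By
construction the top and bottom halves partition the slice's necrotic
area exactly.

### Group comparison

`compare_groups()` implements the unpaired two-tailed t-test used to
compare endpoints between treatment arms. The default is the
pooled-variance Student form, matching a generic "parametric unpaired
t-test"; Welch is available by flag. Because published work often reports
only summary statistics, the function also accepts `list(mean, sd, n)`
per group and computes the t statistic and its two-sided tail directly.
No multiplicity correction is applied.

## Segmentation model

The stain gives three well-separated color populations, and the
segmentation is deliberately simple and auditable rather than learned:

1. **Background**: near-white — HSV-style saturation $\le$ 0.15 *and*
   mean-channel luminance $\ge$ 230 (of 255). Everything else is tissue
   candidate.
2. **Hole filling**: connected components of the non-tissue complement
   that do not touch the image border and are at most `max_hole_area_mm2`
   (default 0.5 mm$^2$) are filled into the tissue mask. The endocervical
   canal, typically several mm$^2$, stays open on purpose.
3. **Speck removal**: tissue components smaller than
   `min_component_area_mm2` (default 0.05 mm$^2$) are dropped. Both area
   parameters are calibrated in mm$^2$ so behavior is resolution
   independent. Labeling is 4-connected (via EBImage).
4. **Color separation**: within tissue, a pixel is *viable* when it is
   sufficiently saturated (s $\ge$ 0.15) and blue-dominant (blue exceeds
   red by $\ge$ 10 of 255); all remaining tissue pixels are *necrotic*.
   The partition `necrosis` $\cup$ `viable` = `tissue`,
   `necrosis` $\cap$ `viable` = $\emptyset$ is enforced by the
   `label_masks()` constructor after every operation.

The original workflow included manual corrections (filling holes,
removing debris, reassigning mislabeled regions). These become
*declarative edits* (`edit_op()`): named actions over closed polygons,
applied in order by `apply_edits()`, persisted as JSON logs
(`write_edit_log()`), and replayable — so the "semi-automated" pipeline
is fully scriptable and every reported number can be reproduced from the
recorded inputs. Degenerate sections (tissue touching the image border)
are kept and flagged, not clipped.

The exact thresholds of the original MATLAB implementation are
unreported; the defaults here were chosen once against the color model of
the synthetic phantoms (below) and are all exposed in `seg_params()`.

## Rigid registration

Serial sections land on slides at arbitrary positions and orientations,
so masks must be brought into a common frame before 3D reconstruction.
Only rigid motion (translation + rotation) is modeled — sections are
fixed tissue, not elastically deformed in-plane to any degree the
endpoint is sensitive to — and rigid maps preserve areas, so
quantification before and after alignment agrees to resampling error
(tested to within 1%).

`estimate_rigid()` is mask-driven (tissue silhouettes, not intensities):

- translation is initialized from the centroid difference at each
  candidate rotation;
- a coarse exhaustive rotation sweep (±20° in 1° steps, on a decimated
  point set) brackets the rotation;
- the orientation difference of the silhouettes' principal axes (central
  second moments) provides a second initializer. This matters because
  consecutive sections differ slightly in size (the organ tapers along
  the sectioning axis), which flattens the IoU-versus-rotation landscape
  into a plateau; the moment orientation is insensitive to isotropic size
  change and stays sharp. The moment initializer is preferred unless the
  sweep clearly beats it;
- local refinement at 0.1° and 0.5 px follows, and is accepted only when
  it improves the overlap score by more than a small epsilon
  (2 × 10$^{-4}$) — a tie-break that keeps the estimate from wandering
  along a flat plateau.

`align_stack()` chains estimates between *neighboring* slices (adjacent
sections are the most similar) to a configurable reference slice
(default: the middle). Drift over the short stacks used here (tens of
sections) stays well within tolerance; slices with empty tissue pass
through with an identity transform and a QC flag. Masks are resampled
nearest-neighbor so labels stay binary; images bilinear. Whether the
original alignment was manual or automatic is not recorded; both the
reference and the search parameters are configurable.

## 3D reconstruction and meshing

`build_volume()` extrudes each aligned necrosis mask along the sectioning
axis by its slab ($t+s$, last slice $t$ only), so the voxel-sum volume is
*identical to the volume formula by construction* — there is exactly one
volume definition in the package. No inter-slice interpolation is
performed: the rendering choice of the original workflow is unrecorded,
and extrusion keeps the rendered volume numerically equal to the reported
one. z = 0 is the first sectioned face.

`extract_mesh()` extracts the 0.5-occupancy iso-surface with a
marching-tetrahedra variant: the occupancy field is supersampled
(`refine` sub-samples per voxel per axis), padded with empty space so the
surface closes, and each cell is split into six tetrahedra sharing the
main diagonal. Compared with classic cubes-based tables this has no
ambiguous configurations, which guarantees a watertight, consistently
oriented surface (verified by edge-pairing and Euler characteristic in
the tests); volumes enclosed agree with the formula volume to well under
5% for smooth shapes. Supersampling sets the resolution floor: with the
default `refine = 2`, an isolated single voxel keeps about 70% (84%
measured for the anisotropic slab voxels used here) of its volume — the
expected shrinkage of midpoint iso-surfaces around point features. The
pipeline meshes full-resolution stacks at `refine = 1`, since those grids
are already finely sampled in-plane and supersampling would multiply
memory eightfold for no volumetric gain. Optional Gaussian pre-smoothing
is provided for visualization only and must not be used for volumetry.

Meshes export as binary little-endian PLY (default), STL or OBJ
(`export_mesh()`), readable by standard viewers. PLY and STL both store
32-bit float vertices, so the two encode identical geometry;
`read_mesh()` round-trips all three.

## The synthetic phantom

`generate_phantom()` renders stacks that emulate the relevant features of
stained cervical cross-sections, with exact ground truth:

- a star-shaped outer boundary (second and third angular harmonics,
  default ellipticity 0.12 and lobe amplitude 0.06, with a mild quadratic
  taper along the stack). The asymmetry is what makes rotation
  *identifiable* for registration; real sections are far less symmetric
  than a circle;
- a central canal hole, and a solid necrotic lesion — cylinder or
  ellipsoid — at a configurable position (default: a cylinder at the
  12 o'clock side spanning slices 4–25, emulating a one-sided injection
  depot);
- an 8-bit RGB color model: blue-dominant viable tissue (62, 78, 168),
  low-saturation light-gray necrosis (202, 200, 206), near-white
  background (250, 250, 250), with additive per-channel Gaussian noise
  (SD 8) clipped to [0, 255]. The exact stain colors of real slides are
  unrecorded; only the ordinal relations (blue-dominance, saturation,
  brightness) matter to the segmentation;
- small unstained voids inside viable tissue and dark specks on the
  background. Voids are rendered but counted as viable in the ground
  truth — they emulate the holes the original workflow filled manually —
  and the generator emits the matching cleanup polygons as replayable
  edits (`ground_truth$edits`);
- per-slice rigid jitter (uniform, default up to 15 px and 8°),
  emulating arbitrary slide placement. Ground truth is defined in the
  unjittered frame; each image is rasterized analytically *in its
  jittered frame*, so truth and image differ only by the recorded
  transform plus noise, with no resampling artifacts. The canvas
  (default 360 px at the 0.05 mm working pixel size) is sized so that the
  jittered section can never clip at the border, which would bias
  silhouette moments.

Identical configuration and seed give bit-identical stacks. The
`phantom_preset()` conditions — `"well_posed"` (moderate noise, voids,
specks, jitter) and `"noise_free"` (all disturbances off) — are the
reference conditions for the recovery tests: 30-section stacks at a
0.05 mm working pixel size, ten seeds, on which the full pipeline must
recover $N$ exactly, the volume within 10% (observed: ~1%), per-slice
areas within 2% on the noise-free variants (observed: exact), and every
injected neighbor transform within 1 px and 1°. The working pixel size is
coarser than a real 2.5× microscope calibration (for which the default
`pixel_size_mm = 0.004` is itself only a placeholder — the true
calibration of the original images is unpublished); rasterization
convergence is covered by dedicated two-resolution tests instead.

What the phantom does *not* emulate: histological texture, stain
gradients and partial staining, out-of-plane distortion, folds and tears,
illumination fields, and lesions with irregular (non-convex) cross
sections. Passing the recovery suite therefore demonstrates the
correctness of the measurement machinery under the stated color model and
rigid-motion assumptions — not segmentation robustness on difficult real
slides, where the declarative-edit mechanism exists precisely to let an
operator correct and document residual errors.

## Numerical choices and degenerate inputs

- Areas are pixel counts × pixel area; no sub-pixel boundary estimation.
- A blank image segments to an empty mask (not an error); empty masks
  yield zero areas, an empty mesh, and $N = 0 \Rightarrow D = 0$, $V = 0$.
- An empty tissue mask makes the hemi-split centroid undefined: the
  top-half area is reported as 0 with a QC flag.
- Registration of an empty mask is an error at the `estimate_rigid()`
  level but a flagged identity pass-through at the `align_stack()` level.
- `compare_groups()` refuses groups of fewer than two values and
  zero variance in both groups; $t = 0 \Rightarrow p = 1$.
- The pipeline writes immutable stage artifacts and returns a cached
  report when re-run on the same output directory without `force`; every
  reported number is recomputable from the persisted per-slice CSV.

## Problem sizes

The test suite exercises 6–10-section stacks for module tests and ten
30-section stacks (360 × 360 px) for the end-to-end recovery suite;
meshing accuracy is checked on cylinder grids at 0.05–0.1 mm pixels.
These sizes were chosen as the smallest that exhibit all the geometric
effects of interest (taper, jitter, chained alignment drift, anisotropic
extrusion); nothing in the implementation is specific to them.
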