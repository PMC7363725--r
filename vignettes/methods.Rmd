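---
title: "Measuring intra-oral surface areas from CBCT-like volumes: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring intra-oral surface areas from CBCT-like volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oralarea)
```

## The measurement model

The quantity of interest is the surface area of the intra-oral cavity,
split into four anatomical regions: the hard palate, the tongue, the
dental hard tissue (crowns in situ plus the alveoli of extracted teeth),
and the remaining mucosa. The measurement chain is

1. **voxel segmentation** of a Hounsfield-unit (HU) volume,
2. **isosurface extraction** to a triangle mesh,
3. **geometric partition** of the mesh faces into the four regions,
4. **area summation** per region, reported in cm².

Each stage is deterministic; the only randomness in the package lives in
the synthetic data generators, which take explicit seeds.

### Voxel segmentation

Air is near −1000 HU, soft tissue near 0–100 HU, cortical bone well above
+300 HU. Two inclusive thresholds — soft tissue at −300 HU, bone at
350 HU — give two nested masks; the *soft* mask (everything ≥ −300 HU)
includes bone, which is deliberate: the surface presented to the oral
cavity includes exposed crowns. Comparison is inclusive (`≥`) because HU
grids are commonly integer-valued and a strict comparison would make the
result depend on representation noise at the threshold itself.

A small Gaussian pre-filter (σ = 0.5 voxel, truncated at 3σ, border
renormalized so constants are preserved) suppresses single-voxel noise
before thresholding. Whether the original workflow filtered the gray
volume or the binary mask is ambiguous; we filter the volume by default
and expose `smooth_mask = TRUE` in `segmentation_config()` for the other
reading, since the choice is a genuine degree of freedom of the method.

Embalmed tissue traps small air bubbles that would otherwise punch
spurious tunnels through the surface. Morphological closing — dilation
then erosion by a discrete Euclidean ball — removes them: any cavity
smaller than the structuring element is filled, while features larger
than it survive (a 5-voxel-radius cavity is reduced to roughly 3 voxels
by the dilation and restored by the erosion). The default radius is
2 voxels = 0.6 mm at the reference 0.3 mm spacing: comfortably above the
sub-millimetre bubbles we model, comfortably below interdental gaps. The
mask is zero-padded by the radius before the operation so closing remains
extensive (never removes foreground) at the grid border.

### Isosurface and area

The mask is converted to a 0/1 field, smoothed, and contoured at level ½
by marching tetrahedra (six tetrahedra per grid cell sharing the main
diagonal; face diagonals agree between neighbouring cells, so closed
masks yield watertight meshes). Vertices are welded on grid edges, which
gives shared connectivity — required later for boundary-loop detection.

Contouring the *raw* binary field overestimates curved areas badly (the
staircase effect: close to +27 % for a 10 mm sphere at 0.3 mm voxels),
so the field is smoothed first. The smoothing width is specified
**physically** (default σ = 0.3 mm, i.e. one voxel at the reference CBCT
spacing) rather than in voxels. The reason is a trade-off measured on
analytic solids: a width of one voxel *at any spacing* nails curved
surfaces but, at coarse spacings, rounds sharp edges so much that a
10 mm cube at 1 mm voxels loses 18 % of its area; a fixed physical width
keeps the edge rounding bounded by the scanner resolution while the
residual staircase error on curved surfaces vanishes as the spacing
shrinks (measured 26 % → 10 % → 0.3 % over 1.0 / 0.6 / 0.3 mm for the
r = 10 mm sphere). At the reference 0.3 mm spacing the two conventions
coincide.

Area is the exact triangle sum `Σ ½‖(v₁−v₀)×(v₂−v₀)‖`, internally mm²,
reported cm². Limited fields of view can truncate the palate; such
defects appear as open boundary loops and are repaired by
`flat_fill_holes()`: every loop with perimeter below a user bound is fan
triangulated around its centroid projected onto the loop's best-fit
plane. Filling a flat defect is exact; filling a curved defect is a
*calculated approximation*, which is why the bound defaults to off and
each loop is reported as filled or skipped.

### Partition rules

The original separation of regions was manual in a mesh editor. The
package formalizes it as deterministic point tests on face centroids,
driven by a `partition_rules()` object:

- the **occlusal plane** splits maxillary from mandibular faces;
- "top view" is the orthographic projection along the occlusal normal;
- the **ridge polygons** (maxillary/mandibular alveolar ridge curves,
  projected top-view) bound palate and tongue laterally and anteriorly;
- the **trans-hamular plane** through the pterygoid hamuli, with the
  anterior direction taken from the lip-crease normal projected into the
  occlusal plane, limits both posteriorly;
- **tooth seeds** capture hard tissue within a radius (default 6 mm,
  roughly one crown-plus-alveolus); an empty seed set models the
  edentulous case;
- the **lip-crease plane** marks everything beyond it `EXCLUDED`.

Labels are assigned with precedence hard tissue > palate > tongue >
mucosa, which resolves overlaps that a manual operator never has to
think about. Centroid tests make the labelling orientation-free and
rigid-motion equivariant (tested). The tongue's posterior limit ("to the
top-view projection of the hamuli") admits more than one geometric
reading; the implemented one — mandibular side, inside the mandibular
polygon, anterior of the trans-hamular plane — is isolated behind
`partition_rules()` so alternatives can be swapped without touching the
pipeline.

### Statistics

Agreement between two raters (or two repeated measurements) uses the
two-way absolute-agreement average-measures intraclass correlation,
`ICC(A,k) = (MSR − MSE)/(MSR + (MSC − MSE)/n)` from the two-way ANOVA
mean squares. The random-model and mixed-model variants share this point
estimate; the declared model is metadata (it would matter for confidence
intervals, which the package does not compute because the reporting
format it mirrors does not). Tables with no between-subject variance, or
so much disagreement that the denominator is non-positive, raise
explicit errors rather than returning a number outside [−1, 1].
Interpretation bins: < 0.5 poor, ≤ 0.75 moderate, ≤ 0.9 good, > 0.9
excellent.

Pearson correlations are tested two-sided via
`t = r√((n−2)/(1−r²))` on `n − 2` degrees of freedom; `p_from_r()`
exposes the same computation for summary-level checks against published
values (a printed `r(12) = 0.59, P = 0.045` is consistent with n = 12
pairs under two-decimal rounding of r — the `r(N)` notation is read as
the number of pairs, not the degrees of freedom, because the recomputed
P-values match only under that reading; results print both n and df).
The strength bins in the literature this mirrors leave gaps
(0.1–0.2, 0.3–0.5, 0.6–0.7, 0.8–0.9); the package uses the gap-free
partition |r| < 0.3 negligible, < 0.5 fair, < 0.8 moderate, ≥ 0.8 very
strong, calibrated so published labels (0.50 and 0.59 both "moderate")
are reproduced.

One-way ANOVA accepts raw vectors or `(mean, sd, n)` summary rows; the
raw path computes the summary first, so both agree to machine precision,
and published tables can be re-tested without raw data. Significance is
α = 0.05 per test with no multiplicity correction, mirroring the
reporting convention; listwise deletion within each measurement mirrors
the variable N of field campaigns.

`aggregate_report()` computes per-subject totals as exact sums of the
four regions *before* averaging, so the cohort total mean equals the sum
of region means exactly — printed tables rounded to one decimal can
disagree by 0.1 between "total" and "sum of regions", and the report
documents the difference instead of reproducing it. The soft-tissue
subtotal (total minus hard tissue) is exposed under that explicit name
because "mucosa" already denotes region IV.

## The synthetic world

`oral_phantom_spec()` describes a styrofoam-separated, air-dried oral
cavity as solid primitives in air: a hemispherical palatal dome above the
occlusal plane, a spherical tongue below it, spherical bone "teeth"
(crown + alveolus lumps, radius 4–5 mm) in a separate band, and a large
mucosa box, each with a closed-form surface area. Voxelization is by
voxel-centre inclusion with no partial-volume averaging, which keeps the
analytic truth exact; partial volume is emulated only through optional
Gaussian HU noise. Default HU values (air −1000, soft tissue +40, bone
+1200, styrofoam −980) put each material on the correct side of both
thresholds; styrofoam is near-air because it is radiolucent at CBCT
energies. Embalmed-tissue HU distributions are not well tabulated, so
the soft-tissue default is a conventional fresh-tissue value and is
configurable. Air bubbles (default radius 0.5 mm) are placed by
rejection sampling (≤ 1000 retries) strictly inside soft tissue with at
least one voxel of margin and pairwise separation, so a request for k
bubbles yields exactly k enclosed air components.

Two scene sizes exist: `"standard"` (75 × 88 × 70 mm, areas at the adult
scale of roughly 20/25/25/100 cm²) and `"compact"` (a 0.4-scale scene
for ensemble runs, ~2 s per phantom end to end). `jitter_frac` perturbs
every structure size by a seeded uniform factor for ensemble studies.

**What a green test establishes — and what it does not.** The phantoms
share the geometry of the real problem (materials, HU contrast,
resolution, trapped bubbles, region adjacency) but none of its
pathology: no beam hardening, scatter, metal artifacts, partial-volume
blur beyond additive noise, anatomical shape variability, or contact
between tongue and palate. Recovery within a few percent on phantoms
therefore validates the *computational chain*, not scanner-specific
accuracy; the separated-structure layout also means the partition rules
are tested in their intended regime, not under the boundary ambiguity a
real tongue-against-ridge contact would create.

Statistical generators state their worlds explicitly:
`generate_rater_table()` draws `μ + sᵢ + rⱼ + eᵢⱼ` with the three
variances given (population `ICC(A,k) = σs²/(σs² + (σr² + σe²)/k)`);
`generate_correlated_pairs()` draws a bivariate normal with the exact
target correlation; `generate_head_landmarks()` is a fixed head geometry
at the adult craniofacial scale (head length ≈ 23 cm, bi-meatal width
≈ 16 cm, palatal width ≈ 4.3 cm) with optional per-coordinate Gaussian
digitisation noise emulating repeated caliper sessions (a 0.5 mm caliper
is emulated by opt-in quantization to 0.05 cm, off by default so exact
oracles stay exact).

## Numerical choices and degenerate inputs

- Thresholding is inclusive; raising the threshold can only remove
  voxels (monotone, tested).
- Closing is idempotent and extensive (tested property-wise); radius 0
  is the identity.
- The isosurface of an empty mask is an empty mesh (area 0), not an
  error; meshes drop degenerate faces at construction.
- STL round trips are exact to 32-bit float; truncated files raise a
  parse error with the byte offset and never return a partial mesh.
- A boundary vertex with more than two boundary edges makes hole filling
  ill-posed; `flat_fill_holes()` refuses with the vertex named.
- Ties at region boundaries are resolved by the fixed label precedence;
  faces are assigned by centroid, so a face is never split.
- `ICC` on an n = 1 group reports SD as missing, never 0; zero-variance
  inputs to `pearson_test()` are errors, not NaN.

## Known limitations

- The mucosa box and tooth spheres are geometric stand-ins; no attempt
  is made at anatomically deformable shapes.
- Flat filling is a planar approximation; for strongly curved defects
  the area is biased low by design (that is what "flat filling" means).
- `ICC` confidence intervals, Bayesian alternatives and multiplicity
  corrections beyond an optional Holm flag are out of scope.
- DICOM series export is not implemented (no DICOM writer is available
  in the supported dependency set); the raw-grid + JSON sidecar format
  carries the same information for all package tools.
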