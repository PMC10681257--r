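---
title: "Mirror-based midsagittal plane construction and surface asymmetry mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mirror-based midsagittal plane construction and surface asymmetry mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facesym)
```

## The model

`facesym` treats bilateral symmetry assessment as a rigid registration
problem.  Given a triangle mesh $S$ with vertices $v_1,\dots,v_n$ (mm), a
mirrored duplicate $S'$ is produced by an improper isometry (here the
reflection across the plane through the mesh centroid normal to the
lateral axis; the choice is immaterial because any two reflections differ
by a rigid motion that the subsequent registration absorbs).  $S'$ is then
best-fit approximated to $S$ by ICP while $S$ stays fixed.  The net map
$T$ from $S$ to the aligned $S'$ is a general improper isometry
$T(x) = Ax + t$, $\det A = -1$.

**Coplanarity of midpoints.**  The midpoints
$m_i = (v_i + T(v_i))/2 = ((I+A)v_i + t)/2$ are the image of the vertices
under an affine map whose linear part $(I+A)/2$ annihilates the $-1$
eigenvector of $A$.  Unless the rotational part of $A$ is a half-turn
(which would make the map rank 1), the image of $\mathbb{R}^3$ is a plane:
the midpoints are coplanar *for any relative pose of the two meshes and
irrespective of registration quality*.  The package verifies this
numerically to $10^{-9}\times$ the bounding-box diagonal.  What
registration quality determines is whether that plane is the *midsagittal*
plane of the surface; for an exactly symmetric surface the fitted $T$ is
the reflection across the true symmetry plane and the midpoint plane
coincides with it.

**Plane extraction.**  The plane is fitted by PCA: it passes through the
midpoint centroid with normal along the eigenvector of the smallest
eigenvalue of the midpoint covariance.  Although three non-collinear
midpoints suffice in exact arithmetic, all $n$ midpoints are used — this
is the most accurate choice and removes a free parameter.  A degeneracy
guard rejects clouds whose second-smallest/smallest eigenvalue ratio falls
below $10^3$ (the cloud has collapsed toward a line or point, which
happens only when $T$ approaches a rotary reflection, never after a
successful near-reflection fit).  The normal is oriented toward the
frame's $+Z$ so signed lateral statistics are comparable across runs.

**Asymmetry quantification.**  The distance map assigns to each original
vertex the exact distance to its closest point on the aligned mirrored
surface (directed distance: the map lives on the original surface, as
colour-coded maps do).  The sign is taken along the source vertex normal;
both signed and absolute values are exported because rendering conventions
vary.  MAD over a vertex selection is the mean of the absolute distances.
Since a selection is carried index-identically onto the mirrored copy, a
single one-sided selection yields two contralateral measurement areas, and
their MAD difference is the validity statistic: zero for a perfect
superimposition.

## Registration details

The defaults encode the reference superimposition settings: 100 %
estimated overlap, point-to-plane metric, exact nearest-neighbour search,
100 % point sampling, overhang exclusion on.

* **Exact correspondences.**  Closest points are exact minimisers of
  point-to-triangle distance over all faces, found with a bounding-volume
  hierarchy that prunes only faces provably farther than the current best
  candidate; tests assert bit-level agreement with a brute-force per-face
  oracle.  Vertex-to-surface (not vertex-to-vertex) matching is used as
  the stronger contract.
* **Overhang exclusion** discards correspondences whose closest point lies
  on a boundary edge or vertex of the target (an edge with exactly one
  incident face).  This is the standard reading of the option — it
  prevents border drag when the two meshes have different extents, e.g.
  after unilateral cropping — and is also applied when distance maps are
  summarised (boundary-flagged vertices are excluded from MAD).
* **Solver.**  Each iteration solves the linearised point-to-plane least
  squares for an incremental twist $(\omega, t)$, using the target
  triangle's face normal at the closest point (interpolating vertex
  normals changes nothing at realistic mesh densities), then
  re-orthonormalises the accumulated rotation by SVD.  Convergence is
  declared when the RMS residual changes by less than
  `convergence_tol = 1e-6` mm — two orders of magnitude below the 0.01 mm
  scale at which reproducibility is judged.  The residual trace is
  monotone after the first correspondence churn settles, and the returned
  transform is always a proper rigid motion.
* **Determinism.**  With default settings the pipeline contains no
  randomness; optional subsampling (`sampling_fraction < 1`) draws one
  seeded vertex subsample and restores the session RNG.

Tunable parameters, with units and defaults: `overlap_fraction` (1.0,
trimmed-ICP knob, fraction), `sampling_fraction` (1.0), `metric`
(`point_to_plane`), `exclude_overhang` (`TRUE`), `max_iterations` (200),
`convergence_tol` (1e-6 mm).  The basin of attraction of the mirror start
pose is wide: start-pose perturbations of ≤ 5° / 5 mm change the final
alignment by ~10⁻³ mm (property-tested), which is what makes the
reproducibility protocol meaningful.

## Plane comparison (Z, Xrot, Yrot)

Two midsagittal planes are compared by the lateral translation and two
rotations needed to carry one onto the other, in a canonical anatomical
frame (X+ anterior, Y+ superior, Z+ subject-left; mm and degrees):
`Xrot`/`Yrot` are the signed angles (right-hand rule about the frame X and
Y axes) between the normals' projections onto the planes perpendicular to
those axes, and `Z` is the signed distance from an anchor point on the
first plane to the second plane along the mean normal.  The anchor is the
original mesh centroid projected onto the first plane — the reference
quantity is reported as a single number, so the anchor must be fixed; the
centroid is the canonical choice and is recorded with the result.  Other
decompositions could differ at the 10⁻³ level for large rotations; for the
sub-0.1° differences actually observed the choice is immaterial.

## The synthetic generator

No human scan data ship with the package, so every experiment runs on
synthetic fixtures with *exact* ground truth:

* **Geometry.**  A single-valued heightfield $x = f(y, z)$ on a regular
  grid (default 100 × 100 over 160 mm × 140 mm), built from a smooth dome
  plus Gaussian features sketching forehead, brows, eye sockets, nose,
  cheeks, mouth and chin.  Features off the midline are applied at $\pm z$
  in the same floating-point order, so $f(y, z) = f(y, -z)$ holds
  *exactly*, the true symmetry plane is $z = 0$, and each vertex's
  contralateral twin is a grid index.  Optional surface noise uses
  identical draws at $\pm z$ to preserve exactness; an independent-noise
  mode would make ground truth only approximate and is deliberately not
  the default.
* **Asymmetries.**  One-sided Gaussian bumps (with the affected footprint,
  $|\Delta| > 5\%$ of amplitude, and its twin recorded as selections) and
  smooth random fields (white noise Gaussian-smoothed to a correlation
  length, scaled to a peak amplitude).
* **Crops.**  Four extent variants parameterised as fractions of the
  height range: Crop 1 keeps ~98 % of the depth range, Crop 2 cuts at 30 %,
  Crop 3 mixes the two sides (left cut deep, right shallow), Crop 4
  removes small seeded peripheral boxes (< 5 % of vertices) from Crop 1;
  two seeds play the roles of two operators cropping freehand
  independently.  Cropping keeps a face only when all three vertices
  survive — no re-meshing; boundary raggedness is below one edge length,
  negligible against the centimetre-scale crops.
* **Measurement areas.**  Rectangles in the un-posed frame: Area A spans
  the midline from brow to mouth level; Area B is a one-sided
  infraorbital/cheek rectangle whose contralateral twin is obtained
  through the grid twin map.

What the generator does *not* emulate: scanner noise correlated along
view directions, holes and topological artefacts, non-heightfield geometry
(ears, nostril interiors), and texture.  Passing the validation
experiments therefore demonstrates correctness of the *method and its
implementation* on well-behaved surfaces, not performance on raw scanner
output.

## Validation experiments and problem sizes

The packaged experiments (test suite and `scripts/acceptance.R`) use
100 × 100-vertex fixtures — 10 faces × 2 repeats for the perturb-and-refit
reproducibility protocol (pose changes ≤ 3° / 3 mm), 20 faces with 1 mm
random asymmetry fields for bilateral validity, and 5 faces × Crops 1–3
for fixed-crop repeatability.  Observed results sit one to two orders of
magnitude inside the corresponding bounds (plane differences ~6 × 10⁻⁴,
summed MADs ~6 × 10⁻³ mm, bilateral differences ~10⁻² mm, vertex-wise
repeat differences ~2 × 10⁻³ mm); thresholds were additionally checked to
be stable at 200 × 200 resolution.  Fixture identities (face seeds) are
fixed study conditions; perturbation seeds vary freely.

## Numerical choices and degenerate inputs

* Barycentric tolerance $10^{-9}$ classifies a closest point as lying on
  an edge/vertex for boundary flagging.
* Reflections/rotations are validated orthonormal to $10^{-9}$;
  accumulated rotations are re-projected onto SO(3) by SVD each iteration.
* Empty meshes, empty crops, all-overhang correspondence sets, degenerate
  midpoint clouds, count mismatches and out-of-range selections all raise
  typed errors rather than returning garbage; the CLI maps usage errors to
  exit 2 and numerical failures to exit 3.
* STL stores vertices per-triangle (no sharing): reading an STL yields
  3 vertices per face by design, since welding would silently break index
  correspondence — the one invariant nothing in this package may touch.
  PLY is the colour-bearing export dialect; selections and planes travel
  as JSON sidecars (0-based indices on disk, 1-based in R).

## Known limitations

Distances are between closest points, not anatomically corresponding
points — adequate for the validated bilateral comparisons, but anatomical
landmarks remain necessary when strict point correspondence is required.
A half-turn net isometry has no unique midpoint plane (guarded, cannot
arise from a successful mirror fit).  Rigid registration only: affine or
non-rigid variants are out of scope, as are re-meshing, hole filling and
texture.
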