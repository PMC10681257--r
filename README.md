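# facesym

Landmark-free midsagittal plane construction and asymmetry mapping for 3D
facial surface meshes.

## The problem

Quantifying the bilateral asymmetry of a face (or any roughly
mirror-symmetric surface) classically requires an operator to place
anatomical landmarks, either to measure left–right distances directly or to
define the midsagittal plane that separates the two sides.  Landmark
identification is slow, needs expertise, and injects operator bias — on
facial soft tissue the identification error alone often exceeds 0.5 mm.

`facesym` implements a fully automated, landmark-free alternative for
triangle surface meshes (e.g. stereophotogrammetry scans in mm):

1. **Mirror.**  The mesh is duplicated and reflected.  Because vertices are
   kept in an ordered array, vertex *i* of the mirrored copy is the
   contralateral twin of vertex *i* of the original, and any
   measurement-area selection made once is automatically present on both
   copies at contralateral positions.
2. **Superimpose.**  The mirrored duplicate is best-fit approximated onto
   the original by point-to-plane iterative closest point (ICP)
   registration with exact closest-point search, 100 % overlap and
   sampling, and exclusion of overhang (mesh-boundary) correspondences.
   The original never moves.
3. **Midsagittal plane.**  The midpoints of the segments joining
   index-corresponding vertices of the two superimposed meshes are
   *exactly* coplanar for any relative orientation (the midpoint map
   `x ↦ ((I + A)x + t)/2` with `A` an improper rotation has rank-2 linear
   part).  The plane is extracted by PCA of all midpoints — the normal is
   the eigenvector of the smallest eigenvalue of the midpoint covariance —
   and is the geometrically defined midsagittal plane of the surface.
4. **Asymmetry map.**  The per-vertex closest-point distances between
   original and aligned mirrored surface give a colour-coded distance map,
   and mean absolute distance (**MAD**) statistics over selected
   measurement areas quantify asymmetry regionally.  Identical
   contralateral areas must show identical MAD when the superimposition is
   perfect, so the bilateral MAD difference doubles as a validity check.

Everything is validated on synthetic face-like surfaces with known,
exactly constructed ground-truth symmetry (no human mesh data ship with
the package).

## Worked example

```r
library(facesym)

# a 100 x 100 synthetic face with a 1 mm bump on the subject's right cheek
face  <- generate_face(face_spec(seed = 1))
face  <- inject_asymmetry(face, bumps = list(list(y = -12, z = -30, a = 1, w = 9)))
areas <- default_areas(face)

fit <- mirror_fit(face$mesh, selections = areas)
fit
#> <mirror_fit>
#>   <icp_fit> 3 iteration(s), RMS residual 0.122 mm, converged, 200 overhang excluded

fit_midsagittal_plane(midpoints(face$mesh, fit$aligned))
#> <plane3> n = (0.000707, -0.001130, 0.999999), d = -0.092189 mm
#>   PCA midsagittal plane
#>   fit over 10000 midpoints; max residual 4.88e-15 mm, rms 1.35e-15 mm

map <- distance_map(face$mesh, fit$aligned)
do.call(rbind, lapply(areas, function(s) area_mad(map, s)))
#> # A tibble: 3 x 5
#>   name             n mad_mm max_mm frac_boundary_excluded
#> 1 area_A        1536 0.0712  0.535                      0
#> 2 area_B_right   468 0.0573  0.339                      0
#> 3 area_B_left    468 0.0584  0.325                      0

bilateral_difference(map, areas$area_B_right, areas$area_B_left)
#> [1] -0.001154696
```

Reading the numbers: the ICP residual (0.122 mm) reflects the injected
asymmetry, not registration error; the midpoint cloud is coplanar to
machine precision (`4.9e-15` mm) as the theory demands; the recovered
plane normal is within 0.08° of the true symmetry plane `z = 0`; the two
contralateral Area-B MADs agree to ~0.001 mm, far below the 0.1 mm
validity bound.  The reproducibility protocol (change the aligned copy's
pose, re-register, compare):

```r
rr <- repeat_superimposition(face$mesh, areas, n_repeats = 2, seed = 100)
glance(rr)
#> # A tibble: 1 x 5
#>   max_mad_sum_mm max_vertex_mm max_abs_Z_mm max_abs_Xrot_deg max_abs_Yrot_deg
#> 1        0.00477       0.00303    0.0000230         0.000525        0.0000117
```

`plot_distance_map(face$mesh, map)` renders the colour-coded map;
`write_mesh(..., vertex_scalars = map$signed)` exports a colour PLY for
any mesh viewer.

## Command line

```sh
Rscript inst/cli/facesym.R synth     --out fixtures --seed 1
Rscript inst/cli/facesym.R midplane  --in fixtures/face.ply --out out/
Rscript inst/cli/facesym.R asymmetry --in fixtures/face.ply \
        --selections fixtures/face.selections.json --out out/
Rscript inst/cli/facesym.R repro     --in fixtures/face.ply \
        --selections fixtures/face.selections.json --repeats 2 --out out/
```

Exit codes: 0 success, 2 usage/input error, 3 numerical failure.

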