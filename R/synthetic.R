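# Synthetic face-like surfaces with known ground-truth symmetry.
#
# The generator emulates the geometry of a cropped facial surface scan as
# a single-valued heightfield x = f(y, z) over a regular grid: y vertical
# (+ superior), z lateral (+ subject-left), x anteroposterior (+ anterior,
# the surface height).  The base surface is exactly mirror-symmetric
# about z = 0 by construction, so every downstream quantity has an exact
# ground truth; localized asymmetries, rigid pose changes and the four
# cropping variants are then applied on top.

#' Specification of a synthetic face surface
#'
#' @param ny,nz grid resolution (vertical x lateral), at least 8 each;
#'   default 100 x 100 (10,000 vertices), a density at which the
#'   acceptance-level results are stable (checked against 200 x 200).
#' @param height,width surface extents in mm (default 160 vertical x
#'   140 lateral, roughly a cropped adult face).
#' @param features list of symmetric Gaussian features
#'   `list(y=, z=, a=, w=)`: centre at vertical position `y` and lateral
#'   offset `|z|` (applied at +z and -z, or once on the midline when
#'   `z = 0`), amplitude `a` mm (negative = trough), width `w` mm.
#'   The default set sketches forehead, brow ridge, eye sockets, nose,
#'   cheeks, mouth and chin.
#' @param noise_sd symmetric surface noise standard deviation (mm);
#'   identical draws at +z and -z so the surface stays exactly symmetric
#'   (default 0).
#' @param seed integer seed for the noise.
#' @return an object of class `face_spec`.
#' @export
face_spec <- function(ny = 100L, nz = 100L, height = 160, width = 140,
                      features = default_face_features(), noise_sd = 0,
                      seed = 1L) {
  if (ny < 8L || nz < 8L) stop("resolution must be at least 8 x 8",
                               call. = FALSE)
  for (f in features)
    if (!(f$w > 0)) stop("feature widths must be > 0", call. = FALSE)
  structure(list(ny = as.integer(ny), nz = as.integer(nz), height = height,
                 width = width, features = features, noise_sd = noise_sd,
                 seed = as.integer(seed)), class = "face_spec")
}

#' @rdname face_spec
#' @export
default_face_features <- function() {
  list(
    list(y = 55, z = 0, a = 8, w = 35),    # forehead swell
    list(y = 30, z = 25, a = 2.5, w = 11), # brow ridges
    list(y = 18, z = 27, a = -4, w = 10),  # eye sockets
    list(y = -8, z = 0, a = 14, w = 10),   # nose
    list(y = -18, z = 38, a = 4, w = 16),  # cheeks
    list(y = -42, z = 0, a = 3, w = 12),   # mouth region
    list(y = -66, z = 0, a = 6, w = 13)    # chin
  )
}

face_grid <- function(spec) {
  y <- seq(-spec$height / 2, spec$height / 2, length.out = spec$ny)
  z <- seq(-spec$width / 2, spec$width / 2, length.out = spec$nz)
  list(y = y, z = z)
}

# heightfield of the symmetric base surface; Y, Z matrices (ny x nz)
base_height <- function(spec, Y, Z) {
  # smooth dome receding toward the periphery
  X <- 50 * exp(-(Y^2 / (2 * 62^2) + Z^2 / (2 * 52^2)))
  for (f in spec$features) {
    g <- exp(-((Y - f$y)^2 + (Z - f$z)^2) / (2 * f$w^2))
    if (f$z != 0)  # bilateral pair: add the contralateral twin
      g <- g + exp(-((Y - f$y)^2 + (Z + f$z)^2) / (2 * f$w^2))
    X <- X + f$a * g
  }
  X
}

#' Generate a synthetic face mesh with ground truth
#'
#' Triangulates the heightfield on the grid (two triangles per cell,
#' fixed diagonal).  With zero noise the vertex set is exactly
#' mirror-symmetric about the z = 0 plane: for every vertex `(x, y, z)`
#' the vertex `(x, y, -z)` exists at the twin grid index.  Ground truth
#' records the true symmetry plane, the (identity) pose, and the
#' index map to each vertex's contralateral twin.
#'
#' @param spec a [face_spec()].
#' @return list of class `face_fixture`: `mesh` (`surface_mesh`),
#'   `truth` (list: `plane` (`plane3` z = 0 pre-pose), `pose`
#'   (`rigid_transform`), `twin_index` (integer vector), `footprints`
#'   (named selections added by [inject_asymmetry()]), `grid`).
#' @export
generate_face <- function(spec = face_spec()) {
  g <- face_grid(spec)
  Y <- matrix(g$y, spec$ny, spec$nz)
  Z <- matrix(g$z, spec$ny, spec$nz, byrow = TRUE)
  X <- base_height(spec, Y, Z)
  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed, {
      half <- matrix(stats::rnorm(spec$ny * ceiling(spec$nz / 2),
                                  sd = spec$noise_sd),
                     spec$ny, ceiling(spec$nz / 2))
      full <- matrix(0, spec$ny, spec$nz)
      full[, seq_len(ncol(half))] <- half
      # mirror the draws so x(y, z) = x(y, -z) stays exact
      full[, spec$nz:(spec$nz - ncol(half) + 1L)] <- half
      full
    })
    X <- X + noise
  }
  verts <- cbind(x = as.vector(X), y = as.vector(Y), z = as.vector(Z))
  faces <- grid_faces(spec$ny, spec$nz)
  # twin of grid point (iy, iz) is (iy, nz + 1 - iz); column-major layout
  iy <- rep(seq_len(spec$ny), spec$nz)
  iz <- rep(seq_len(spec$nz), each = spec$ny)
  twin <- (spec$nz - iz) * spec$ny + iy
  structure(list(mesh = surface_mesh(verts, faces),
                 truth = list(plane = plane3(c(0, 0, 1), 0,
                                             note = "ground-truth symmetry plane"),
                              pose = rigid_transform(),
                              twin_index = twin, footprints = list(),
                              grid = g),
                 spec = spec),
            class = "face_fixture")
}

# two triangles per grid cell, fixed diagonal; vertices column-major
# (vertex id = (iz - 1) * ny + iy)
grid_faces <- function(ny, nz) {
  iy <- rep(seq_len(ny - 1L), nz - 1L)
  iz <- rep(seq_len(nz - 1L), each = ny - 1L)
  v00 <- (iz - 1L) * ny + iy
  v01 <- iz * ny + iy
  v10 <- v00 + 1L
  v11 <- v01 + 1L
  rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
}

#' @export
print.face_fixture <- function(x, ...) {
  cat(sprintf("<face_fixture> %d x %d grid, %d asymmetry footprint(s)\n",
              x$spec$ny, x$spec$nz, length(x$truth$footprints) / 2L))
  print(x$mesh)
  invisible(x)
}

#' Inject controlled asymmetries into a synthetic face
#'
#' Adds one-sided displacements along the surface-height (x) axis:
#' Gaussian bumps at arbitrary (y, z) centres and/or a smooth random
#' field (white noise smoothed to a given correlation length and scaled
#' to a peak amplitude).  For every bump the affected footprint (vertices
#' displaced by more than 5% of the amplitude) and its contralateral twin
#' are recorded as ground-truth selections -- the regions where the
#' asymmetry statistic should fire.
#'
#' @param face a `face_fixture` (in its un-posed frame).
#' @param bumps list of `list(y=, z=, a=, w=)` one-sided Gaussian bumps
#'   (amplitude `a` mm, width `w` mm; `z` may be any side).
#' @param field optional `list(amplitude=, corr_len=, seed=)` smooth
#'   random field: peak |amplitude| in mm, correlation length in mm.
#' @return the modified `face_fixture`, with footprint selections
#'   appended to `truth$footprints` (named `bump1`, `bump1_twin`, ...).
#' @export
inject_asymmetry <- function(face, bumps = list(), field = NULL) {
  stopifnot(inherits(face, "face_fixture"))
  v <- face$mesh$vertices
  delta <- numeric(nrow(v))
  fps <- face$truth$footprints
  for (i in seq_along(bumps)) {
    b <- bumps[[i]]
    if (b$a == 0) next
    g <- b$a * exp(-((v[, "y"] - b$y)^2 + (v[, "z"] - b$z)^2) / (2 * b$w^2))
    delta <- delta + g
    fp <- which(abs(g) > 0.05 * abs(b$a))
    nm <- sprintf("bump%d", i)
    fps[[nm]] <- vertex_selection(nm, fp)
    fps[[paste0(nm, "_twin")]] <-
      vertex_selection(paste0(nm, "_twin"), face$truth$twin_index[fp])
  }
  if (!is.null(field)) {
    spec <- face$spec
    W <- with_seed(field$seed, matrix(stats::rnorm(spec$ny * spec$nz),
                                      spec$ny, spec$nz))
    S <- smooth_grid(W, face$truth$grid, field$corr_len)
    S <- S / max(abs(S)) * field$amplitude
    delta <- delta + as.vector(S)
  }
  face$mesh$vertices[, "x"] <- v[, "x"] + delta
  face$truth$footprints <- fps
  face
}

# separable Gaussian smoothing of a grid field with kernel sd = corr_len
smooth_grid <- function(W, grid, corr_len) {
  ky <- stats::dnorm(outer(grid$y, grid$y, `-`), sd = corr_len)
  kz <- stats::dnorm(outer(grid$z, grid$z, `-`), sd = corr_len)
  ky <- ky / rowSums(ky)
  kz <- kz / rowSums(kz)
  ky %*% W %*% t(kz)
}

#' Apply a rigid pose change to a fixture
#'
#' Rotates (about the mesh centroid, random axis) and translates the
#' mesh by seeded random amounts, updating the ground truth covariantly:
#' the true symmetry plane and recorded pose transform with the mesh.
#' Used by the reproducibility protocol, where a superimposed mesh's
#' "original position in space is changed" before re-superimposition.
#'
#' @param face a `face_fixture`.
#' @param max_rotation_deg,max_translation_mm perturbation bounds
#'   (rotation angle <= 30 degrees).
#' @param seed integer seed.
#' @return the posed `face_fixture`.
#' @export
apply_pose <- function(face, max_rotation_deg = 10, max_translation_mm = 10,
                       seed = 1L) {
  stopifnot(inherits(face, "face_fixture"))
  if (max_rotation_deg > 30)
    stop("pose rotations above 30 degrees are outside the registration basin",
         call. = FALSE)
  tr <- random_rigid(max_rotation_deg, max_translation_mm, seed,
                     center = mesh_centroid(face$mesh))
  face$mesh <- apply_transform(face$mesh, tr)
  face$truth$plane <- transform_plane(face$truth$plane, tr)
  face$truth$pose <- compose_isometries(tr, face$truth$pose)
  face
}

#' Seeded random rigid perturbation
#'
#' Rotation by a uniform angle in `[0, max_rotation_deg]` about a random
#' axis through `center`, plus a translation drawn uniformly in the ball
#' of radius `max_translation_mm`.
#'
#' @param max_rotation_deg,max_translation_mm bounds.
#' @param seed integer seed.
#' @param center 3-vector the rotation pivots about.
#' @return a `rigid_transform`.
#' @export
random_rigid <- function(max_rotation_deg, max_translation_mm, seed,
                         center = c(0, 0, 0)) {
  with_seed(seed, {
    ax <- stats::rnorm(3)
    ax <- ax / sqrt(sum(ax^2))
    ang <- stats::runif(1, 0, max_rotation_deg) * pi / 180
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                3, 3, byrow = TRUE)
    R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
    R <- project_orthonormal(R, proper = TRUE)
    tdir <- stats::rnorm(3)
    tdir <- tdir / sqrt(sum(tdir^2))
    tmag <- max_translation_mm * stats::runif(1)^(1 / 3)
    t0 <- as.numeric(center - R %*% center) + tdir * tmag
    rigid_transform(R, t0)
  })
}

# plane n.x = d under x -> Ax + t:  n' = An (unit), d' = d + n'.t
transform_plane <- function(plane, transform) {
  n2 <- as.numeric(transform$A %*% plane$normal)
  plane3(n2, plane$offset + sum(n2 * transform$t), plane$note)
}

#' Default measurement-area selections on a synthetic face
#'
#' Rectangles in the un-posed face frame emulating the two areas used for
#' validity and reproducibility statistics: Area A, a midface rectangle
#' spanning the midline from mid-eyebrow level to the mouth; Area B, a
#' one-sided infraorbital/cheek rectangle on the subject's right
#' (z < 0).  `area_B_left` is the contralateral twin of `area_B_right`
#' by grid symmetry -- the same region the identical indices designate on
#' a mirrored copy.
#'
#' @param face a `face_fixture` (un-posed).
#' @return named list of `vertex_selection`s: `area_A`, `area_B_right`,
#'   `area_B_left`.
#' @export
default_areas <- function(face) {
  v <- face$mesh$vertices
  inrect <- function(ylim, zlim)
    which(v[, "y"] >= ylim[1] & v[, "y"] <= ylim[2] &
          v[, "z"] >= zlim[1] & v[, "z"] <= zlim[2])
  a <- vertex_selection("area_A", inrect(c(-45, 32), c(-22, 22)))
  br_idx <- inrect(c(-2, 28), c(-52, -16))
  br <- vertex_selection("area_B_right", br_idx)
  bl <- vertex_selection("area_B_left", face$truth$twin_index[br_idx])
  list(area_A = a, area_B_right = br, area_B_left = bl)
}

#' Cropping variants emulating the four surface extents
#'
#' Produces the four extent variants used to probe robustness, as
#' fractions of the surface-height range: Crop 1 keeps nearly the whole
#' surface (posterior cut just behind the "ears", i.e. the far
#' periphery); Crop 2 cuts bilaterally much closer to the face front;
#' Crop 3 is unilateral -- the subject-left side (z > 0) cut at the
#' Crop-2 depth and the right side at the Crop-1 depth; Crop 4 starts
#' from Crop 1 and removes small seeded random boxes at the periphery
#' (at most ~5% of vertices), emulating freehand peripheral trimming.
#' On the lateral/posterior axis Crop 1 contains Crop 3 contains Crop 2.
#'
#' @param face a `face_fixture`.
#' @param selections optional selections to remap into each crop (the
#'   default takes [default_areas()]).
#' @param seed seed for the Crop-4 nibbles (two different seeds emulate
#'   two operators cropping independently).
#' @return named list `crop1`..`crop4`, each a list with `mesh`,
#'   `selections`, `index_map` (as [crop_box()]).
#' @export
make_crops <- function(face, selections = default_areas(face), seed = 1L) {
  stopifnot(inherits(face, "face_fixture"))
  v <- face$mesh$vertices
  xr <- range(v[, "x"])
  lvl1 <- xr[1] + 0.02 * diff(xr)   # just behind the periphery
  lvl2 <- xr[1] + 0.30 * diff(xr)   # well forward of it
  keep1 <- v[, "x"] >= lvl1
  keep2 <- v[, "x"] >= lvl2
  keep3 <- ifelse(v[, "z"] > 0, v[, "x"] >= lvl2, v[, "x"] >= lvl1)
  crop1 <- crop_by_vertex_mask(face$mesh, keep1, selections)
  crop2 <- crop_by_vertex_mask(face$mesh, keep2, selections)
  crop3 <- crop_by_vertex_mask(face$mesh, keep3, selections)

  # Crop 4: seeded peripheral box nibbles off Crop 1
  keep4 <- keep1
  nib <- with_seed(seed, {
    yr <- range(v[, "y"]); zr <- range(v[, "z"])
    lapply(seq_len(4L), function(i) {
      side <- sample(4L, 1L)
      cy <- switch(side, yr[1], yr[2], stats::runif(1, yr[1], yr[2]),
                   stats::runif(1, yr[1], yr[2]))
      cz <- switch(side, stats::runif(1, zr[1], zr[2]),
                   stats::runif(1, zr[1], zr[2]), zr[1], zr[2])
      list(cy = cy, cz = cz, wy = stats::runif(1, 5, 10),
           wz = stats::runif(1, 5, 10))
    })
  })
  for (b in nib)
    keep4 <- keep4 & !(abs(v[, "y"] - b$cy) <= b$wy &
                       abs(v[, "z"] - b$cz) <= b$wz)
  crop4 <- crop_by_vertex_mask(face$mesh, keep4, selections)
  list(crop1 = crop1, crop2 = crop2, crop3 = crop3, crop4 = crop4)
}
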