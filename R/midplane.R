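#' Midpoints of index-corresponding vertices
#'
#' For an original mesh and its aligned mirrored duplicate, the midpoint
#' of every segment joining vertex `i` to vertex `i` of the other mesh.
#' Because the two meshes are related by an improper isometry, these
#' midpoints are exactly coplanar whatever the relative orientation (the
#' linear map `(I + A)/2` with `A` an improper rotation has rank 2 unless
#' the rotation part is a half-turn), and that plane is the midsagittal
#' plane once the registration is good.
#'
#' @param original,aligned_mirrored `surface_mesh`es with equal vertex
#'   counts and index correspondence.
#' @return n x 3 matrix of midpoints (mm).
#' @export
midpoints <- function(original, aligned_mirrored) {
  if (n_vertices(original) != n_vertices(aligned_mirrored))
    stop("vertex counts differ; meshes are not index-corresponding",
         call. = FALSE)
  (original$vertices + aligned_mirrored$vertices) / 2
}

#' Fit the midsagittal plane to a midpoint cloud by PCA
#'
#' The plane passes through the cloud centroid with normal along the
#' eigenvector of the smallest eigenvalue of the midpoint covariance
#' (total least squares).  All midpoints are used.  The normal is oriented
#' toward the frame's +Z (subject's left) so signed lateral differences
#' are comparable across runs.  A degeneracy guard rejects clouds that
#' have collapsed toward a line or point (ratio of the second-smallest to
#' smallest eigenvalue below `1e3`), which happens when the net improper
#' isometry approaches a rotary reflection rather than a near-reflection.
#'
#' @param cloud n x 3 matrix of midpoints (n >= 3).
#' @param frame `canonical_frame` used only to orient the normal sign.
#' @return an object of class `midplane`: `plane` (`plane3`),
#'   `eigenvalues` (descending), `max_residual` and `rms_residual`
#'   (point-plane distances over the cloud, mm), `n` (cloud size).
#' @export
fit_midsagittal_plane <- function(cloud, frame = canonical_frame()) {
  cloud <- as.matrix(cloud)
  if (nrow(cloud) < 3L) stop("need at least 3 midpoints", call. = FALSE)
  ctr <- colMeans(cloud)
  X <- sweep(cloud, 2, ctr)
  cv <- crossprod(X) / nrow(X)
  eg <- eigen(cv, symmetric = TRUE)
  ev <- eg$values  # descending
  if (!(ev[2] > 0) ||
      ev[2] / max(ev[3], .Machine$double.xmin) < 1e3)
    stop("degenerate midpoint cloud (no unique plane)", call. = FALSE)
  nrm <- eg$vectors[, 3]
  if (sum(nrm * frame$z) < 0) nrm <- -nrm
  pl <- plane3(nrm, sum(nrm * ctr), note = "PCA midsagittal plane")
  d <- plane_distance(pl, cloud)
  structure(list(plane = pl, eigenvalues = ev, max_residual = max(abs(d)),
                 rms_residual = sqrt(mean(d^2)), n = nrow(cloud)),
            class = "midplane")
}

#' @export
print.midplane <- function(x, ...) {
  print(x$plane)
  cat(sprintf("  fit over %d midpoints; max residual %.3g mm, rms %.3g mm\n",
              x$n, x$max_residual, x$rms_residual))
  invisible(x)
}

#' Difference between two midsagittal planes (Z / Xrot / Yrot)
#'
#' The movements needed to carry plane `a` onto plane `b`, reported the
#' way plane reproducibility is summarised: `Z`, the lateral translation
#' in mm; `Xrot`, the rotation about the anteroposterior axis in degrees;
#' `Yrot`, the rotation about the vertical axis in degrees.  `Xrot` and
#' `Yrot` are the signed angles between the two normals' projections onto
#' the frame's YZ and XZ planes; `Z` is the signed distance from the
#' reference point (the anchor, typically the mesh centroid projected
#' onto plane `a`) to plane `b`, measured along the mean normal.
#'
#' @param a,b `plane3` objects, normals within 45 degrees of the frame's
#'   +Z axis (the orientation contract of [fit_midsagittal_plane()]).
#' @param frame a `canonical_frame`.
#' @param reference_point 3-vector anchor for the lateral displacement;
#'   it is first projected onto plane `a`.
#' @return a one-row tibble with columns `Z_mm`, `Xrot_deg`, `Yrot_deg`.
#' @export
plane_difference <- function(a, b, frame = canonical_frame(),
                             reference_point = c(0, 0, 0)) {
  for (p in list(a, b)) {
    cosz <- sum(p$normal * frame$z)
    if (cosz <= 0)
      stop("plane normal anti-parallel to the frame Z axis", call. = FALSE)
    if (cosz < cos(45 * pi / 180))
      stop("plane normal more than 45 degrees from the frame Z axis",
           call. = FALSE)
  }
  proj_angle <- function(na, nb, axis) {
    # signed angle (right-hand rule about `axis`) between the projections
    # of the two normals onto the plane perpendicular to the axis
    pa <- na - sum(na * axis) * axis
    pb <- nb - sum(nb * axis) * axis
    cr <- c(pa[2] * pb[3] - pa[3] * pb[2], pa[3] * pb[1] - pa[1] * pb[3],
            pa[1] * pb[2] - pa[2] * pb[1])
    atan2(sum(axis * cr), sum(pa * pb)) * 180 / pi
  }
  # Xrot: about the anteroposterior axis -> projections in the YZ plane
  xrot <- proj_angle(a$normal, b$normal, frame$x)
  # Yrot: about the vertical axis -> projections in the XZ plane
  yrot <- proj_angle(a$normal, b$normal, frame$y)
  # lateral displacement at the anchor, along the mean normal
  p0 <- reference_point - plane_distance(a, reference_point) * a$normal
  m <- a$normal + b$normal
  m <- m / sqrt(sum(m^2))
  z <- (b$offset - sum(b$normal * p0)) / sum(b$normal * m)
  tibble::tibble(Z_mm = as.numeric(z), Xrot_deg = xrot, Yrot_deg = yrot)
}

#' Construct the midsagittal plane of a mesh
#'
#' Convenience composition of the whole pipeline: mirror the mesh,
#' best-fit the mirrored duplicate onto the original by ICP, take the
#' midpoints of index-corresponding vertices, and fit the plane by PCA.
#'
#' @inheritParams mirror_fit
#' @return an object of class `midsagittal_fit`: `plane` (`plane3`),
#'   `midplane` (the full `midplane` fit), `fit` (the `mirror_fit`),
#'   `aligned` (aligned mirrored mesh).
#' @export
midsagittal_from_mesh <- function(mesh, frame = canonical_frame(),
                                  selections = NULL, config = icp_config()) {
  mf <- mirror_fit(mesh, frame, selections, config)
  mp <- fit_midsagittal_plane(midpoints(mesh, mf$aligned), frame)
  structure(list(plane = mp$plane, midplane = mp, fit = mf,
                 aligned = mf$aligned), class = "midsagittal_fit")
}

#' @export
print.midsagittal_fit <- function(x, ...) {
  print(x$midplane)
  print(x$fit$icp)
  invisible(x)
}

# angle in degrees between two directions (sign-insensitive)
angle_between <- function(u, v) {
  cu <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(min(1, max(-1, abs(cu)))) * 180 / pi
}
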