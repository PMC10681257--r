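#' Rigid and improper isometries
#'
#' A rigid transform is a rotation (orthonormal, det +1) plus a
#' translation; an improper isometry has an orthonormal linear part with
#' det -1 and is the net map linking an original mesh to its aligned
#' mirrored copy (reflection composed with the ICP rigid motion).  Both
#' act on points as `A %*% x + t`.
#'
#' @param rotation,linear 3 x 3 orthonormal matrix.
#' @param translation 3-vector (mm).
#' @return An object of class `rigid_transform` or `improper_isometry`
#'   (both inherit from `isometry3`).
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  check_orthonormal(rotation)
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation must have determinant +1", call. = FALSE)
  structure(list(A = rotation, t = as.numeric(translation)),
            class = c("rigid_transform", "isometry3"))
}

#' @rdname rigid_transform
#' @export
improper_isometry <- function(linear, translation = c(0, 0, 0)) {
  check_orthonormal(linear)
  if (abs(det(linear) + 1) > 1e-9)
    stop("improper isometry must have determinant -1", call. = FALSE)
  structure(list(A = linear, t = as.numeric(translation)),
            class = c("improper_isometry", "isometry3"))
}

check_orthonormal <- function(A, tol = 1e-9) {
  A <- as.matrix(A)
  if (!all(dim(A) == c(3L, 3L)) || max(abs(crossprod(A) - diag(3))) > tol)
    stop("linear part must be a 3 x 3 orthonormal matrix", call. = FALSE)
  invisible(A)
}

#' @export
print.isometry3 <- function(x, ...) {
  kind <- if (inherits(x, "improper_isometry")) "improper isometry (det -1)"
          else "rigid transform (det +1)"
  cat("<", kind, ">\n", sep = "")
  cat("  linear:\n")
  print(round(x$A, 6))
  cat("  translation (mm):", paste(signif(x$t, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Compose two isometries: `a %then% b` applies `a` first, then `b`
#' @param a,b isometries.
#' @return the composite isometry (class chosen by the determinant).
#' @export
compose_isometries <- function(b, a) {
  A <- b$A %*% a$A
  t <- as.numeric(b$A %*% a$t + b$t)
  if (det(A) > 0) rigid_transform(project_orthonormal(A, proper = TRUE), t)
  else improper_isometry(project_orthonormal(A, proper = FALSE), t)
}

#' @rdname compose_isometries
#' @export
invert_isometry <- function(a) {
  A <- t(a$A)
  t <- as.numeric(-A %*% a$t)
  if (det(A) > 0) rigid_transform(A, t) else improper_isometry(A, t)
}

# nearest orthonormal matrix with the requested orientation (polar/SVD)
project_orthonormal <- function(A, proper = TRUE) {
  s <- svd(A)
  R <- s$u %*% t(s$v)
  want <- if (proper) 1 else -1
  if (sign(det(R)) != want) {
    u <- s$u
    u[, 3] <- -u[, 3]
    R <- u %*% t(s$v)
  }
  R
}

# points: n x 3 matrix
transform_points <- function(points, transform) {
  sweep(points %*% t(transform$A), 2, transform$t, `+`)
}

#' Apply an isometry to a mesh
#'
#' Maps every vertex through `A x + t`.  When the transform is
#' orientation-reversing (det -1) the face winding is flipped so outward
#' normals remain outward.  Stored vertex normals are recomputed.
#'
#' @param mesh a `surface_mesh`.
#' @param transform a `rigid_transform` or `improper_isometry`.
#' @return the transformed `surface_mesh`.
#' @export
apply_transform <- function(mesh, transform) {
  if (!inherits(transform, "isometry3"))
    stop("transform must be a rigid_transform or improper_isometry",
         call. = FALSE)
  v <- transform_points(mesh$vertices, transform)
  f <- mesh$faces
  if (det(transform$A) < 0) f <- f[, c(1L, 3L, 2L), drop = FALSE]
  out <- surface_mesh(v, f)
  if (!is.null(mesh$normals)) out$normals <- vertex_normals(out)
  out
}

#' Mirror a mesh across its centroid lateral plane
#'
#' Duplicates and mirrors a mesh: vertices are reflected across the plane
#' through the mesh centroid with normal along the frame's lateral (Z)
#' axis, and the face winding is reversed so the surface stays outward.
#' Vertex `i` of the result is the contralateral twin of vertex `i` of the
#' input, and selections carry over index-identical -- the property that
#' makes midpoint-plane construction and bilateral area comparison
#' possible.  The exact mirroring plane is immaterial: any other choice
#' differs by a rigid motion, which the subsequent best-fit registration
#' absorbs.
#'
#' @param mesh a non-empty `surface_mesh`.
#' @param frame a `canonical_frame` supplying the lateral axis.
#' @param selections optional list of `vertex_selection`s to carry over.
#' @return list with elements `mesh` (mirrored copy), `isometry` (the
#'   reflection as an `improper_isometry`; maps original vertex i to
#'   mirrored vertex i exactly) and `selections`.
#' @export
mirror_mesh <- function(mesh, frame = canonical_frame(), selections = NULL) {
  if (!inherits(mesh, "surface_mesh") || n_vertices(mesh) == 0L)
    stop("empty mesh", call. = FALSE)
  n <- frame$z / sqrt(sum(frame$z^2))
  c0 <- mesh_centroid(mesh)
  A <- diag(3) - 2 * tcrossprod(n)
  t <- as.numeric(c0 - A %*% c0)
  iso <- improper_isometry(A, t)
  list(mesh = apply_transform(mesh, iso), isometry = iso,
       selections = selections)
}
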