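# Exact closest-point queries against a triangle mesh, via the compiled
# BVH (pruning is conservative, so results are identical to a brute-force
# scan over all faces).

# internal batch query; returns list(distance, point, face, bary, boundary)
# `topo` (boundary_topology of the target) may be passed to avoid recompute.
closest_point_batch <- function(points, mesh, topo = NULL,
                                bary_tol = 1e-9) {
  if (n_faces(mesh) < 1L) stop("empty mesh", call. = FALSE)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  res <- .cpp_closest_points(mesh$vertices, mesh$faces - 1L, points)
  if (is.null(topo)) topo <- boundary_topology(mesh)
  res$boundary <- boundary_flag(res, mesh, topo, bary_tol)
  res
}

# A correspondence is boundary-flagged iff its closest point lies on an
# edge or vertex owned by a boundary edge (an edge with exactly one
# incident face).  Barycentric coordinate ~0 identifies the simplex the
# closest point lies on.
boundary_flag <- function(res, mesh, topo, bary_tol = 1e-9) {
  b <- res$bary
  onb <- logical(nrow(b))
  zero <- b <= bary_tol
  nzero <- rowSums(zero)
  f <- res$face
  # interior of a triangle: never boundary
  edge_case <- nzero == 1L
  if (any(edge_case)) {
    # zero coord k => closest point on edge opposite vertex k
    k <- max.col(zero[edge_case, , drop = FALSE], ties.method = "first")
    eb <- topo$edge_boundary
    onb[edge_case] <- eb[cbind(f[edge_case], k)]
  }
  vert_case <- nzero == 2L
  if (any(vert_case)) {
    # the surviving coordinate's vertex
    k <- max.col(!zero[vert_case, , drop = FALSE], ties.method = "first")
    vid <- mesh$faces[cbind(f[vert_case], k)]
    onb[vert_case] <- topo$vertex_boundary[vid]
  }
  onb
}

#' Exact closest point on a mesh surface
#'
#' For each query point, the exact minimiser of point-to-triangle distance
#' over all faces of the mesh, found through a bounding-volume hierarchy
#' that only prunes faces provably farther than the current best
#' candidate.  A correspondence is flagged as `boundary` when the closest
#' point lies on an edge or vertex belonging to a boundary edge (an edge
#' with exactly one incident face) -- the correspondences the "exclude
#' overhang regions" registration option discards.
#'
#' @param points query point(s): 3-vector or n x 3 matrix (mm).
#' @param mesh target `surface_mesh` (at least one face).
#' @return a tibble with columns `distance` (mm), `px`,`py`,`pz` (closest
#'   point), `face` (1-based face index), `b1`,`b2`,`b3` (barycentric
#'   coordinates) and `boundary` (logical).
#' @export
closest_points <- function(points, mesh) {
  res <- closest_point_batch(points, mesh)
  tibble::tibble(distance = res$distance, px = res$point[, 1],
                 py = res$point[, 2], pz = res$point[, 3], face = res$face,
                 b1 = res$bary[, 1], b2 = res$bary[, 2], b3 = res$bary[, 3],
                 boundary = res$boundary)
}
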