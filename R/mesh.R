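#' Triangle surface mesh
#'
#' The common currency of every stage of the pipeline: an ordered vertex
#' array (millimetres) and a face array of vertex index triples.  Vertex
#' order is significant throughout the package -- vertex `i` of a mirrored
#' copy is the contralateral twin of vertex `i` of the original, and every
#' correspondence-based statistic relies on that ordering, so no operation
#' ever reorders or welds vertices.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z (mm).
#' @param faces integer matrix, one row per triangle, 1-based vertex
#'   indices.
#' @param normals optional numeric matrix of per-vertex unit normals.
#' @return An object of class `surface_mesh`: a list with elements
#'   `vertices`, `faces` and (optionally) `normals`.
#' @examples
#' m <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'                   rbind(c(1L, 2L, 3L)))
#' n_vertices(m)
#' @export
surface_mesh <- function(vertices, faces, normals = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (nrow(vertices) == 0L) stop("empty mesh", call. = FALSE)
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix", call. = FALSE)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix", call. = FALSE)
  if (nrow(faces) > 0L) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face index out of range", call. = FALSE)
    degen <- faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
      faces[, 2] == faces[, 3]
    if (any(degen))
      stop("face repeats a vertex (degenerate triangle)", call. = FALSE)
  }
  dimnames(vertices) <- list(NULL, c("x", "y", "z"))
  dimnames(faces) <- NULL
  out <- list(vertices = vertices, faces = faces)
  if (!is.null(normals)) {
    normals <- as.matrix(normals)
    stopifnot(nrow(normals) == nrow(vertices), ncol(normals) == 3L)
    out$normals <- normals
  }
  structure(out, class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("<surface_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  cat(sprintf("  bbox [mm]: x %.2f..%.2f  y %.2f..%.2f  z %.2f..%.2f\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' @rdname surface_mesh
#' @param mesh a `surface_mesh`.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname surface_mesh
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

#' @rdname surface_mesh
#' @export
mesh_centroid <- function(mesh) colMeans(mesh$vertices)

#' Bounding-box diagonal of a mesh (mm)
#' @param mesh a `surface_mesh`.
#' @export
bbox_diagonal <- function(mesh) {
  r <- apply(mesh$vertices, 2, range)
  sqrt(sum((r[2, ] - r[1, ])^2))
}

#' Canonical anatomical frame
#'
#' Right-handed orthonormal frame fixing the anatomical axis convention
#' used by every directional quantity in the package: X+ anterior
#' (anteroposterior axis), Y+ superior (vertical axis), Z+ toward the
#' subject's left (lateral axis).  Lateral plane translation ("Z") is
#' measured along the Z axis; "Xrot" is rotation about the anteroposterior
#' axis and "Yrot" about the vertical axis.  For meshes produced by the
#' synthetic generator the default world-aligned frame is the correct one.
#'
#' @param origin 3-vector, frame origin (mm).
#' @param x,y,z 3-vectors, the anteroposterior, vertical and lateral axes.
#' @return An object of class `canonical_frame`.
#' @export
canonical_frame <- function(origin = c(0, 0, 0), x = c(1, 0, 0),
                            y = c(0, 1, 0), z = c(0, 0, 1)) {
  A <- cbind(x, y, z)
  if (max(abs(crossprod(A) - diag(3))) > 1e-9)
    stop("frame axes must be orthonormal", call. = FALSE)
  if (det(A) < 0)
    stop("frame must be right-handed (det = +1)", call. = FALSE)
  structure(list(origin = as.numeric(origin), x = as.numeric(x),
                 y = as.numeric(y), z = as.numeric(z)),
            class = "canonical_frame")
}

#' Named vertex selection (measurement area)
#'
#' A named subset of vertex indices of a specific mesh, the package's
#' representation of a measurement area (e.g. the midface Area A or the
#' one-sided Area B).  Selections survive mirroring unchanged: the same
#' indices on the mirrored copy designate the contralateral area, which is
#' how a single Area B selection yields both "Area B right" and
#' "Area B left" without being drawn twice.
#'
#' Indices are 1-based in memory (R convention); the JSON sidecar format
#' written by [save_selections()] stores them 0-based.
#'
#' @param name selection name.
#' @param indices integer vertex indices (1-based); stored sorted, unique.
#' @param mesh optional `surface_mesh` to validate the indices against.
#' @return An object of class `vertex_selection`.
#' @export
vertex_selection <- function(name, indices, mesh = NULL) {
  indices <- sort(unique(as.integer(indices)))
  if (length(indices) && indices[1] < 1L)
    stop("selection indices must be >= 1", call. = FALSE)
  if (!is.null(mesh) && length(indices) && max(indices) > n_vertices(mesh))
    stop(sprintf("selection '%s' references vertex %d of a %d-vertex mesh",
                 name, max(indices), n_vertices(mesh)), call. = FALSE)
  structure(list(name = as.character(name), indices = indices),
            class = "vertex_selection")
}

#' @export
print.vertex_selection <- function(x, ...) {
  cat(sprintf("<vertex_selection> '%s': %d vertices\n", x$name,
              length(x$indices)))
  invisible(x)
}

# per-face unit normals and twice-areas; degenerate faces get zero normal
face_normals <- function(mesh, keep_magnitude = FALSE) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  if (keep_magnitude) return(cr)
  nrm <- sqrt(rowSums(cr^2))
  nrm[nrm == 0] <- 1
  cr / nrm
}

#' Per-vertex outward normals
#'
#' Area-weighted average of incident face normals, normalised.  Vertices
#' referenced by no face get a zero normal and are flagged in the
#' `"isolated"` attribute.  Reversing the face winding negates every
#' normal, which is how mirrored copies keep their normals outward.
#'
#' @param mesh a `surface_mesh` with at least one face.
#' @return n x 3 matrix of unit normals with attribute `isolated`
#'   (logical vector marking vertices with no incident face).
#' @export
vertex_normals <- function(mesh) {
  if (n_faces(mesh) < 1L) stop("mesh has no faces", call. = FALSE)
  fn <- face_normals(mesh, keep_magnitude = TRUE)  # |cross| = 2 * area
  n <- n_vertices(mesh)
  acc <- matrix(0, n, 3)
  for (k in 1:3) {
    s <- rowsum(fn, group = mesh$faces[, k], reorder = FALSE)
    idx <- as.integer(rownames(s))
    acc[idx, ] <- acc[idx, ] + s
  }
  nrm <- sqrt(rowSums(acc^2))
  isolated <- !(seq_len(n) %in% as.vector(mesh$faces))
  nrm[nrm == 0] <- 1
  out <- acc / nrm
  out[isolated, ] <- 0
  attr(out, "isolated") <- isolated
  out
}

# Boundary topology of a mesh: edges with exactly one incident face.
# Returns list(edge_boundary = m x 3 logical where column k flags the face
# edge *opposite* vertex k, vertex_boundary = n logical).
boundary_topology <- function(mesh) {
  f <- mesh$faces
  m <- nrow(f)
  # edge opposite vertex k joins the other two vertices
  ea <- rbind(cbind(f[, 2], f[, 3]), cbind(f[, 3], f[, 1]),
              cbind(f[, 1], f[, 2]))
  key <- paste(pmin(ea[, 1], ea[, 2]), pmax(ea[, 1], ea[, 2]))
  cnt <- table(key)
  onb <- cnt[key] == 1L
  edge_boundary <- matrix(onb, nrow = m, ncol = 3)
  vb <- logical(n_vertices(mesh))
  if (any(onb)) vb[unique(as.vector(ea[onb, ]))] <- TRUE
  list(edge_boundary = edge_boundary, vertex_boundary = vb)
}
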