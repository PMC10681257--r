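# Cropping: keep faces whose three vertices all satisfy a predicate; drop
# unreferenced vertices; remap selections through the old->new index map.
# No re-meshing at the crop boundary -- raggedness is at most one edge
# length, negligible at the centimetre scale of the posterior crops.

crop_by_vertex_mask <- function(mesh, keep_vertex, selections = NULL) {
  f <- mesh$faces
  keep_face <- keep_vertex[f[, 1]] & keep_vertex[f[, 2]] & keep_vertex[f[, 3]]
  if (!any(keep_face)) stop("empty crop", call. = FALSE)
  f2 <- f[keep_face, , drop = FALSE]
  used <- sort(unique(as.vector(f2)))
  index_map <- rep(NA_integer_, n_vertices(mesh))
  index_map[used] <- seq_along(used)
  out <- surface_mesh(mesh$vertices[used, , drop = FALSE],
                      matrix(index_map[f2], ncol = 3))
  sel2 <- NULL
  if (!is.null(selections)) {
    sel2 <- lapply(selections, function(s) {
      vertex_selection(s$name, stats::na.omit(index_map[s$indices]), out)
    })
    names(sel2) <- vapply(sel2, function(s) s$name, character(1))
  }
  list(mesh = out, selections = sel2, index_map = index_map)
}

#' Crop a mesh with an axis-aligned box
#'
#' Keeps exactly the faces whose three vertices all lie inside the closed
#' box, expressed in the canonical frame (box planes parallel or
#' perpendicular to the frame axes, the way posterior crops are placed
#' relative to the Frankfurt-Horizontal orientation).  Unreferenced
#' vertices are dropped; selections are remapped through the returned
#' index map, silently losing indices of removed vertices.
#'
#' @param mesh a `surface_mesh`.
#' @param limits 2 x 3 matrix or list: row 1 = per-axis minima, row 2 =
#'   maxima (mm, frame coordinates); `-Inf`/`Inf` allowed.
#' @param frame a `canonical_frame`; vertices are tested in its axes.
#' @param selections optional list of `vertex_selection`s to remap.
#' @return list with `mesh`, `selections` (remapped) and `index_map`
#'   (old vertex index -> new index, `NA` where dropped; injective on
#'   retained vertices).
#' @export
crop_box <- function(mesh, limits, frame = canonical_frame(),
                     selections = NULL) {
  if (is.list(limits)) lim <- rbind(limits$min, limits$max)
  else lim <- as.matrix(limits)
  if (!all(dim(lim) == c(2L, 3L)))
    stop("limits must be a 2 x 3 matrix (min row, max row) or list(min=, max=)",
         call. = FALSE)
  if (any(lim[1, ] > lim[2, ])) stop("limits define an empty box", call. = FALSE)
  B <- cbind(frame$x, frame$y, frame$z)
  local <- sweep(mesh$vertices, 2, frame$origin) %*% B
  keep <- local[, 1] >= lim[1, 1] & local[, 1] <= lim[2, 1] &
          local[, 2] >= lim[1, 2] & local[, 2] <= lim[2, 2] &
          local[, 3] >= lim[1, 3] & local[, 3] <= lim[2, 3]
  crop_by_vertex_mask(mesh, keep, selections)
}
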