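#' Per-vertex distance map between original and aligned mirrored surfaces
#'
#' The directed closest-point distance from every vertex of the original
#' mesh to the aligned mirrored surface -- the quantity rendered as a
#' colour-coded asymmetry map and summarised by area MAD statistics.
#' The sign is positive where the mirrored surface lies along the source
#' vertex's outward normal and negative otherwise; vertices whose closest
#' point falls on the mirrored mesh's boundary are flagged (such
#' distances are cropping artefacts and are excluded from MAD by
#' default).
#'
#' @param original `surface_mesh` whose vertices carry the map.
#' @param aligned_mirrored `surface_mesh`, the registered mirrored copy.
#' @return an object of class `distance_map`: a tibble with columns
#'   `vertex`, `distance` (absolute mm), `signed` (mm) and `boundary`.
#' @export
distance_map <- function(original, aligned_mirrored) {
  if (n_faces(aligned_mirrored) < 1L || n_vertices(original) < 1L)
    stop("both meshes must be non-empty", call. = FALSE)
  res <- closest_point_batch(original$vertices, aligned_mirrored)
  vn <- vertex_normals(original)
  to_cp <- res$point - original$vertices
  sgn <- ifelse(rowSums(to_cp * vn) >= 0, 1, -1)
  out <- tibble::tibble(vertex = seq_len(n_vertices(original)),
                        distance = res$distance,
                        signed = sgn * res$distance,
                        boundary = res$boundary)
  class(out) <- c("distance_map", class(out))
  out
}

#' Mean absolute distance over a measurement area
#'
#' MAD is the mean of the absolute closest-point distances over the
#' retained vertices of a selection.  Boundary-flagged vertices are
#' excluded by default, mirroring the registration's overhang logic.
#'
#' @param map a [distance_map()].
#' @param selection a `vertex_selection` (non-empty after exclusions).
#' @param exclude_boundary drop boundary-flagged vertices (default TRUE).
#' @return a one-row tibble: `name`, `n` (vertices used), `mad_mm`,
#'   `max_mm`, `frac_boundary_excluded`.
#' @export
area_mad <- function(map, selection, exclude_boundary = TRUE) {
  idx <- selection$indices
  if (length(idx) == 0L)
    stop("selection '", selection$name, "' is empty", call. = FALSE)
  if (max(idx) > nrow(map))
    stop("selection '", selection$name, "' exceeds the map", call. = FALSE)
  d <- map$distance[idx]
  bnd <- map$boundary[idx]
  keep <- if (exclude_boundary) !bnd else rep(TRUE, length(idx))
  if (!any(keep))
    stop("selection '", selection$name,
         "' is empty after boundary exclusion", call. = FALSE)
  tibble::tibble(name = selection$name, n = sum(keep),
                 mad_mm = mean(d[keep]), max_mm = max(d[keep]),
                 frac_boundary_excluded = mean(bnd))
}

#' Bilateral MAD difference (validity statistic)
#'
#' `MAD(right area) - MAD(left area)`: for a perfect superimposition of a
#' mesh with its mirrored duplicate the two contralateral areas see the
#' same surface pair, so the difference should be zero; its deviation
#' from zero measures superimposition error.  This is the headline
#' validity statistic.
#'
#' @param map a [distance_map()].
#' @param area_right,area_left `vertex_selection`s (index-identical areas
#'   on the two sides, e.g. a right-side area and its contralateral twin).
#' @param exclude_boundary passed to [area_mad()].
#' @return signed difference in mm (scalar).
#' @export
bilateral_difference <- function(map, area_right, area_left,
                                 exclude_boundary = TRUE) {
  area_mad(map, area_right, exclude_boundary)$mad_mm -
    area_mad(map, area_left, exclude_boundary)$mad_mm
}

#' Diverging palette and scalar-to-colour mapping
#'
#' Signed distances are clamped to `scale` and mapped linearly through a
#' diverging palette; zero maps to the palette midpoint.  The default
#' scale of ±2 mm matches the magnitude at which individual facial
#' asymmetries are typically discussed.
#'
#' @param values numeric vector (signed mm).
#' @param scale length-2 numeric, `c(min, max)` with `min < max`.
#' @param palette vector of R colours interpolated in RGB.
#' @return integer matrix n x 3 of 8-bit RGB values.
#' @export
colourize <- function(values, scale = c(-2, 2),
                      palette = diverging_palette()) {
  if (!(scale[1] < scale[2])) stop("scale min must be < max", call. = FALSE)
  x <- pmin(pmax(values, scale[1]), scale[2])
  u <- (x - scale[1]) / (scale[2] - scale[1])  # 0..1
  rgb <- grDevices::col2rgb(palette)           # 3 x k
  k <- ncol(rgb)
  pos <- u * (k - 1)
  lo <- pmin(floor(pos) + 1, k)
  hi <- pmin(lo + 1, k)
  fr <- pos - (lo - 1)
  out <- sapply(1:3, function(ch)
    as.integer(round(rgb[ch, lo] * (1 - fr) + rgb[ch, hi] * fr)))
  matrix(out, ncol = 3, dimnames = list(NULL, c("red", "green", "blue")))
}

#' @rdname colourize
#' @export
diverging_palette <- function() {
  c("#2166AC", "#67A9CF", "#D1E5F0", "#FFFFFF", "#FDDBC7", "#EF8A62",
    "#B2182B")
}

#' Export a distance map as CSV (vertex index, signed mm, boundary flag)
#' @param map a [distance_map()].
#' @param path output CSV path.
#' @export
write_distance_csv <- function(map, path) {
  utils::write.csv(
    data.frame(vertex = map$vertex, signed_mm = map$signed,
               boundary = map$boundary),
    path, row.names = FALSE)
  invisible(path)
}
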