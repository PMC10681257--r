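#' Re-superimposition reproducibility protocol
#'
#' The method-error protocol: after a reference mirror-and-fit, the
#' aligned mirrored mesh is duplicated, its position in space is changed
#' by a seeded random rigid perturbation, and it is superimposed again on
#' the untouched original.  Each repeat reports (a) the MAD between the
#' repeat-aligned and reference-aligned mirrored meshes over the
#' measurement areas (Area A, Area B right, Area B left; their sum is the
#' per-case error figure), (b) the maximum vertex-wise distance between
#' the two aligned meshes, and (c) the Z/Xrot/Yrot difference between the
#' repeat and reference midsagittal planes.  Corresponding-vertex
#' distances are exact because the two aligned meshes share the vertex
#' array.
#'
#' @param mesh the original `surface_mesh` (never moved).
#' @param areas named list of `vertex_selection`s; the conventional names
#'   `area_A`, `area_B_right`, `area_B_left` make up the summed MAD.
#' @param frame a `canonical_frame`.
#' @param config an [icp_config()].
#' @param n_repeats number of perturb-and-refit repeats.
#' @param max_rotation_deg,max_translation_mm perturbation bounds
#'   (default 3 degrees / 3 mm).
#' @param seed integer; repeat `i` perturbs with seed `seed + i`.
#' @param reference optionally a precomputed `mirror_fit` for `mesh`.
#' @return an object of class `repro_result`: `table` (tibble, one row
#'   per repeat: per-area MADs, `mad_sum_mm`, `max_vertex_mm`, `Z_mm`,
#'   `Xrot_deg`, `Yrot_deg`), `reference` (the reference `mirror_fit`),
#'   `reference_plane` (`plane3`).
#' @export
repeat_superimposition <- function(mesh, areas, frame = canonical_frame(),
                                   config = icp_config(), n_repeats = 2L,
                                   max_rotation_deg = 3,
                                   max_translation_mm = 3, seed = 1L,
                                   reference = NULL) {
  if (is.null(reference))
    reference <- mirror_fit(mesh, frame, areas, config)
  ref_aligned <- reference$aligned
  ref_plane <- fit_midsagittal_plane(midpoints(mesh, ref_aligned),
                                     frame)$plane
  anchor <- mesh_centroid(mesh)

  rows <- vector("list", n_repeats)
  for (i in seq_len(max(0L, as.integer(n_repeats)))) {
    pert <- random_rigid(max_rotation_deg, max_translation_mm,
                         seed = seed + i,
                         center = mesh_centroid(ref_aligned))
    moved <- apply_transform(ref_aligned, pert)
    refit <- icp_align(moved, mesh, config)
    rep_aligned <- refit$aligned
    dv <- sqrt(rowSums((rep_aligned$vertices - ref_aligned$vertices)^2))
    mads <- vapply(areas, function(s) mean(dv[s$indices]), numeric(1))
    rep_plane <- fit_midsagittal_plane(midpoints(mesh, rep_aligned),
                                       frame)$plane
    pd <- plane_difference(ref_plane, rep_plane, frame, anchor)
    rows[[i]] <- tibble::tibble(
      repeat_id = i,
      !!!stats::setNames(as.list(mads), paste0("mad_", names(areas), "_mm")),
      mad_sum_mm = sum(mads), max_vertex_mm = max(dv),
      Z_mm = pd$Z_mm, Xrot_deg = pd$Xrot_deg, Yrot_deg = pd$Yrot_deg)
  }
  tab <- if (n_repeats > 0L) do.call(rbind, rows) else
    tibble::tibble(repeat_id = integer(), mad_sum_mm = numeric(),
                   max_vertex_mm = numeric(), Z_mm = numeric(),
                   Xrot_deg = numeric(), Yrot_deg = numeric())
  structure(list(table = tab, reference = reference,
                 reference_plane = ref_plane),
            class = "repro_result")
}

#' @export
print.repro_result <- function(x, ...) {
  cat(sprintf("<repro_result> %d repeat(s)\n", nrow(x$table)))
  if (nrow(x$table)) {
    s <- summary(x)
    cat(sprintf(
      "  max summed MAD %.3g mm; max |Z| %.3g mm; max |Xrot| %.3g deg; max |Yrot| %.3g deg\n",
      s$max_mad_sum_mm, s$max_abs_Z_mm, s$max_abs_Xrot_deg,
      s$max_abs_Yrot_deg))
  }
  invisible(x)
}

#' @export
summary.repro_result <- function(object, ...) {
  t <- object$table
  list(max_mad_sum_mm = max(t$mad_sum_mm, -Inf),
       max_vertex_mm = max(t$max_vertex_mm, -Inf),
       max_abs_Z_mm = max(abs(t$Z_mm), -Inf),
       max_abs_Xrot_deg = max(abs(t$Xrot_deg), -Inf),
       max_abs_Yrot_deg = max(abs(t$Yrot_deg), -Inf))
}
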