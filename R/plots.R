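# ggplot2 visualisations: distance maps rendered in the frontal (z, y)
# projection, ICP convergence traces, reproducibility summaries.

#' Frontal-view colour-coded distance map
#'
#' Renders a per-vertex signed distance map in the frontal projection
#' (lateral axis horizontal, flipped so the subject's right appears on
#' the viewer's left; vertical axis up) with the package's diverging
#' palette -- the static counterpart of an interactive colour-mapped
#' mesh.
#'
#' @param mesh the `surface_mesh` carrying the map.
#' @param map a [distance_map()] for that mesh.
#' @param scale colour limits in mm (default ±2).
#' @return a ggplot object.
#' @export
plot_distance_map <- function(mesh, map, scale = c(-2, 2)) {
  df <- tibble::tibble(z = mesh$vertices[, "z"], y = mesh$vertices[, "y"],
                       signed = pmin(pmax(map$signed, scale[1]), scale[2]))
  ggplot2::ggplot(df, ggplot2::aes(x = -z, y = y,
                                   colour = signed)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_colour_gradientn(colours = diverging_palette(),
                                    limits = scale,
                                    name = "signed\ndistance (mm)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "lateral (subject right → viewer left) [mm]",
                  y = "vertical [mm]",
                  title = "Colour-coded asymmetry map (frontal view)") +
    ggplot2::theme_minimal()
}

#' @method autoplot icp_fit
#' @export
autoplot.icp_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = iteration, y = rms_mm)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "RMS point-to-plane residual (mm)",
                  title = "ICP convergence") +
    ggplot2::theme_minimal()
}

#' @method autoplot repro_result
#' @export
autoplot.repro_result <- function(object, ...) {
  t <- object$table
  df <- tibble::tibble(
    metric = rep(c("Z (mm)", "Xrot (deg)", "Yrot (deg)", "MAD sum (mm)"),
                 each = nrow(t)),
    value = c(abs(t$Z_mm), abs(t$Xrot_deg), abs(t$Yrot_deg), t$mad_sum_mm))
  ggplot2::ggplot(df, ggplot2::aes(x = metric, y = value)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "absolute repeat difference",
                  title = "Re-superimposition reproducibility") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
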