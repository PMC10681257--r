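# broom-style tidiers for the package's fitted objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-iteration trace of an ICP fit
#' @param x an `icp_fit`.
#' @param ... unused.
#' @return tibble with columns `iteration`, `rms_mm`.
#' @method tidy icp_fit
#' @export
tidy.icp_fit <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$trace), rms_mm = x$trace)
}

#' One-row summary of an ICP fit
#' @param x an `icp_fit`.
#' @param ... unused.
#' @method glance icp_fit
#' @export
glance.icp_fit <- function(x, ...) {
  tibble::tibble(iterations = x$iterations, rms_mm = x$rms,
                 converged = x$converged, n_overhang_excluded = x$n_excluded,
                 metric = x$config$metric)
}

#' Tidy a midsagittal-plane fit: the plane parameters
#' @param x a `midplane` (from [fit_midsagittal_plane()]).
#' @param ... unused.
#' @method tidy midplane
#' @export
tidy.midplane <- function(x, ...) {
  tibble::tibble(term = c("nx", "ny", "nz", "offset_mm"),
                 estimate = c(x$plane$normal, x$plane$offset))
}

#' One-row summary of a midsagittal-plane fit
#' @param x a `midplane`.
#' @param ... unused.
#' @method glance midplane
#' @export
glance.midplane <- function(x, ...) {
  tibble::tibble(n_midpoints = x$n, max_residual_mm = x$max_residual,
                 rms_residual_mm = x$rms_residual,
                 lambda1 = x$eigenvalues[1], lambda2 = x$eigenvalues[2],
                 lambda3 = x$eigenvalues[3])
}

#' Tidy a reproducibility run: one row per repeat
#' @param x a `repro_result`.
#' @param ... unused.
#' @method tidy repro_result
#' @export
tidy.repro_result <- function(x, ...) x$table

#' One-row maxima summary of a reproducibility run
#' @param x a `repro_result`.
#' @param ... unused.
#' @method glance repro_result
#' @export
glance.repro_result <- function(x, ...) {
  tibble::as_tibble(summary(x))
}
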