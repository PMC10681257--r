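#' ICP registration settings
#'
#' Defaults reproduce the superimposition settings the method is defined
#' with: 100% estimated mesh overlap, point-to-plane metric, exact nearest
#' neighbour search (always exact here), 100% point sampling, and overhang
#' (mesh-boundary) correspondences excluded.
#'
#' @param overlap_fraction fraction (0,1] of correspondences retained,
#'   keeping the smallest distances (trimmed ICP knob; default 1 = all).
#' @param sampling_fraction fraction (0,1] of moving vertices used,
#'   drawn once as a seeded uniform subsample (default 1 = all).
#' @param metric `"point_to_plane"` (default) or `"point_to_point"`.
#' @param exclude_overhang drop correspondences whose closest point lies
#'   on the target boundary (default `TRUE`).
#' @param max_iterations iteration cap (default 200).
#' @param convergence_tol stop when the RMS residual changes by less than
#'   this between iterations (mm; default 1e-6).
#' @param seed integer seed for the vertex subsample when
#'   `sampling_fraction < 1`.
#' @return an object of class `icp_config`.
#' @export
icp_config <- function(overlap_fraction = 1.0, sampling_fraction = 1.0,
                       metric = c("point_to_plane", "point_to_point"),
                       exclude_overhang = TRUE, max_iterations = 200L,
                       convergence_tol = 1e-6, seed = 1L) {
  metric <- match.arg(metric)
  if (!(overlap_fraction > 0 && overlap_fraction <= 1))
    stop("overlap_fraction must be in (0, 1]", call. = FALSE)
  if (!(sampling_fraction > 0 && sampling_fraction <= 1))
    stop("sampling_fraction must be in (0, 1]", call. = FALSE)
  if (convergence_tol <= 0) stop("convergence_tol must be > 0", call. = FALSE)
  structure(list(overlap_fraction = overlap_fraction,
                 sampling_fraction = sampling_fraction, metric = metric,
                 exclude_overhang = isTRUE(exclude_overhang),
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol, seed = as.integer(seed)),
            class = "icp_config")
}

#' Read an ICP configuration from a YAML or JSON file
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return an `icp_config`.
#' @export
read_icp_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
          else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(icp_config, vals[names(vals) %in% names(formals(icp_config))])
}

#' Rigid best-fit of a moving mesh onto a fixed surface (ICP)
#'
#' Iterates: (1) exact closest-point correspondences from the moving
#' vertices to the fixed surface; (2) optional rejection of boundary
#' (overhang) correspondences and of the largest distances when
#' `overlap_fraction < 1`; (3) a linearised point-to-plane least-squares
#' solve for an incremental rigid update (the target triangle's face
#' normal supplies the plane), with SVD re-orthonormalisation of the
#' accumulated rotation.  The fixed mesh never moves.  Stops when the RMS
#' residual change drops below `convergence_tol` or at `max_iterations`.
#'
#' @param moving,fixed `surface_mesh` objects; `moving` is registered onto
#'   `fixed`.
#' @param config an [icp_config()].
#' @param initial optional `rigid_transform` applied to `moving` before
#'   iteration starts.
#' @return an object of class `icp_fit`: `transform` (the
#'   `rigid_transform` mapping the original moving mesh into alignment),
#'   `aligned` (the transformed moving mesh), `iterations`, `rms`
#'   (final RMS residual, mm), `trace` (per-iteration RMS), `n_excluded`
#'   (overhang correspondences dropped at the last iteration) and
#'   `converged`.
#' @export
icp_align <- function(moving, fixed, config = icp_config(),
                      initial = rigid_transform()) {
  stopifnot(inherits(moving, "surface_mesh"), inherits(fixed, "surface_mesh"))
  if (n_faces(fixed) < 1L || n_vertices(moving) < 1L)
    stop("both meshes must be non-empty", call. = FALSE)
  if (!inherits(config, "icp_config")) stop("invalid config", call. = FALSE)

  topo <- boundary_topology(fixed)
  fnorm <- face_normals(fixed)

  idx <- seq_len(n_vertices(moving))
  if (config$sampling_fraction < 1) {
    k <- max(6L, ceiling(config$sampling_fraction * length(idx)))
    old <- local_seed(config$seed)
    idx <- sort(sample(idx, k))
    restore_seed(old)
  }

  P0 <- moving$vertices[idx, , drop = FALSE]
  Rtot <- initial$A
  ttot <- initial$t
  P <- transform_points(P0, initial)

  trace <- numeric(0)
  rms_prev <- Inf
  n_excl <- 0L
  converged <- FALSE
  iters <- 0L

  for (it in seq_len(config$max_iterations)) {
    iters <- it
    cp <- closest_point_batch(P, fixed, topo)
    use <- rep(TRUE, nrow(P))
    if (config$exclude_overhang) use <- use & !cp$boundary
    n_excl <- sum(cp$boundary)
    if (config$overlap_fraction < 1) {
      keep_n <- max(6L, ceiling(config$overlap_fraction * sum(use)))
      ord <- order(cp$distance)
      ord <- ord[use[ord]][seq_len(min(keep_n, sum(use)))]
      use <- rep(FALSE, nrow(P))
      use[ord] <- TRUE
    }
    if (sum(use) < 6L)
      stop("no usable correspondences (all excluded as overhang)",
           call. = FALSE)

    p <- P[use, , drop = FALSE]
    q <- cp$point[use, , drop = FALSE]
    if (config$metric == "point_to_plane") {
      nrm <- fnorm[cp$face[use], , drop = FALSE]
      r <- rowSums((p - q) * nrm)
      # jacobian rows: [ p x n , n ]
      J <- cbind(p[, 2] * nrm[, 3] - p[, 3] * nrm[, 2],
                 p[, 3] * nrm[, 1] - p[, 1] * nrm[, 3],
                 p[, 1] * nrm[, 2] - p[, 2] * nrm[, 1],
                 nrm)
    } else {
      d <- p - q
      r <- as.vector(t(d))
      J <- matrix(0, 3L * nrow(p), 6L)
      # rows for x,y,z residuals of each point: d/domega (-[p]x) and I
      px <- p[, 1]; py <- p[, 2]; pz <- p[, 3]
      i3 <- seq_len(nrow(p)) * 3L
      J[i3 - 2L, ] <- cbind(0, pz, -py, 1, 0, 0)
      J[i3 - 1L, ] <- cbind(-pz, 0, px, 0, 1, 0)
      J[i3, ] <- cbind(py, -px, 0, 0, 0, 1)
    }
    rms <- sqrt(mean(r^2))
    trace <- c(trace, rms)

    if (abs(rms_prev - rms) < config$convergence_tol) {
      converged <- TRUE
      break
    }
    rms_prev <- rms

    JtJ <- crossprod(J)
    Jtr <- crossprod(J, r)
    x <- tryCatch(solve(JtJ, -Jtr), error = function(e) rep(NA_real_, 6L))
    if (any(!is.finite(x))) {
      err <- simpleError("non-finite ICP update")
      err$trace <- trace
      stop(err)
    }
    w <- x[1:3]
    tr <- x[4:6]
    W <- matrix(c(0, -w[3], w[2], w[3], 0, -w[1], -w[2], w[1], 0), 3L, 3L,
                byrow = TRUE)
    Rinc <- project_orthonormal(diag(3) + W, proper = TRUE)
    Rtot <- Rinc %*% Rtot
    ttot <- as.numeric(Rinc %*% ttot + tr)
    Rtot <- project_orthonormal(Rtot, proper = TRUE)
    P <- sweep(P0 %*% t(Rtot), 2, ttot, `+`)
  }

  transform <- rigid_transform(Rtot, ttot)
  structure(list(transform = transform,
                 aligned = apply_transform(moving, transform),
                 iterations = iters, rms = trace[length(trace)],
                 trace = trace, n_excluded = n_excl,
                 converged = converged, config = config),
            class = "icp_fit")
}

#' @export
print.icp_fit <- function(x, ...) {
  cat(sprintf(
    "<icp_fit> %d iteration(s), RMS residual %.3g mm, %s, %d overhang excluded\n",
    x$iterations, x$rms, if (x$converged) "converged" else "max iterations",
    x$n_excluded))
  invisible(x)
}

#' Mirror a mesh and best-fit the mirrored copy back onto the original
#'
#' The heart of the method: the mesh is duplicated and mirrored (with its
#' measurement-area selections), and the mirrored duplicate is registered
#' onto the original by ICP.  The original never moves.  The net map from
#' original vertex `i` to aligned mirrored vertex `i` is an improper
#' isometry (ICP rigid motion composed with the reflection); for a
#' perfectly symmetric surface it is numerically the reflection across the
#' true symmetry plane.
#'
#' @inheritParams mirror_mesh
#' @param config an [icp_config()].
#' @return an object of class `mirror_fit`: `aligned` (aligned mirrored
#'   mesh, index-corresponding with the original), `net`
#'   (`improper_isometry`), `icp` (`icp_fit`), `mirror` (the reflection
#'   used), `selections`, `original`, `frame`.
#' @export
mirror_fit <- function(mesh, frame = canonical_frame(), selections = NULL,
                       config = icp_config()) {
  mir <- mirror_mesh(mesh, frame, selections)
  fit <- icp_align(mir$mesh, mesh, config)
  net <- compose_isometries(fit$transform, mir$isometry)
  structure(list(aligned = fit$aligned, net = net, icp = fit,
                 mirror = mir$isometry, selections = selections,
                 original = mesh, frame = frame),
            class = "mirror_fit")
}

#' @export
print.mirror_fit <- function(x, ...) {
  cat("<mirror_fit>\n  ")
  print(x$icp)
  invisible(x)
}

# seed helpers: run seeded code without disturbing the session RNG
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
with_seed <- function(seed, expr) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  expr
}
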