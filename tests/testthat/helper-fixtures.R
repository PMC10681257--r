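# Shared fixtures and independent oracles, all built in code.

# flat rectangular grid mesh in the y-z plane at x = x0 (faces wound so
# outward normals point +x)
flat_grid_mesh <- function(ny = 3, nz = 3, dy = 1, dz = 1, x0 = 0) {
  y <- seq(0, by = dy, length.out = ny)
  z <- seq(0, by = dz, length.out = nz)
  verts <- cbind(x = x0, y = rep(y, nz), z = rep(z, each = ny))
  iy <- rep(seq_len(ny - 1L), nz - 1L)
  iz <- rep(seq_len(nz - 1L), each = ny - 1L)
  v00 <- (iz - 1L) * ny + iy; v01 <- iz * ny + iy
  v10 <- v00 + 1L; v11 <- v01 + 1L
  surface_mesh(verts, rbind(cbind(v00, v10, v11), cbind(v00, v11, v01)))
}

# icosahedron-ish random convex-ish mesh: unit-sphere fibonacci points with
# convex hull faces is unavailable; instead use a jittered sphere grid
sphere_mesh <- function(n_theta = 10, n_phi = 20, r = 1) {
  th <- seq(0.15, pi - 0.15, length.out = n_theta)
  ph <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  verts <- do.call(rbind, lapply(th, function(t)
    cbind(r * sin(t) * cos(ph), r * sin(t) * sin(ph), r * cos(t))))
  idx <- function(i, j) (i - 1L) * n_phi + ((j - 1L) %% n_phi) + 1L
  faces <- do.call(rbind, lapply(seq_len(n_theta - 1L), function(i)
    do.call(rbind, lapply(seq_len(n_phi), function(j)
      rbind(c(idx(i, j), idx(i, j + 1), idx(i + 1, j)),
            c(idx(i + 1, j), idx(i, j + 1), idx(i + 1, j + 1)))))))
  surface_mesh(verts, faces)
}

# small random triangle soup (for oracle comparisons)
random_mesh <- function(n_faces = 50, seed = 1) {
  set.seed(seed)
  verts <- matrix(runif(3 * 3 * n_faces, -5, 5), ncol = 3)
  surface_mesh(verts, matrix(seq_len(3 * n_faces), ncol = 3, byrow = TRUE))
}

small_face <- function(seed = 1, n = 40) {
  generate_face(face_spec(ny = n, nz = n, seed = seed))
}

# ---- independent closest-point oracle -------------------------------------
# Candidate-based point-to-triangle distance: the in-plane projection (if
# its barycentric coordinates are inside) and the closest points of the
# three edge segments.  Deliberately different logic from the package's
# region-classification implementation.

oracle_point_segment <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / sum(ab * ab)
  t <- min(1, max(0, t))
  a + t * ab
}

oracle_point_triangle <- function(p, a, b, c) {
  n <- pracma::cross(b - a, c - a)
  cand <- list(oracle_point_segment(p, a, b), oracle_point_segment(p, b, c),
               oracle_point_segment(p, c, a))
  if (sum(n * n) > 0) {
    q <- p - sum((p - a) * n) / sum(n * n) * n
    # barycentric via 2x2 solve
    M <- cbind(b - a, c - a)
    st <- tryCatch(qr.solve(crossprod(M), crossprod(M, q - a)),
                   error = function(e) NULL)
    if (!is.null(st) && st[1] >= 0 && st[2] >= 0 && sum(st) <= 1)
      cand <- c(cand, list(as.numeric(a + M %*% st)))
  }
  d <- vapply(cand, function(q) sqrt(sum((p - q)^2)), numeric(1))
  list(distance = min(d), point = cand[[which.min(d)]])
}

oracle_closest_on_mesh <- function(p, mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  best <- list(distance = Inf, point = NULL)
  for (i in seq_len(nrow(f))) {
    r <- oracle_point_triangle(p, v[f[i, 1], ], v[f[i, 2], ], v[f[i, 3], ])
    if (r$distance < best$distance) best <- r
  }
  best
}

max_abs <- function(x) max(abs(x))

# vertices incident to a boundary edge (edge with one incident face)
boundary_vertices <- function(mesh) {
  f <- mesh$faces
  ea <- rbind(cbind(f[, 2], f[, 3]), cbind(f[, 3], f[, 1]),
              cbind(f[, 1], f[, 2]))
  key <- paste(pmin(ea[, 1], ea[, 2]), pmax(ea[, 1], ea[, 2]))
  onb <- table(key)[key] == 1L
  out <- logical(n_vertices(mesh))
  if (any(onb)) out[unique(as.vector(ea[onb, ]))] <- TRUE
  out
}

# sign-insensitive angle (degrees) between a fitted plane and a reference
angle_to_truth <- function(plane, truth) {
  cu <- abs(sum(plane$normal * truth$normal))
  acos(min(1, cu)) * 180 / pi
}
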