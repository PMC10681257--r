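test_that("surface_mesh validates its invariants", {
  expect_error(surface_mesh(matrix(numeric(0), 0, 3), matrix(1L, 0, 3)),
               "empty mesh")
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_error(surface_mesh(v, rbind(c(1L, 2L, 4L))), "out of range")
  expect_error(surface_mesh(v, rbind(c(1L, 2L, 2L))), "repeats a vertex")
  expect_error(vertex_selection("a", c(1, 10), surface_mesh(v, rbind(1:3))),
               "vertex 10 of a 3-vertex mesh")
})

test_that("mirroring reflects across the centroid lateral plane with det -1", {
  f <- small_face(seed = 3)
  mir <- mirror_mesh(f$mesh)
  expect_s3_class(mir$isometry, "improper_isometry")
  expect_equal(det(mir$isometry$A), -1, tolerance = 1e-12)
  # the returned isometry maps original vertex i to mirrored vertex i exactly
  mapped <- sweep(f$mesh$vertices %*% t(mir$isometry$A), 2,
                  mir$isometry$t, `+`)
  expect_identical(unname(mapped), unname(mir$mesh$vertices))
  # symmetric face about z = 0 with centroid on the plane: the mirrored
  # vertex set equals the original set at contralateral (twin) indices
  expect_lt(max_abs(mir$mesh$vertices -
                    f$mesh$vertices[f$truth$twin_index, ]), 1e-9)
})

test_that("mirroring twice composes to the identity", {
  f <- small_face(seed = 4)
  m1 <- mirror_mesh(f$mesh)
  m2 <- mirror_mesh(m1$mesh)
  expect_lt(max_abs(m2$mesh$vertices - f$mesh$vertices), 1e-12)
  net <- compose_isometries(m2$isometry, m1$isometry)
  expect_lt(max_abs(net$A - diag(3)), 1e-12)
  expect_lt(max_abs(net$t), 1e-12)
  expect_identical(m2$mesh$faces, f$mesh$faces)  # winding flipped twice
})

test_that("reflection preserves pairwise distances (isometry)", {
  f <- small_face(seed = 5, n = 12)
  mir <- mirror_mesh(f$mesh)
  idx <- seq(1, n_vertices(f$mesh), by = 13)
  d0 <- dist(f$mesh$vertices[idx, ])
  d1 <- dist(mir$mesh$vertices[idx, ])
  expect_lt(max_abs(d0 - d1), 1e-9)
})

test_that("apply_transform round-trips and rejects bad input", {
  f <- small_face(seed = 6, n = 10)
  tr <- random_rigid(20, 15, seed = 9)
  back <- invert_isometry(tr)
  m2 <- apply_transform(apply_transform(f$mesh, tr), back)
  expect_lt(max_abs(m2$vertices - f$mesh$vertices), 1e-12)
  shift <- rigid_transform(diag(3), c(1, 0, 0))
  expect_equal(apply_transform(f$mesh, shift)$vertices[, "x"],
               f$mesh$vertices[, "x"] + 1)
  expect_error(rigid_transform(matrix(2 * diag(3), 3), c(0, 0, 0)),
               "orthonormal")
  expect_error(apply_transform(f$mesh, list(A = diag(3), t = c(0, 0, 0))),
               "transform")
})

test_that("crop_box keeps exactly the all-inside faces and remaps selections", {
  # 2 x 2 squares toy grid: 9 vertices, 8 triangles
  g <- flat_grid_mesh(3, 3)
  # box covering the left half (z in [0, 1]): one column of squares
  cr <- crop_box(g, rbind(c(-Inf, -Inf, 0), c(Inf, Inf, 1)),
                 selections = list(vertex_selection("s", c(1, 5, 9))))
  expect_equal(n_faces(cr$mesh), 4)
  expect_equal(n_vertices(cr$mesh), 6)
  # output faces are a subset of input faces by vertex coordinates
  key <- function(m) apply(m$faces, 1, function(f)
    paste(sort(apply(m$vertices[f, ], 1, paste, collapse = ",")),
          collapse = "|"))
  expect_true(all(key(cr$mesh) %in% key(g)))
  # index map: injective on retained vertices, round-trips coordinates
  im <- cr$index_map
  kept <- which(!is.na(im))
  expect_false(any(duplicated(im[kept])))
  expect_identical(g$vertices[kept, ], cr$mesh$vertices[im[kept], ])
  # selection remap: vertex 9 (z = 2) dropped silently
  expect_equal(cr$selections$s$indices, im[c(1, 5)])

  # box containing everything: identity crop
  all_cr <- crop_box(g, rbind(c(-Inf, -Inf, -Inf), c(Inf, Inf, Inf)))
  expect_identical(all_cr$mesh$vertices, g$vertices)
  expect_identical(all_cr$index_map, seq_len(9L))
  expect_error(crop_box(g, rbind(c(10, 10, 10), c(11, 11, 11))),
               "empty crop")
})

test_that("vertex normals: flat grids, spheres, winding flips", {
  g <- flat_grid_mesh(4, 4)
  vn <- vertex_normals(g)
  expect_lt(max_abs(sweep(vn, 2, c(1, 0, 0))), 1e-12)
  # winding flip negates all normals
  g2 <- g
  g2$faces <- g$faces[, c(1, 3, 2)]
  expect_lt(max_abs(vertex_normals(g2) + vn), 1e-12)
  # sphere tessellation: interior normals within 5 degrees of the radial
  # direction (cap-ring vertices have one-sided stars and are excluded)
  s <- sphere_mesh(n_theta = 12, n_phi = 24)
  sn <- vertex_normals(s)
  radial <- s$vertices / sqrt(rowSums(s$vertices^2))
  interior <- !boundary_vertices(s)
  ang <- acos(pmin(1, abs(rowSums(sn * radial)))) * 180 / pi
  expect_lt(max(ang[interior]), 5)
  # isolated vertex: zero normal, flagged
  iso <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(9, 9, 9)),
                      rbind(1:3))
  n4 <- vertex_normals(iso)
  expect_true(attr(n4, "isolated")[4])
  expect_identical(n4[4, ], c(0, 0, 0))
})
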