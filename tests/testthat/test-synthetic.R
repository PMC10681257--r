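test_that("generated faces are exactly mirror-symmetric and deterministic", {
  f <- generate_face(face_spec(ny = 30, nz = 31, noise_sd = 0.2, seed = 9))
  v <- f$mesh$vertices
  tw <- f$truth$twin_index
  # for every vertex (x, y, z) the twin (x, y, -z) exists exactly
  expect_lt(max_abs(v[, "x"] - v[tw, "x"]), 1e-12)
  expect_lt(max_abs(v[, "y"] - v[tw, "y"]), 1e-12)
  expect_lt(max_abs(v[, "z"] + v[tw, "z"]), 1e-12)
  # determinism: same seed, bit-identical meshes
  f2 <- generate_face(face_spec(ny = 30, nz = 31, noise_sd = 0.2, seed = 9))
  expect_identical(f$mesh$vertices, f2$mesh$vertices)
  expect_identical(f$mesh$faces, f2$mesh$faces)
})

test_that("grid size formula: 100 x 100 gives 10,000 vertices, 19,602 faces", {
  f <- generate_face(face_spec(ny = 100, nz = 100))
  expect_equal(n_vertices(f$mesh), 10000L)
  expect_equal(n_faces(f$mesh), 19602L)
  expect_error(face_spec(ny = 4), "at least 8 x 8")
  expect_error(face_spec(features = list(list(y = 0, z = 0, a = 1, w = 0))),
               "widths")
})

test_that("asymmetry injection: amplitude, footprints, twins", {
  f0 <- small_face(seed = 41, n = 50)
  same <- inject_asymmetry(f0, bumps = list(list(y = 0, z = -20, a = 0,
                                                 w = 10)))
  expect_identical(same$mesh$vertices, f0$mesh$vertices)
  # centre the bump on a grid point so its peak is sampled exactly
  ctr <- list(y = f0$truth$grid$y[20], z = f0$truth$grid$z[15])
  f2 <- inject_asymmetry(f0, bumps = list(list(y = ctr$y, z = ctr$z, a = 2,
                                               w = 10)))
  dx <- f2$mesh$vertices[, "x"] - f0$mesh$vertices[, "x"]
  expect_equal(max(abs(dx)), 2, tolerance = 0.01)
  fp <- f2$truth$footprints
  expect_equal(length(fp$bump1$indices), length(fp$bump1_twin$indices))
  expect_identical(sort(f2$truth$twin_index[fp$bump1$indices]),
                   fp$bump1_twin$indices)
  # smooth random field reaches its nominal amplitude and is seeded
  fr1 <- inject_asymmetry(f0, field = list(amplitude = 1, corr_len = 20,
                                           seed = 3))
  fr2 <- inject_asymmetry(f0, field = list(amplitude = 1, corr_len = 20,
                                           seed = 3))
  expect_identical(fr1$mesh$vertices, fr2$mesh$vertices)
  expect_equal(max(abs(fr1$mesh$vertices[, "x"] - f0$mesh$vertices[, "x"])),
               1, tolerance = 1e-9)
})

test_that("apply_pose transforms mesh and ground truth covariantly", {
  f <- small_face(seed = 42, n = 21)  # odd lateral count: z = 0 column exists
  posed <- apply_pose(f, max_rotation_deg = 25, max_translation_mm = 12,
                      seed = 4)
  # the true plane still passes through the posed midline vertices
  mid <- which(abs(f$mesh$vertices[, "z"]) < 1e-9)
  expect_gt(length(mid), 0)
  d <- posed$mesh$vertices[mid, ] %*% posed$truth$plane$normal -
    posed$truth$plane$offset
  expect_lt(max_abs(d), 1e-9)
  # seeded repeatability; identity pose bounds respected
  posed2 <- apply_pose(f, 25, 12, seed = 4)
  expect_identical(posed$mesh$vertices, posed2$mesh$vertices)
  expect_error(apply_pose(f, max_rotation_deg = 60, seed = 1),
               "outside the registration basin")
})

test_that("crop variants: containment chain, asymmetry, nibble variation", {
  f <- small_face(seed = 43, n = 60)
  crops <- make_crops(f, seed = 1)
  coord_set <- function(m) {
    apply(m$vertices, 1, paste, collapse = ",")
  }
  c1 <- coord_set(crops$crop1$mesh)
  c2 <- coord_set(crops$crop2$mesh)
  c3 <- coord_set(crops$crop3$mesh)
  expect_true(all(c2 %in% c3))
  expect_true(all(c3 %in% c1))
  # crop 3 is laterally asymmetric about the true plane
  zr <- range(crops$crop3$mesh$vertices[, "z"])
  expect_gt(abs(zr[2] + zr[1]), 5)
  # crop 2 is laterally symmetric
  zr2 <- range(crops$crop2$mesh$vertices[, "z"])
  expect_lt(abs(zr2[2] + zr2[1]), 1e-9)
  # crop 4 removes at most 5% of crop 1's vertices and differs by seed
  n1 <- n_vertices(crops$crop1$mesh)
  n4 <- n_vertices(crops$crop4$mesh)
  expect_lt((n1 - n4) / n1, 0.05)
  expect_gt(n1 - n4, 0)
  crops_b <- make_crops(f, seed = 2)
  expect_false(identical(coord_set(crops_b$crop4$mesh),
                         coord_set(crops$crop4$mesh)))
  # selections remain valid in every crop
  for (cr in crops)
    for (s in cr$selections)
      if (length(s$indices))
        expect_lte(max(s$indices), n_vertices(cr$mesh))
})

test_that("pipeline closure: symmetric fixture recovers its ground truth", {
  f <- inject_asymmetry(small_face(seed = 44, n = 50), bumps = list())
  res <- midsagittal_from_mesh(f$mesh)
  expect_lt(angle_to_truth(res$plane, f$truth$plane), 0.01)
  expect_lt(abs(res$plane$offset - f$truth$plane$offset), 0.01)
})
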