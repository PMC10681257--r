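test_that("midpoints are the element-wise means of corresponding vertices", {
  f <- small_face(seed = 21, n = 10)
  iso <- compose_isometries(
    random_rigid(15, 8, seed = 2),
    mirror_mesh(f$mesh)$isometry)  # improper net map
  img <- apply_transform(f$mesh, iso)
  mp <- midpoints(f$mesh, img)
  v <- f$mesh$vertices
  expected <- (v + sweep(v %*% t(iso$A), 2, iso$t, `+`)) / 2
  expect_lt(max_abs(mp - expected), 1e-12)
  a <- surface_mesh(rbind(c(0, 0, 1), c(1, 0, 1), c(0, 1, 1)), rbind(1:3))
  b <- surface_mesh(rbind(c(0, 0, -1), c(1, 0, -1), c(0, 1, -1)), rbind(1:3))
  expect_equal(midpoints(a, b)[1, ], c(x = 0, y = 0, z = 0))
  expect_error(midpoints(f$mesh, a), "vertex counts differ")
})

test_that("pure reflection: plane recovered exactly", {
  f <- small_face(seed = 22, n = 20)
  mir <- mirror_mesh(f$mesh)  # centroid plane is z = 0 for this mesh
  mp <- fit_midsagittal_plane(midpoints(f$mesh, mir$mesh))
  expect_lt(max_abs(abs(mp$plane$normal) - c(0, 0, 1)), 1e-9)
  expect_lt(abs(mp$plane$offset), 1e-9)
  expect_lt(mp$max_residual, 1e-9)
})

test_that("coplanarity holds for any improper isometry (rotation <= 30 deg)", {
  f <- small_face(seed = 23, n = 20)
  refl <- mirror_mesh(f$mesh)$isometry
  diag_len <- bbox_diagonal(f$mesh)
  for (s in 1:25) {
    iso <- compose_isometries(random_rigid(30, 20, seed = s), refl)
    img <- apply_transform(f$mesh, iso)
    mp <- fit_midsagittal_plane(midpoints(f$mesh, img))
    expect_lt(mp$max_residual, 1e-9 * diag_len)
  }
})

test_that("three non-collinear midpoints give the analytic plane", {
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 1))
  mp <- fit_midsagittal_plane(pts)
  n_analytic <- c(0, -1, 1) / sqrt(2)  # normal of the 3-point plane
  expect_lt(min(max_abs(mp$plane$normal - n_analytic),
                max_abs(mp$plane$normal + n_analytic)), 1e-12)
  expect_lt(mp$max_residual, 1e-12)
})

test_that("degenerate midpoint clouds are rejected", {
  # 3D blob: no unique plane
  set.seed(1)
  blob <- matrix(rnorm(300), ncol = 3)
  expect_error(fit_midsagittal_plane(blob), "degenerate midpoint cloud")
  # collinear cloud
  line <- cbind(1:50, 2 * (1:50), 0.5 * (1:50))
  expect_error(fit_midsagittal_plane(line), "degenerate midpoint cloud")
})

test_that("plane fit is stable under 50% subsampling", {
  f <- small_face(seed = 24, n = 40)
  mir <- mirror_mesh(f$mesh)
  cloud <- midpoints(f$mesh, mir$mesh)
  full <- fit_midsagittal_plane(cloud)
  set.seed(7)
  half <- fit_midsagittal_plane(cloud[sample(nrow(cloud), nrow(cloud) / 2), ])
  expect_lt(max_abs(full$plane$normal - half$plane$normal), 1e-9)
  expect_lt(abs(full$plane$offset - half$plane$offset), 1e-9)
})

test_that("plane differences: identity, translation, rotation, antisymmetry", {
  a <- plane3(c(0, 0, 1), 5)
  expect_equal(unlist(plane_difference(a, a, reference_point = c(3, 2, 0))),
               c(Z_mm = 0, Xrot_deg = 0, Yrot_deg = 0))
  # pure translation along the normal
  b <- plane3(c(0, 0, 1), 6)
  pd <- plane_difference(a, b, reference_point = c(10, -4, 0))
  expect_equal(pd$Z_mm, 1, tolerance = 1e-12)
  expect_equal(pd$Xrot_deg, 0)
  expect_equal(pd$Yrot_deg, 0)
  # rotation of 2 degrees about the frame X axis through the anchor
  ref <- c(1, 2, 5)  # a point on plane a
  th <- 2 * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  n2 <- as.numeric(Rx %*% c(0, 0, 1))
  b2 <- plane3(n2, sum(n2 * ref))
  pd2 <- plane_difference(a, b2, reference_point = ref)
  expect_equal(pd2$Xrot_deg, 2, tolerance = 1e-6)
  expect_equal(pd2$Yrot_deg, 0, tolerance = 1e-9)
  expect_equal(pd2$Z_mm, 0, tolerance = 1e-9)
  # rotation components change sign when the planes swap roles
  pd2r <- plane_difference(b2, a, reference_point = ref)
  expect_equal(pd2r$Xrot_deg, -pd2$Xrot_deg, tolerance = 1e-9)
  # orientation contract: anti-parallel or steep normals are rejected
  expect_error(plane_difference(a, plane3(c(0, 0, -1), 0)),
               "anti-parallel")
  expect_error(plane_difference(a, plane3(c(1, 0, 0.2), 0)), "45 degrees")
})

test_that("midsagittal plane recovery: exact face, bumped face", {
  f <- small_face(seed = 25, n = 60)
  res <- midsagittal_from_mesh(f$mesh)
  expect_lt(angle_to_truth(res$plane, f$truth$plane), 0.01)
  expect_lt(abs(res$plane$offset - f$truth$plane$offset), 0.01)
  # a 1 mm one-sided cheek bump barely tilts the global plane
  fb <- inject_asymmetry(small_face(seed = 25, n = 60),
                         bumps = list(list(y = -15, z = -35, a = 1, w = 9)))
  resb <- midsagittal_from_mesh(fb$mesh)
  expect_lt(angle_to_truth(resb$plane, fb$truth$plane), 0.2)
})
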