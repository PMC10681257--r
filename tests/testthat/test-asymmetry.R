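test_that("distance maps: zero on self, analytic on parallel grids, oracle", {
  f <- small_face(seed = 31, n = 12)
  m0 <- distance_map(f$mesh, f$mesh)
  expect_lt(max(m0$distance), 1e-12)
  # two parallel flat grids 1 mm apart: interior vertices at distance 1,
  # uniform sign (+: target lies along the source outward normal +x)
  g1 <- flat_grid_mesh(5, 5)
  g2 <- flat_grid_mesh(5, 5, x0 = 1)
  mp <- distance_map(g1, g2)
  inner <- !mp$boundary
  expect_true(any(inner))
  expect_lt(max_abs(mp$distance[inner] - 1), 1e-12)
  expect_true(all(mp$signed[inner] > 0))
})

test_that("distance map equals the brute-force oracle on random meshes", {
  src <- small_face(seed = 32, n = 8)
  tgt <- random_mesh(n_faces = 40, seed = 5)
  got <- distance_map(src$mesh, tgt)
  for (i in seq_len(n_vertices(src$mesh))) {
    ref <- oracle_closest_on_mesh(src$mesh$vertices[i, ], tgt)
    expect_lt(abs(got$distance[i] - ref$distance), 1e-9)
  }
})

test_that("area MAD arithmetic and error handling", {
  map <- tibble::tibble(vertex = 1:6, distance = c(1, 1, 2, 4, 9, 9),
                        signed = c(1, 1, 2, 4, 9, 9),
                        boundary = c(rep(FALSE, 4), TRUE, TRUE))
  s <- vertex_selection("mid", 1:4)
  st <- area_mad(map, s)
  expect_equal(st$mad_mm, 2)
  expect_equal(st$max_mm, 4)
  expect_equal(st$n, 4L)
  # all-zero map
  map0 <- tibble::tibble(vertex = 1:4, distance = 0, signed = 0,
                         boundary = FALSE)
  expect_equal(area_mad(map0, vertex_selection("z", 1:4))$mad_mm, 0)
  # boundary exclusion can empty a selection
  expect_error(area_mad(map, vertex_selection("edge", 5:6)),
               "empty after boundary exclusion")
  expect_equal(area_mad(map, vertex_selection("edge", 5:6),
                        exclude_boundary = FALSE)$mad_mm, 9)
  expect_error(area_mad(map, vertex_selection("none", integer(0))), "empty")
})

test_that("bilateral difference is ~0 for a perfectly symmetric mesh", {
  f <- small_face(seed = 33)
  areas <- default_areas(f)
  mf <- mirror_fit(f$mesh)
  map <- distance_map(f$mesh, mf$aligned)
  expect_lt(abs(bilateral_difference(map, areas$area_B_right,
                                     areas$area_B_left)), 1e-6)
  # bookkeeping: the left area is the twin image of the right area
  expect_identical(sort(f$truth$twin_index[areas$area_B_right$indices]),
                   areas$area_B_left$indices)
})

test_that("footprint MAD grows strictly with injected bump amplitude", {
  mads <- vapply(c(0.5, 1, 2), function(a) {
    f <- inject_asymmetry(small_face(seed = 34, n = 60),
                          bumps = list(list(y = -12, z = -30, a = a, w = 9)))
    mf <- mirror_fit(f$mesh)
    map <- distance_map(f$mesh, mf$aligned)
    area_mad(map, f$truth$footprints$bump1)$mad_mm
  }, numeric(1))
  expect_true(all(diff(mads) > 0))
  # regression range for the 2 mm bump: closest-point distances average the
  # Gaussian profile over its footprint, so footprint MAD is a moderate
  # fraction of the peak amplitude (observed ~0.22 * a on this fixture)
  expect_gt(mads[3], 0.15 * 2)
  expect_lt(mads[3], 0.6 * 2)
})

test_that("bump and contralateral footprints agree after mirror-fit", {
  f <- inject_asymmetry(small_face(seed = 35, n = 60),
                        bumps = list(list(y = -10, z = 28, a = 1.5, w = 10)))
  mf <- mirror_fit(f$mesh)
  map <- distance_map(f$mesh, mf$aligned)
  m_fp <- area_mad(map, f$truth$footprints$bump1)$mad_mm
  m_tw <- area_mad(map, f$truth$footprints$bump1_twin)$mad_mm
  expect_lt(abs(m_fp - m_tw) / max(m_fp, m_tw), 0.2)
})

test_that("colourize maps zero to the palette midpoint and clamps extremes", {
  pal <- diverging_palette()
  ends <- grDevices::col2rgb(pal)
  mid <- colourize(0, scale = c(-2, 2), palette = pal)
  expect_equal(as.integer(mid), as.integer(ends[, (ncol(ends) + 1) / 2]))
  lo <- colourize(c(-2, -99), scale = c(-2, 2), palette = pal)
  hi <- colourize(c(2, 99), scale = c(-2, 2), palette = pal)
  expect_equal(lo[1, ], lo[2, ])  # clamped beyond scale
  expect_equal(hi[1, ], hi[2, ])
  expect_equal(as.integer(lo[1, ]), as.integer(ends[, 1]))
  expect_equal(as.integer(hi[1, ]), as.integer(ends[, ncol(ends)]))
  expect_error(colourize(0, scale = c(2, -2)), "scale min")
})

test_that("distance CSV export round-trips", {
  f <- small_face(seed = 36, n = 8)
  map <- distance_map(f$mesh, f$mesh)
  p <- tempfile(fileext = ".csv")
  write_distance_csv(map, p)
  got <- utils::read.csv(p)
  expect_equal(nrow(got), n_vertices(f$mesh))
  expect_equal(got$signed_mm, map$signed)
})
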