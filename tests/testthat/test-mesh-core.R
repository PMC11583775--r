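test_that("enclosed volume matches closed forms", {
  expect_equal(mesh_volume(mesh_cube(1)), 1)
  expect_equal(mesh_volume(mesh_cube(2)), 8)
  expect_equal(mesh_volume(unit_tetra()), 1 / 6)
  # inscribed icosphere is slightly smaller than the analytic sphere
  v <- mesh_volume(icosphere(10, 4))
  v_true <- 4 / 3 * pi * 1000
  expect_lt(abs(v - v_true) / v_true, 0.005)
  expect_lt(v, v_true)
})

test_that("volume is invariant under rigid motion and flips with winding", {
  m <- small_phantom()
  v0 <- mesh_volume(m)
  set.seed(11)
  for (i in 1:5) {
    r <- random_rotation(pi)
    t <- runif(3, -50, 50)
    mt <- tri_mesh(sweep(m$vertices %*% t(r), 2, t, "+"), m$faces)
    expect_lt(abs(mesh_volume(mt) - v0), 1e-9 * v0)
  }
  flipped <- tri_mesh(m$vertices, m$faces[, c(1, 3, 2)])
  expect_equal(mesh_volume(flipped), -v0)
})

test_that("volume of an open mesh errors with the open-edge count", {
  m <- mesh_cube(1)
  open_cube <- tri_mesh(m$vertices, m$faces[-1, ])
  expect_false(mesh_is_watertight(open_cube))
  expect_error(mesh_volume(open_cube), "3 open edges")
})

test_that("file-size proxy is the binary STL layout and monotone in triangles", {
  empty <- tri_mesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3))
  expect_equal(file_size_proxy(empty), 84)
  expect_equal(file_size_proxy(mesh_cube(1)), 684)
  sizes <- sapply(0:3, function(s) file_size_proxy(icosphere(1, s)))
  expect_true(all(diff(sizes) > 0))
  # proxy equals actual on-disk size of this package's binary export
  for (m in list(mesh_cube(3), icosphere(5, 2), small_phantom())) {
    path <- withr::local_tempfile(fileext = ".stl")
    write_stl(m, path)
    expect_identical(as.numeric(file.size(path)), as.numeric(file_size_proxy(m)))
  }
})

test_that("mesh_metrics bundles volume, count and proxy", {
  mm <- mesh_metrics(mesh_cube(2))
  expect_equal(mm$volume_mm3, 8)
  expect_equal(mm$n_triangles, 12L)
  expect_equal(mm$file_size_bytes, 684)
})

test_that("tri_mesh validates its inputs", {
  expect_error(tri_mesh(matrix(1:6, 2, 3), rbind(c(1, 2, 3))), "outside")
  expect_error(tri_mesh(matrix(1, 1, 2), matrix(integer(0), 0, 3)), "3 columns")
})
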