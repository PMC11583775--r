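test_that("identical meshes deviate by exactly zero", {
  m <- small_phantom()
  d <- signed_surface_deviation(m, m, n_samples = 5000, seed = 1)
  expect_equal(d$mean_dS, 0)
  expect_equal(d$six_sigma_dS, 0)
})

test_that("offset icospheres recover the analytic +0.1 mm mean", {
  d <- signed_surface_deviation(icosphere(10.1, 4), icosphere(10, 4),
                                n_samples = 2e4, seed = 2)
  expect_equal(d$mean_dS, 0.1, tolerance = 0.05) # 0.005 mm absolute
  expect_lt(abs(d$mean_dS - 0.1), 0.005)
})

test_that("a shrunken analyzed object has a negative mean by convention", {
  m <- small_phantom()
  ctr <- colMeans(m$vertices)
  shr <- tri_mesh(sweep(sweep(m$vertices, 2, ctr) * 0.99, 2, ctr, "+"), m$faces)
  d <- signed_surface_deviation(shr, m, n_samples = 1e4, seed = 3)
  expect_lt(d$mean_dS, 0)
})

test_that("swapping analyzed and reference flips the sign for nested spheres", {
  s1 <- icosphere(10, 3)
  s2 <- icosphere(10.5, 3)
  d12 <- signed_surface_deviation(s2, s1, n_samples = 5000, seed = 4)
  d21 <- signed_surface_deviation(s1, s2, n_samples = 5000, seed = 4)
  expect_gt(d12$mean_dS, 0)
  expect_lt(d21$mean_dS, 0)
})

test_that("deviation statistics are invariant under a common rigid motion", {
  a <- icosphere(9.7, 3)
  b <- icosphere(10, 3)
  d0 <- signed_surface_deviation(a, b, n_samples = 5000, seed = 5)
  set.seed(6)
  r <- random_rotation(pi)
  t <- runif(3, -30, 30)
  mt <- function(m) tri_mesh(sweep(m$vertices %*% t(r), 2, t, "+"), m$faces)
  d1 <- signed_surface_deviation(mt(a), mt(b), n_samples = 5000, seed = 5)
  expect_lt(abs(d1$mean_dS - d0$mean_dS), 1e-6)
})

test_that("internal islands drive the mean negative", {
  ref <- icosphere(10, 3)
  isl <- icosphere(2, 2) # strictly inside the reference
  analyzed <- tri_mesh(rbind(ref$vertices, isl$vertices),
                       rbind(ref$faces, isl$faces + nrow(ref$vertices)))
  d_plain <- signed_surface_deviation(ref, ref, n_samples = 5000, seed = 7)
  d_isl <- signed_surface_deviation(analyzed, ref, n_samples = 5000, seed = 7)
  expect_lt(d_isl$mean_dS, d_plain$mean_dS)
  expect_lt(d_isl$mean_dS, 0)
})

test_that("non-watertight reference is rejected for the inside test", {
  open_ref <- tri_mesh(mesh_cube(1)$vertices, mesh_cube(1)$faces[-1, ])
  expect_error(signed_surface_deviation(mesh_cube(1), open_ref),
               "not watertight")
})

test_that("reverse correspondence direction keeps the sign convention", {
  small <- icosphere(9.5, 3)
  big <- icosphere(10, 3)
  d <- signed_surface_deviation(small, big, n_samples = 5000, seed = 8,
                                direction = "reference_to_analyzed")
  expect_lt(d$mean_dS, 0) # analyzed smaller => negative, in either direction
})

test_that("ICP recovers known rigid motions to sub-micrometre accuracy", {
  ph <- small_phantom()
  set.seed(9)
  for (i in 1:3) {
    r <- random_rotation(30 * pi / 180)
    t <- runif(3, -20, 20)
    mv <- tri_mesh(sweep(ph$vertices %*% t(r), 2, t, "+"), ph$faces)
    tf <- icp_align(mv, ph, n_samples = 500, seed = i)
    back <- apply_transform(mv, tf)
    rms <- sqrt(mean(rowSums((back$vertices - ph$vertices)^2)))
    expect_lt(rms, 1e-3)
    # rotation recovered to ~1e-4 rad
    rr <- tf$rotation %*% r
    ang <- acos(pmin(pmax((sum(diag(rr)) - 1) / 2, -1), 1))
    expect_lt(ang, 1e-4)
    expect_true(tf$converged)
  }
})

test_that("ICP on identical meshes is the identity", {
  ph <- small_phantom()
  tf <- icp_align(ph, ph, n_samples = 500, seed = 1)
  expect_lt(max(abs(tf$rotation - diag(3))), 1e-6)
  expect_lt(max(abs(tf$translation)), 1e-4)
})

test_that("grossly mismatched surfaces fail alignment loudly", {
  ph <- small_phantom()
  tiny <- mesh_cube(2, c(200, 200, 200))
  expect_error(icp_align(ph, tiny, n_samples = 200, seed = 1),
               "alignment unreliable")
})

test_that("ASCII export round trip is lossless at six decimals", {
  d <- signed_surface_deviation(icosphere(10.05, 3), icosphere(10, 3),
                                n_samples = 2000, seed = 10)
  path <- withr::local_tempfile(fileext = ".txt")
  write_deviation_ascii(d, path)
  lines <- readLines(path)
  expect_equal(length(lines), d$n_samples + 6) # 5 header lines + column names
  d2 <- read_deviation_ascii(path)
  expect_equal(d2$n_samples, d$n_samples)
  expect_lt(abs(d2$mean_dS - d$mean_dS), 1e-6)
  expect_lt(abs(d2$sigma - d$sigma), 1e-6)
})

test_that("empty statistics export as a header-only file", {
  empty <- printqa:::new_deviation_stats(
    tibble::tibble(x = numeric(0), y = numeric(0), z = numeric(0),
                   deviation = numeric(0)))
  path <- withr::local_tempfile(fileext = ".txt")
  write_deviation_ascii(empty, path)
  lines <- readLines(path)
  expect_equal(length(lines), 6)
  expect_match(lines[2], "n_samples 0")
})

test_that("six-sigma interval is definitionally 6 sigma of the samples", {
  d <- signed_surface_deviation(icosphere(10.2, 3), icosphere(10, 3),
                                n_samples = 3000, seed = 11)
  expect_equal(d$six_sigma_dS, 6 * d$sigma)
  expect_equal(d$six_sigma_dS, 6 * sd(d$samples$deviation))
})
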