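test_that("smoothing profiles resolve the level-to-parameter mappings", {
  expect_equal(smoothing_spec("slicer_like", "low")$median_kernel_mm, 1)
  expect_equal(smoothing_spec("slicer_like", "medium")$median_kernel_mm, 3)
  expect_equal(smoothing_spec("slicer_like", "high")$median_kernel_mm, 5)
  expect_equal(smoothing_spec("brainlab_like", "low")$factor, 0.66)
  expect_equal(smoothing_spec("brainlab_like", "medium")$factor, 1.33)
  expect_equal(smoothing_spec("brainlab_like", "high")$factor, 2.00)
  expect_equal(smoothing_spec("d2p_like", "low")$median_kernel_mm, 1)
  expect_error(smoothing_spec("d2p_like", "medium"), "only level")
})

test_that("median filtering is an identity on constants and removes speckle", {
  arr <- array(37, c(6, 6, 6))
  attr(arr, "spacing") <- c(1, 1, 1)
  out <- smooth_volume_median(arr, 3)
  expect_equal(as.vector(out), rep(37, length(arr)))
  # single-voxel island in air
  arr2 <- array(0, c(9, 9, 9))
  arr2[5, 5, 5] <- 1
  attr(arr2, "spacing") <- c(1, 1, 1)
  out2 <- smooth_volume_median(arr2, 3)
  expect_equal(max(out2), 0)
  # sub-voxel kernel warns and returns input
  expect_warning(out3 <- smooth_volume_median(arr2, 0.4), "smaller than one voxel")
  expect_equal(as.vector(out3), as.vector(arr2))
})

test_that("stronger median kernels shrink a convex mask more", {
  ph <- small_phantom()
  v <- simulate_ct(ph, ct_protocol(1.5, "soft", in_plane_mm = 1, seed = 5))
  # kernels of 2 and 5 mm span 3+ voxels on this 1 mm test grid
  v0 <- segment_threshold(v, -400)$metrics$volume_mm3
  v1 <- segment_threshold(smooth_volume_median(v, 2), -400)$metrics$volume_mm3
  v5 <- segment_threshold(smooth_volume_median(v, 5), -400)$metrics$volume_mm3
  expect_gt(abs(v5 - v0), abs(v1 - v0))
  expect_lt(v5, v0) # shrinkage
})

test_that("Taubin smoothing is identity at factor 0 and shrinks spheres monotonically", {
  ico <- icosphere(10, 3)
  expect_identical(smooth_mesh_factor(ico, 0)$vertices, ico$vertices)
  vols <- sapply(c(0.66, 1.33, 2.0), function(f) mesh_volume(smooth_mesh_factor(ico, f)))
  expect_true(all(diff(c(mesh_volume(ico), vols)) < 0))
  expect_equal(nrow(smooth_mesh_factor(ico, 2)$faces), nrow(ico$faces))
  expect_true(mesh_is_watertight(smooth_mesh_factor(ico, 2)))
})

test_that("mesh smoothing attacks edges and corners, not flat faces", {
  bx <- mesh_box(c(20, 20, 20), subdivisions = 4)
  sm <- smooth_mesh_factor(bx, 1)
  disp <- sqrt(rowSums((sm$vertices - bx$vertices)^2))
  v <- bx$vertices
  on_edge <- rowSums(cbind(v[, 1] %in% c(0, 20), v[, 2] %in% c(0, 20),
                           v[, 3] %in% c(0, 20))) >= 2
  face_center <- apply(abs(sweep(v, 2, c(10, 10, 10))), 1,
                       function(r) sum(r < 4) >= 2) & !on_edge
  expect_gt(mean(disp[on_edge]), 50 * mean(disp[face_center]))
})

test_that("dee_metrics is zero on identity and linear in triangle count", {
  m <- icosphere(8, 2)
  met <- dee_metrics(m, m, n_samples = 2000, seed = 1)
  expect_equal(met$dFi_rel_pct, 0)
  expect_equal(met$dV_rel_pct, 0)
  expect_equal(met$deviation$mean_dS, 0)
  expect_equal(met$deviation$six_sigma_dS, 0)
  # halving the triangle count halves Fi up to the 84-byte header
  before <- mesh_cylinder(segments = 320) # 1280 triangles
  after <- mesh_cylinder(segments = 160)  # 640 triangles
  met2 <- dee_metrics(before, after, n_samples = 2000, seed = 1)
  expect_equal(met2$dFi_rel_pct, -50, tolerance = 0.005)
})

test_that("apply_smoothing dispatches on the profile method", {
  ph <- small_phantom()
  v <- simulate_ct(ph, ct_protocol(1.5, "soft", in_plane_mm = 1, seed = 5))
  seg <- segment_threshold(v, -400)
  out_vol <- apply_smoothing(smoothing_spec("slicer_like", "medium"), seg, v)
  out_mesh <- apply_smoothing(smoothing_spec("brainlab_like", "low"), seg)
  expect_true(mesh_is_watertight(out_vol))
  expect_true(mesh_is_watertight(out_mesh))
  expect_equal(nrow(out_mesh$faces), nrow(seg$mesh$faces)) # mesh method keeps count
  expect_error(apply_smoothing(smoothing_spec("slicer_like", "low"), seg),
               "needs the source")
})
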