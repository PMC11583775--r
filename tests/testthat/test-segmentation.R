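noiseless_volume <- function(mesh = mesh_cube(20), thickness = 0.5) {
  simulate_ct(mesh, ct_protocol(thickness, "soft", in_plane_mm = 0.5,
                                psf_fwhm_mm = 0, noise_sd_hu = 0,
                                slice_profile_fwhm_factor = 0))
}

test_that("relative volume error follows its definition and sign convention", {
  expect_equal(round(relative_volume_error(30000, 51955), 2), -42.26)
  expect_equal(relative_volume_error(123.4, 123.4), 0)
  expect_equal(relative_volume_error(20, 10), 100)
  expect_lt(relative_volume_error(10, 20), 0)
  expect_error(relative_volume_error(10, 0), "v_ref")
  expect_error(relative_volume_error(10, -5), "v_ref")
})

test_that("volume cut-off is inclusive at the boundary", {
  expect_false(passes_cutoff(29999.9))
  expect_true(passes_cutoff(30000))
  expect_true(passes_cutoff(51955))
  expect_error(passes_cutoff(-1), ">= 0")
})

test_that("threshold segmentation recovers a known cube volume", {
  v <- noiseless_volume()
  seg <- segment_threshold(v, -400, reference_volume_mm3 = 8000)
  expect_lt(abs(seg$metrics$volume_mm3 - 8000) / 8000, 0.02)
  expect_lt(abs(seg$rel_volume_error_pct), 2)
  expect_equal(seg$n_components, 1L)
  expect_true(mesh_is_watertight(seg$mesh))
})

test_that("segmented volume is monotone non-increasing in threshold (noiseless)", {
  v <- noiseless_volume(small_phantom(), thickness = 1.5)
  vols <- sapply(c(-800, -600, -400, -200, 0, 100), function(th) {
    segment_threshold(v, th)$metrics$volume_mm3
  })
  expect_true(all(diff(vols) <= 0))
})

test_that("a threshold above the dynamic range is an empty segmentation", {
  v <- noiseless_volume()
  expect_error(segment_threshold(v, 500), "empty segmentation")
})

test_that("island policy controls components and their bookkeeping", {
  # two disjoint cubes in one volume
  arr <- array(-1000, c(30, 30, 30))
  arr[5:12, 5:12, 5:12] <- 200
  arr[20:28, 20:28, 20:28] <- 200
  v <- hu_volume(arr, c(1, 1, 1))
  seg_all <- segment_threshold(v, -400, island_policy = "keep_all")
  expect_equal(seg_all$n_components, 2L)
  seg_big <- segment_threshold(v, -400, island_policy = "largest_component")
  expect_lt(mesh_volume(seg_big$mesh), mesh_volume(seg_all$mesh))
  expect_equal(max(printqa:::cpp_face_components(seg_big$mesh$faces - 1L,
                                                 nrow(seg_big$mesh$vertices))), 1L)
  expect_gte(seg_all$n_components, 1L)
})

test_that("binary-mask surfacing is available behind a flag", {
  v <- noiseless_volume()
  seg <- segment_threshold(v, -400, surface = "binary")
  expect_true(mesh_is_watertight(seg$mesh))
  # mask surfacing quantizes at voxel resolution, so the tolerance is a
  # voxel-scale band rather than the sub-voxel 2% of the default surface
  expect_lt(abs(seg$metrics$volume_mm3 - 8000) / 8000, 0.10)
  sub <- segment_threshold(v, -400)
  expect_lt(abs(sub$metrics$volume_mm3 - 8000),
            abs(seg$metrics$volume_mm3 - 8000))
})

test_that("the volume cut-off flags small segmentations as excluded", {
  arr <- array(-1000, c(20, 20, 20))
  arr[8:12, 8:12, 8:12] <- 200 # ~125 mm^3 at 1 mm spacing
  v <- hu_volume(arr, c(1, 1, 1))
  seg <- segment_threshold(v, -400)
  expect_false(seg$included)
  seg2 <- segment_threshold(v, -400, v_min_mm3 = 1)
  expect_true(seg2$included)
})
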