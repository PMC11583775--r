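# fast noise-free protocol used by several tests
ideal_protocol <- function(thickness = 0.4, in_plane = 0.5) {
  ct_protocol(thickness, "soft", in_plane_mm = in_plane, psf_fwhm_mm = 0,
              noise_sd_hu = 0, slice_profile_fwhm_factor = 0)
}

test_that("occupancy-to-HU mapping hits air, object and midpoint levels", {
  cube <- mesh_cube(20)
  v <- simulate_ct(cube, ideal_protocol())
  expect_equal(min(v$voxels), -1000)
  expect_equal(max(v$voxels), 200)
  # the half-occupancy level sits at -400 HU: check via occupancy directly
  occ <- mesh_occupancy(cube, spacing = c(0.5, 0.5, 0.4))
  hu <- -1000 + occ * 1200
  half <- abs(occ - 0.5) < 0.01
  expect_gt(sum(half), 0)
  expect_true(all(abs(hu[half] + 400) < 15))
})

test_that("noiseless 0.4 mm simulation recovers the volume at -400 HU", {
  cube <- mesh_cube(20)
  v <- simulate_ct(cube, ideal_protocol())
  seg <- segment_threshold(v, -400)
  expect_lt(abs(seg$metrics$volume_mm3 - 8000) / 8000, 0.02)
})

test_that("noise is seeded and reproducible; kernels order air noise", {
  ph <- small_phantom()
  p1 <- ct_protocol(1.5, "soft", in_plane_mm = 1, seed = 7)
  v1 <- simulate_ct(ph, p1)
  v2 <- simulate_ct(ph, p1)
  expect_identical(v1$voxels, v2$voxels)
  p2 <- ct_protocol(1.5, "soft", in_plane_mm = 1, seed = 8)
  v3 <- simulate_ct(ph, p2)
  expect_false(identical(v1$voxels, v3$voxels))
  vb <- simulate_ct(ph, ct_protocol(1.5, "bone", in_plane_mm = 1, seed = 7))
  # homogeneous air corner: bone kernel strictly noisier
  expect_gt(sd(vb$voxels[1:8, 1:8, 1:8]), sd(v1$voxels[1:8, 1:8, 1:8]))
})

test_that("kernel defaults respect the sharpness/noise trade-off", {
  soft <- ct_protocol(1.5, "soft")
  bone <- ct_protocol(1.5, "bone")
  expect_gt(soft$psf_fwhm_mm, bone$psf_fwhm_mm)
  expect_gt(bone$noise_sd_hu, soft$noise_sd_hu)
})

test_that("an explicit grid that cannot hold the mesh errors", {
  cube <- mesh_cube(20)
  expect_error(
    simulate_ct(cube, ideal_protocol(), origin = c(0, 0, 0), dim = c(10L, 10L, 10L)),
    "too small")
  expect_error(
    mesh_occupancy(cube, c(1, 1, 1), origin = c(5, 5, 5), dim = c(10L, 10L, 10L)),
    "too small")
})

test_that("HU values are clamped to the scanner range", {
  v <- hu_volume(array(c(-2000, 5000, 0), c(1, 1, 3)), c(1, 1, 1))
  expect_equal(range(v$voxels), c(-1024, 3071))
})

test_that("NIfTI export writes the volume with its spacing", {
  skip_if_not_installed("RNifti")
  v <- simulate_ct(mesh_cube(10), ideal_protocol(1.5, 1))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume_nifti(v, path)
  img <- RNifti::readNifti(path)
  expect_equal(dim(img), rev(dim(v$voxels)))
  expect_equal(RNifti::pixdim(img), v$spacing, tolerance = 1e-6)
})
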