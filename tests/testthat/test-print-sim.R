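test_that("print simulation is the identity in the zero-deformation limit", {
  ph <- small_phantom()
  out <- simulate_print(ph, print_spec(layer_height_mm = 1e-9,
                                       warp_amplitude_mm = 0))
  expect_lt(max(abs(out$vertices - ph$vertices)), 1e-9)
  expect_identical(out$faces, ph$faces)
})

test_that("staircase displacement is toward the layer floor and watertight", {
  ph <- small_phantom()
  out <- simulate_print(ph, print_spec(layer_height_mm = 0.3))
  dz <- out$vertices[, 3] - ph$vertices[, 3]
  expect_true(all(dz <= 1e-12))
  expect_true(all(dz >= -0.15 - 1e-12)) # at most half a layer with weight 0.5
  expect_true(mesh_is_watertight(out))
})

test_that("warping lifts base corners more than the base center", {
  bx <- mesh_box(c(20, 20, 20), subdivisions = 3)
  out <- simulate_print(bx, print_spec(layer_height_mm = 1e-9,
                                       warp_amplitude_mm = 1, warp_decay_mm = 10))
  lift <- out$vertices[, 3] - bx$vertices[, 3]
  base <- bx$vertices[, 3] == 0
  corner <- base & bx$vertices[, 1] %in% c(0, 20) & bx$vertices[, 2] %in% c(0, 20)
  center <- base & abs(bx$vertices[, 1] - 10) < 3 & abs(bx$vertices[, 2] - 10) < 3
  expect_gt(min(lift[corner]), max(lift[center]))
  expect_gt(min(lift[corner]), 0.5)
  # above the warp height the surface is untouched
  high <- bx$vertices[, 3] > 5
  expect_equal(max(abs(lift[high])), 0)
})

test_that("warp amplitude monotonically widens the deviation spread", {
  ph <- small_phantom()
  six_sigma <- sapply(c(0, 0.5, 1.5), function(a) {
    printed <- simulate_print(ph, print_spec(0.3, warp_amplitude_mm = a))
    signed_surface_deviation(printed, ph, n_samples = 2e4, seed = 3)$six_sigma_dS
  })
  expect_true(all(diff(six_sigma) > 0))
  # amplitude-0 print: only layer quantization remains, below the layer height
  expect_lt(six_sigma[1], 0.3)
})

test_that("self-intersecting warp specifications are rejected", {
  expect_error(simulate_print(small_phantom(),
                              print_spec(0.3, warp_amplitude_mm = 6,
                                         warp_height_mm = 5)),
               "self-intersect")
})
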