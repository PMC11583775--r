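small_config <- function() {
  study_config(
    phantom_complexity = 1, phantom_seed = 42, in_plane_mm = 1.5,
    slice_thicknesses_mm = c(1.5, 5.0), kernels = "soft",
    thresholds_hu = c(-600, -400, 0),
    dee_slice_thicknesses_mm = c(1.5, 5.0),
    deviation_samples = 2000, n_print_replicates = 2, seed = 3
  )
}

test_that("configurations round-trip losslessly through YAML", {
  cfg <- study_config()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_study_config(cfg, path)
  cfg2 <- read_study_config(path)
  expect_equal(cfg2, cfg)
})

test_that("sweep bookkeeping: profiles x protocols x thresholds cells", {
  cfg <- small_config()
  sw <- run_sege_sweep(cfg, deviation = FALSE)
  expect_equal(nrow(sw), 3 * 2 * 3)
  expect_setequal(unique(sw$software_profile),
                  c("slicer_like", "brainlab_like", "d2p_like"))
  # volume response is monotone in threshold within a protocol
  one <- dplyr::filter(sw, software_profile == "slicer_like",
                       slice_thickness_mm == 1.5)
  expect_true(all(diff(one$volume_mm3[order(one$threshold_hu)]) <= 0))
})

test_that("the sweep is deterministic: a rerun reproduces every cell", {
  cfg <- small_config()
  s1 <- run_sege_sweep(cfg, deviation = TRUE)
  s2 <- run_sege_sweep(cfg, deviation = TRUE)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
})

test_that("DEE study emits 7 profile-level rows per thickness plus controls", {
  cfg <- small_config()
  dee <- suppressWarnings(run_dee_study(cfg, include_control = TRUE))
  expect_equal(nrow(dee), 2 * (7 + 1))
  ctrl <- dplyr::filter(dee, software_profile == "none")
  expect_true(all(ctrl$dFi_rel_pct == 0 & ctrl$dV_rel_pct == 0 &
                    ctrl$mean_dS == 0 & ctrl$six_sigma_dS == 0))
  # within slicer_like, smoothing level orders the volume reduction
  sl <- dplyr::filter(dee, software_profile == "slicer_like",
                      slice_thickness_mm == 1.5)
  sl <- sl[match(c("low", "medium", "high"), sl$level), ]
  expect_true(all(diff(abs(sl$dV_rel_pct)) > 0))
})

test_that("print study produces distinct replicate rows per printer", {
  cfg <- small_config()
  pre <- run_pre_study(cfg)
  expect_equal(nrow(pre), 2 * 2)
  expect_equal(anyDuplicated(pre[, c("mean_dS", "six_sigma_dS")]), 0L)
  warped <- dplyr::filter(pre, printer == "warped")
  accurate <- dplyr::filter(pre, printer == "accurate")
  expect_gt(min(warped$six_sigma_dS), max(accurate$six_sigma_dS))
  # accurate printer: only layer quantization remains
  expect_true(all(accurate$six_sigma_dS < 0.3))
  expect_true(all(abs(accurate$mean_dS) < 0.3))
})

test_that("total-error report propagates its partials definitionally", {
  cfg <- small_config()
  tot <- suppressWarnings(run_total_error(cfg))
  expect_equal(nrow(tot), 2)
  expect_equal(tot$six_sigma, 6 * tot$sigma_total)
  expect_equal(tot$d_mean_total, tot$sege_mean + tot$dee_mean + tot$pre_mean)
  expect_equal(tot$sigma_total,
               sqrt(tot$sege_sigma^2 + tot$dee_sigma^2 + tot$pre_sigma^2))
  totals <- attr(tot, "totals")
  expect_named(totals, c("config_1_optimal", "config_2_worst_case"))
  # JSON report round trip
  path <- withr::local_tempfile(fileext = ".json")
  write_total_error_json(tot, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$config_1_optimal$total$sigma, tot$sigma_total[1],
               tolerance = 1e-12)
})

test_that("autoplot methods return ggplot objects", {
  cfg <- small_config()
  sw <- run_sege_sweep(cfg, deviation = FALSE)
  dee <- suppressWarnings(run_dee_study(cfg))
  pre <- run_pre_study(cfg)
  expect_s3_class(autoplot(sw), "ggplot")
  expect_s3_class(autoplot(dee, metric = "dV_rel_pct"), "ggplot")
  expect_s3_class(autoplot(pre), "ggplot")
})

test_that("threshold response steepens with slice thickness in the default sweep", {
  sw <- default_sege_sweep()
  soft <- dplyr::filter(sw, software_profile == "slicer_like", kernel == "soft")
  # below the optimum the segmentation is biased large; the bias grows with
  # slice thickness (0.4 and 0.6 mm are resolution-equivalent here)
  low <- dplyr::filter(soft, threshold_hu == -600)
  low <- low[order(low$slice_thickness_mm), ]
  expect_true(all(diff(low$mean_dS[-1]) > 0))
  expect_true(all(low$mean_dS > 0))
  # at the optimum the bias is below the in-plane voxel spacing everywhere
  opt <- dplyr::filter(soft, threshold_hu == -400)
  expect_true(all(abs(opt$mean_dS) < 0.5))
})
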