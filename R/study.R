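#' Study configuration
#'
#' Bundles every parameter of the synthetic end-to-end study: the phantom,
#' the CT protocol grid (five slice thicknesses by two kernels), the
#' seven-value threshold grid, the three software-like profiles with their
#' smoothing levels, the printer specifications, replication and seeding.
#' The defaults are the study conditions; all fields are plain values so a
#' configuration round-trips losslessly through its YAML file form.
#'
#' @param phantom_complexity,phantom_seed parameters of [femur_phantom()].
#' @param in_plane_mm CT in-plane voxel spacing, mm.
#' @param slice_thicknesses_mm CT slice thickness grid, mm.
#' @param kernels reconstruction kernels to simulate.
#' @param thresholds_hu segmentation threshold grid, HU. The default grid
#'   spans -800 to 200 HU in seven steps and contains every threshold the
#'   study tables discuss (-600, -400, 0, 100).
#' @param profiles software-like profile names.
#' @param dee_slice_thicknesses_mm,dee_threshold_hu,dee_kernel the cells
#'   selected for the digital-editing study (bone kernel, -600 HU, three
#'   thicknesses).
#' @param printers named list of [print_spec()] parameter lists. Defaults: an
#'   `accurate` well-adhered printer (no warp) and a `warped` printer with
#'   1.2 mm mean lift-off.
#' @param n_print_replicates prints per printer.
#' @param deviation_samples sample budget per surface-deviation analysis.
#' @param v_min_mm3 volume cut-off for deviation analysis, mm^3.
#' @param hu_object_hu interior HU of the scanned object.
#' @param seed master seed; every stage derives its own stream from it.
#' @return A `study_config` list.
#' @export
study_config <- function(phantom_complexity = 3,
                         phantom_seed = 101,
                         in_plane_mm = 0.5,
                         slice_thicknesses_mm = c(0.4, 0.6, 1.5, 3.0, 5.0),
                         kernels = c("soft", "bone"),
                         thresholds_hu = c(-800, -600, -400, -200, 0, 100, 200),
                         profiles = c("slicer_like", "brainlab_like", "d2p_like"),
                         dee_slice_thicknesses_mm = c(0.4, 1.5, 5.0),
                         dee_threshold_hu = -600,
                         dee_kernel = "bone",
                         printers = list(
                           accurate = list(layer_height_mm = 0.3,
                                           warp_amplitude_mm = 0),
                           warped = list(layer_height_mm = 0.3,
                                         warp_amplitude_mm = 1.2,
                                         warp_decay_mm = 10,
                                         warp_height_mm = 5)
                         ),
                         n_print_replicates = 5,
                         deviation_samples = 1e5,
                         v_min_mm3 = 30000,
                         hu_object_hu = 200,
                         seed = 1) {
  stopifnot(all(slice_thicknesses_mm > 0), in_plane_mm > 0,
            all(kernels %in% c("soft", "bone")),
            all(profiles %in% c("slicer_like", "brainlab_like", "d2p_like")),
            n_print_replicates >= 1, deviation_samples >= 1)
  structure(
    list(phantom_complexity = phantom_complexity, phantom_seed = phantom_seed,
         in_plane_mm = in_plane_mm,
         slice_thicknesses_mm = slice_thicknesses_mm, kernels = kernels,
         thresholds_hu = thresholds_hu, profiles = profiles,
         dee_slice_thicknesses_mm = dee_slice_thicknesses_mm,
         dee_threshold_hu = dee_threshold_hu, dee_kernel = dee_kernel,
         printers = printers, n_print_replicates = n_print_replicates,
         deviation_samples = deviation_samples, v_min_mm3 = v_min_mm3,
         hu_object_hu = hu_object_hu, seed = seed),
    class = "study_config"
  )
}

#' @rdname study_config
#' @param config a `study_config`.
#' @param path YAML file path.
#' @export
write_study_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname study_config
#' @export
read_study_config <- function(path) {
  do.call(study_config, yaml::read_yaml(path))
}

study_phantom <- function(config) {
  femur_phantom(config$phantom_complexity, config$phantom_seed)
}

study_protocol <- function(config, thickness, kernel, index) {
  ct_protocol(thickness, kernel, in_plane_mm = config$in_plane_mm,
              seed = derive_seed(config$seed, index))
}

#' Run the segmentation-error sweep
#'
#' Simulates a CT per (kernel, slice thickness) protocol, segments it at every
#' threshold of the grid, applies the volume cut-off and - for included cells
#' - computes the signed surface deviation against the ground-truth phantom.
#' One record per (software profile, protocol, threshold): with the default
#' grid 3 x 10 x 7 = 210 records. The threshold-segmentation stage is
#' identical across the software profiles (they differ downstream, in
#' smoothing), so profile rows share cell values.
#'
#' @param config a [study_config()].
#' @param deviation compute surface-deviation statistics for included cells.
#' @param align run [icp_align()] before deviation analysis (the synthetic
#'   pipeline is already in a common frame, so the default is off).
#' @param progress print per-protocol progress to stderr.
#' @return A tibble of class `sege_sweep`; excluded cells carry `NA`
#'   deviation statistics. The ground-truth volume is attached as attribute
#'   `phantom_volume_mm3`.
#' @export
run_sege_sweep <- function(config, deviation = TRUE, align = FALSE,
                           progress = FALSE) {
  stopifnot(inherits(config, "study_config"))
  phantom <- study_phantom(config)
  gt_vol <- mesh_volume(phantom)
  grid <- expand.grid(slice_thickness_mm = config$slice_thicknesses_mm,
                      kernel = config$kernels, stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid) * length(config$thresholds_hu))
  n <- 0L
  for (p in seq_len(nrow(grid))) {
    proto <- study_protocol(config, grid$slice_thickness_mm[p], grid$kernel[p], p)
    if (progress) {
      message(sprintf("[sege] protocol %d/%d: %s %.1f mm", p, nrow(grid),
                      proto$kernel, proto$slice_thickness_mm))
    }
    vol <- simulate_ct(phantom, proto, hu_object = config$hu_object_hu)
    for (ti in seq_along(config$thresholds_hu)) {
      thr <- config$thresholds_hu[ti]
      n <- n + 1L
      rows[[n]] <- sege_cell(vol, thr, phantom, gt_vol, config,
                             cell_index = p * 100L + ti,
                             deviation = deviation, align = align)
      rows[[n]]$kernel <- proto$kernel
      rows[[n]]$slice_thickness_mm <- proto$slice_thickness_mm
    }
  }
  cells <- dplyr::bind_rows(rows)
  out <- dplyr::bind_rows(lapply(config$profiles, function(pr) {
    dplyr::mutate(cells, software_profile = pr)
  }))
  out <- dplyr::select(out, "software_profile", "kernel", "slice_thickness_mm",
                       "threshold_hu", dplyr::everything())
  class(out) <- c("sege_sweep", class(out))
  attr(out, "phantom_volume_mm3") <- gt_vol
  out
}

sege_cell <- function(vol, thr, phantom, gt_vol, config, cell_index,
                      deviation, align) {
  empty <- tibble::tibble(
    threshold_hu = thr, volume_mm3 = 0, dV_rel_pct = -100, Fi_bytes = 84,
    n_components = 0L, included = FALSE, mean_dS = NA_real_,
    sigma_dS = NA_real_, six_sigma_dS = NA_real_, status = "empty"
  )
  seg <- tryCatch(
    segment_threshold(vol, thr, island_policy = "keep_all",
                      reference_volume_mm3 = gt_vol,
                      v_min_mm3 = config$v_min_mm3),
    error = function(e) NULL
  )
  if (is.null(seg)) return(empty)
  mean_dS <- sigma_dS <- six_sigma <- NA_real_
  status <- "ok"
  if (seg$included && deviation) {
    dev <- tryCatch({
      mesh <- seg$mesh
      if (align) {
        tf <- icp_align(mesh, phantom, seed = derive_seed(config$seed, cell_index))
        mesh <- apply_transform(mesh, tf)
      }
      signed_surface_deviation(mesh, phantom,
                               n_samples = config$deviation_samples,
                               seed = derive_seed(config$seed, cell_index))
    }, error = function(e) {
      status <<- conditionMessage(e)
      NULL
    })
    if (!is.null(dev)) {
      mean_dS <- dev$mean_dS
      sigma_dS <- dev$sigma
      six_sigma <- dev$six_sigma_dS
    }
  }
  tibble::tibble(
    threshold_hu = thr, volume_mm3 = seg$metrics$volume_mm3,
    dV_rel_pct = seg$rel_volume_error_pct,
    Fi_bytes = seg$metrics$file_size_bytes, n_components = seg$n_components,
    included = seg$included, mean_dS = mean_dS, sigma_dS = sigma_dS,
    six_sigma_dS = six_sigma, status = status
  )
}

#' Run the digital-editing (smoothing) study
#'
#' Applies every profile/level combination to the designated segmentations
#' (by default the bone-kernel volumes at 0.4, 1.5 and 5.0 mm slices,
#' threshold -600 HU) and compares each print-STL to its direct segmentation:
#' relative file-size and volume change plus signed surface deviation. With
#' the default profiles (3 + 3 + 1 levels) and three thicknesses the result
#' has 21 rows.
#'
#' @param config a [study_config()].
#' @param include_control also emit an identity-smoothing control row per
#'   thickness (profile `"none"`), for which all metrics are zero.
#' @param progress print progress to stderr.
#' @return A tibble of class `dee_study`.
#' @export
run_dee_study <- function(config, include_control = FALSE, progress = FALSE) {
  stopifnot(inherits(config, "study_config"))
  phantom <- study_phantom(config)
  rows <- list()
  for (si in seq_along(config$dee_slice_thicknesses_mm)) {
    thick <- config$dee_slice_thicknesses_mm[si]
    proto <- study_protocol(config, thick, config$dee_kernel, 900L + si)
    if (progress) message(sprintf("[dee] %s %.1f mm", proto$kernel, thick))
    vol <- simulate_ct(phantom, proto, hu_object = config$hu_object_hu)
    seg0 <- segment_threshold(vol, config$dee_threshold_hu,
                              island_policy = "keep_all", v_min_mm3 = 0)
    med_cache <- list()
    smoothed_for <- function(spec) {
      if (spec$method == "volume_median") {
        key <- sprintf("%.3f", spec$median_kernel_mm)
        if (is.null(med_cache[[key]])) {
          sm <- smooth_volume_median(vol, spec$median_kernel_mm)
          seg <- segment_threshold(sm, config$dee_threshold_hu,
                                   island_policy = "keep_all", v_min_mm3 = 0)
          med_cache[[key]] <<- seg$mesh
        }
        med_cache[[key]]
      } else {
        smooth_mesh_factor(seg0$mesh, spec$factor)
      }
    }
    for (profile in config$profiles) {
      levels <- if (profile == "d2p_like") "low" else c("low", "medium", "high")
      for (level in levels) {
        spec <- smoothing_spec(profile, level)
        after <- smoothed_for(spec)
        met <- dee_metrics(seg0$mesh, after,
                           n_samples = config$deviation_samples,
                           seed = derive_seed(config$seed, 5000L + 37L * si +
                                                length(rows)))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          software_profile = profile, level = level, slice_thickness_mm = thick,
          dFi_rel_pct = met$dFi_rel_pct, dV_rel_pct = met$dV_rel_pct,
          mean_dS = met$deviation$mean_dS, sigma_dS = met$deviation$sigma,
          six_sigma_dS = met$deviation$six_sigma_dS
        )
      }
    }
    if (include_control) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        software_profile = "none", level = "none", slice_thickness_mm = thick,
        dFi_rel_pct = 0, dV_rel_pct = 0, mean_dS = 0, sigma_dS = 0,
        six_sigma_dS = 0
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("dee_study", class(out))
  out
}

#' Run the printing-error study
#'
#' Simulates replicate prints of the construction STL (the phantom mesh) for
#' each configured printer and compares every printed model to the print-STL.
#' Replicates vary the warp amplitude by a seeded draw around the printer's
#' mean (15% coefficient of variation), emulating print-bed position effects;
#' the drawn amplitudes are recorded.
#'
#' @param config a [study_config()].
#' @param progress print progress to stderr.
#' @return A tibble of class `pre_study` with one row per (printer,
#'   replicate).
#' @export
run_pre_study <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "study_config"))
  print_stl <- study_phantom(config)
  rows <- list()
  for (pi in seq_along(config$printers)) {
    name <- names(config$printers)[pi]
    base <- do.call(print_spec, config$printers[[pi]])
    if (progress) message(sprintf("[pre] printer %s", name))
    for (r in seq_len(config$n_print_replicates)) {
      amp <- base$warp_amplitude_mm
      if (amp > 0) {
        amp <- with_seed(derive_seed(config$seed, 7000L + 100L * pi + r),
                         rnorm(1, mean = amp, sd = 0.15 * amp))
        amp <- min(max(amp, 0), base$warp_height_mm)
      }
      spec <- base
      spec$warp_amplitude_mm <- amp
      printed <- simulate_print(print_stl, spec)
      dev <- signed_surface_deviation(printed, print_stl,
                                      n_samples = config$deviation_samples,
                                      seed = derive_seed(config$seed,
                                                         8000L + 100L * pi + r))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        printer = name, replicate = r, warp_amplitude_mm = amp,
        mean_dS = dev$mean_dS, sigma_dS = dev$sigma,
        six_sigma_dS = dev$six_sigma_dS
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("pre_study", class(out))
  out
}

#' Total-error report for named parameter configurations
#'
#' Builds one partial-error record per stage and propagates them (means add,
#' variances add). Two presets mirror the study's configurations: an optimal
#' setup (threshold -400 HU, 0.4 mm slices, soft kernel, low smoothing,
#' accurate printer) and a worst-case setup with only 5.0 mm slices available
#' (threshold -600 HU, high smoothing, accurate printer). The printing
#' partial uses the replicate average of the accurate printer (mean of means,
#' root-mean-square of sigmas).
#'
#' @param config a [study_config()].
#' @param sege optional precomputed [run_sege_sweep()] table; computed (for
#'   the needed cells only) when missing.
#' @param dee optional precomputed [run_dee_study()] table.
#' @param pre optional precomputed [run_pre_study()] table.
#' @param progress print progress to stderr.
#' @return A tibble of class `total_error_report`, one row per configuration,
#'   with the partial means/sigmas, the propagated total and its 6-sigma
#'   width. The underlying `total_error` objects are in attribute `totals`.
#' @export
run_total_error <- function(config, sege = NULL, dee = NULL, pre = NULL,
                            progress = FALSE) {
  stopifnot(inherits(config, "study_config"))
  presets <- tibble::tibble(
    configuration = c("config_1_optimal", "config_2_worst_case"),
    kernel = "soft",
    slice_thickness_mm = c(0.4, 5.0),
    threshold_hu = c(-400, -600),
    smoothing_level = c("low", "high"),
    printer = "accurate"
  )
  if (is.null(sege)) {
    narrowed <- config
    narrowed$kernels <- "soft"
    narrowed$slice_thicknesses_mm <- unique(presets$slice_thickness_mm)
    narrowed$thresholds_hu <- unique(presets$threshold_hu)
    sege <- run_sege_sweep(narrowed, progress = progress)
  }
  if (is.null(dee)) {
    narrowed <- config
    narrowed$dee_slice_thicknesses_mm <- unique(presets$slice_thickness_mm)
    narrowed$profiles <- "slicer_like"
    dee <- run_dee_study(narrowed, progress = progress)
  }
  if (is.null(pre)) pre <- run_pre_study(config, progress = progress)

  pre_acc <- dplyr::filter(pre, .data$printer == "accurate")
  if (nrow(pre_acc) == 0) stop("no 'accurate' printer rows in `pre`", call. = FALSE)
  pre_part <- partial_error("PrE", mean(pre_acc$mean_dS),
                            sqrt(mean(pre_acc$sigma_dS^2)))

  totals <- list()
  rows <- list()
  for (i in seq_len(nrow(presets))) {
    ps <- presets[i, ]
    sg <- dplyr::filter(sege, .data$kernel == ps$kernel,
                        .data$slice_thickness_mm == ps$slice_thickness_mm,
                        .data$threshold_hu == ps$threshold_hu)
    sg <- sg[1, ]
    if (nrow(sg) == 0 || is.na(sg$mean_dS)) {
      stop(sprintf("segmentation cell for %s is missing or excluded",
                   ps$configuration), call. = FALSE)
    }
    de <- dplyr::filter(dee, .data$software_profile == "slicer_like",
                        .data$level == ps$smoothing_level,
                        .data$slice_thickness_mm == ps$slice_thickness_mm)
    de <- de[1, ]
    if (nrow(de) == 0 || is.na(de$mean_dS)) {
      stop(sprintf("smoothing cell for %s is missing", ps$configuration),
           call. = FALSE)
    }
    tot <- propagate_total(
      partial_error("SegE", sg$mean_dS, sg$sigma_dS),
      partial_error("DEE", de$mean_dS, de$sigma_dS),
      pre_part
    )
    totals[[ps$configuration]] <- tot
    rows[[i]] <- tibble::tibble(
      configuration = ps$configuration,
      sege_mean = sg$mean_dS, sege_sigma = sg$sigma_dS,
      dee_mean = de$mean_dS, dee_sigma = de$sigma_dS,
      pre_mean = pre_part$d_mean, pre_sigma = pre_part$sigma,
      d_mean_total = tot$d_mean_total, sigma_total = tot$sigma_total,
      six_sigma = tot$six_sigma
    )
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("total_error_report", class(out))
  attr(out, "totals") <- totals
  out
}

#' Export a total-error report as JSON
#'
#' One entry per configuration with the three partials, the propagated total
#' and its 6-sigma width, written at full precision.
#'
#' @param report a [run_total_error()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_total_error_json <- function(report, path) {
  stopifnot(inherits(report, "total_error_report"))
  obj <- lapply(seq_len(nrow(report)), function(i) {
    r <- report[i, ]
    list(
      partials = list(
        SegE = list(d_mean = r$sege_mean, sigma = r$sege_sigma),
        DEE = list(d_mean = r$dee_mean, sigma = r$dee_sigma),
        PrE = list(d_mean = r$pre_mean, sigma = r$pre_sigma)
      ),
      total = list(d_mean = r$d_mean_total, sigma = r$sigma_total,
                   six_sigma = r$six_sigma)
    )
  })
  names(obj) <- report$configuration
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
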