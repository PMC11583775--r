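#' Smoothing profile specification
#'
#' Three software-like smoothing profiles with the study's three-level
#' parameter mappings. `slicer_like` is a median filter on the label/HU
#' volume with kernel sizes 1/3/5 mm for low/medium/high; `brainlab_like` is
#' mesh-based Taubin smoothing with factors 0.66/1.33/2.00; `d2p_like` offers
#' a single low level, a 1 mm median pass. The commercial algorithms are
#' unpublished, so only the orderings and qualitative behaviour of these
#' profiles are meaningful, not absolute agreement between profiles.
#'
#' @param profile `"slicer_like"`, `"brainlab_like"` or `"d2p_like"`.
#' @param level `"low"`, `"medium"` or `"high"`; `d2p_like` supports only
#'   `"low"`.
#' @return A `smoothing_spec` with the resolved parameter
#'   (`median_kernel_mm` or `factor`) and `method`.
#' @export
smoothing_spec <- function(profile = c("slicer_like", "brainlab_like", "d2p_like"),
                           level = c("low", "medium", "high")) {
  profile <- match.arg(profile)
  level <- match.arg(level)
  if (profile == "d2p_like" && level != "low") {
    stop("d2p_like supports only level = \"low\"", call. = FALSE)
  }
  spec <- switch(profile,
    slicer_like = list(method = "volume_median",
                       median_kernel_mm = c(low = 1, medium = 3, high = 5)[[level]]),
    brainlab_like = list(method = "mesh_taubin",
                         factor = c(low = 0.66, medium = 1.33, high = 2.00)[[level]]),
    d2p_like = list(method = "volume_median", median_kernel_mm = 1)
  )
  structure(c(list(profile = profile, level = level), spec),
            class = "smoothing_spec")
}

#' @export
print.smoothing_spec <- function(x, ...) {
  par <- if (x$method == "volume_median") {
    sprintf("median kernel %.1f mm", x$median_kernel_mm)
  } else {
    sprintf("Taubin factor %.2f", x$factor)
  }
  cat(sprintf("<smoothing_spec> %s, level %s (%s)\n", x$profile, x$level, par))
  invisible(x)
}

#' Median smoothing of a volume or mask
#'
#' The kernel size in millimetres is converted per axis to an odd voxel
#' window, rounding up (at least one voxel). For binary masks the median is a
#' majority vote. If the kernel is smaller than one voxel along every axis
#' the input is returned unchanged with a warning.
#'
#' @param volume an [hu_volume()], or a 3D array (e.g. a 0/1 mask) carrying
#'   `spacing`/`origin` attributes.
#' @param kernel_mm kernel edge length, mm (> 0).
#' @return The same kind of object, median filtered.
#' @export
smooth_volume_median <- function(volume, kernel_mm) {
  stopifnot_scalar_num(kernel_mm, "kernel_mm", positive = TRUE)
  if (inherits(volume, "hu_volume")) {
    spacing <- volume$spacing
    vox <- volume$voxels
  } else {
    spacing <- attr(volume, "spacing")
    if (is.null(spacing)) stop("array volume needs a `spacing` attribute", call. = FALSE)
    vox <- volume
  }
  # window per axis in (z, y, x) dimension order
  w_axis <- function(s) {
    w <- ceiling(kernel_mm / s)
    w <- max(1L, as.integer(w))
    if (w %% 2L == 0L) w + 1L else w
  }
  w <- c(w_axis(spacing[3]), w_axis(spacing[2]), w_axis(spacing[1]))
  if (all(w == 1L)) {
    warning("median kernel smaller than one voxel along every axis; returning input unchanged")
    return(volume)
  }
  sm <- cpp_median_filter3(vox, dim(vox), w)
  if (inherits(volume, "hu_volume")) {
    out <- hu_volume(array(sm, dim(vox)), spacing, volume$origin)
    attr(out, "protocol") <- attr(volume, "protocol")
    out
  } else {
    out <- array(sm, dim(vox))
    attributes(out) <- attributes(volume)
    out
  }
}

#' Taubin mesh smoothing with a scalar factor
#'
#' Two-step (lambda/mu) Laplacian smoothing; the factor maps to
#' `round(10 * factor)` lambda-mu iteration pairs. The mu step inflates back
#' most of the plain-Laplacian shrinkage but the net effect on curved regions
#' is a mild, monotone shrink, concentrated at edges and corners - flat areas
#' are nearly unaffected. Triangle count and watertightness are preserved.
#'
#' @param mesh a [tri_mesh()].
#' @param factor smoothing factor (> 0 for any effect; `round(10 * factor)`
#'   iterations, so factors below 0.05 are the identity).
#' @param lambda,mu Taubin step weights.
#' @return The smoothed [tri_mesh()].
#' @export
smooth_mesh_factor <- function(mesh, factor, lambda = 0.5, mu = -0.45) {
  assert_mesh(mesh)
  stopifnot_scalar_num(factor, "factor", nonneg = TRUE)
  iters <- round(10 * factor)
  if (iters == 0) return(mesh)
  v <- cpp_taubin_smooth(mesh$vertices, mesh$faces - 1L, as.integer(iters),
                         lambda, mu)
  tri_mesh(v, mesh$faces)
}

#' Apply a smoothing profile to a segmentation
#'
#' Volume-method profiles (`slicer_like`, `d2p_like`) median-filter the HU
#' volume and re-extract the iso-surface at the original threshold;
#' the mesh-method profile (`brainlab_like`) smooths the segmentation mesh
#' directly.
#'
#' @param spec a [smoothing_spec()].
#' @param segmentation a `segmentation_result` (see [segment_threshold()]).
#' @param volume the [hu_volume()] the segmentation came from; required for
#'   volume-method profiles.
#' @return The smoothed print-STL candidate as a [tri_mesh()].
#' @export
apply_smoothing <- function(spec, segmentation, volume = NULL) {
  if (!inherits(spec, "smoothing_spec")) stop("`spec` must be a smoothing_spec", call. = FALSE)
  if (!inherits(segmentation, "segmentation_result")) {
    stop("`segmentation` must be a segmentation_result", call. = FALSE)
  }
  if (spec$method == "volume_median") {
    if (is.null(volume)) {
      stop("volume-method smoothing needs the source `volume`", call. = FALSE)
    }
    sm <- smooth_volume_median(volume, spec$median_kernel_mm)
    seg <- segment_threshold(sm, segmentation$threshold_hu,
                             island_policy = segmentation$island_policy,
                             v_min_mm3 = 0)
    seg$mesh
  } else {
    smooth_mesh_factor(segmentation$mesh, spec$factor)
  }
}

#' Digital-editing error metrics
#'
#' Compares a print-STL (after smoothing) to the direct segmentation result:
#' relative change of the binary-STL file-size proxy and of enclosed volume
#' (pre-smoothing values as denominator; negative means reduction), plus the
#' signed surface deviation of the smoothed mesh against the direct
#' segmentation.
#'
#' @param before direct segmentation mesh ([tri_mesh()], watertight).
#' @param after print-STL mesh ([tri_mesh()], watertight).
#' @param n_samples deviation sample budget.
#' @param seed sampling seed.
#' @return A `dee_metrics` list: `dFi_rel_pct`, `dV_rel_pct`, `deviation`
#'   (a `deviation_stats`).
#' @export
dee_metrics <- function(before, after, n_samples = 1e5, seed = 1) {
  assert_mesh(before, "before")
  assert_mesh(after, "after")
  fi_before <- file_size_proxy(before)
  v_before <- mesh_volume(before)
  v_after <- mesh_volume(after)
  structure(
    list(
      dFi_rel_pct = 100 * (file_size_proxy(after) - fi_before) / fi_before,
      dV_rel_pct = 100 * (v_after - v_before) / v_before,
      deviation = signed_surface_deviation(after, before,
                                           n_samples = n_samples, seed = seed)
    ),
    class = "dee_metrics"
  )
}

#' @export
print.dee_metrics <- function(x, ...) {
  cat(sprintf(
    "<dee_metrics> dFi_rel %.2f%%, dV_rel %.2f%%, mean dS %.4f mm, 6-sigma %.4f mm\n",
    x$dFi_rel_pct, x$dV_rel_pct, x$deviation$mean_dS, x$deviation$six_sigma_dS))
  invisible(x)
}
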