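#' Extract an iso-surface from an HU volume
#'
#' Sub-voxel iso-surface of the scalar field at a chosen iso level, with
#' physical spacing applied so the mesh lives in millimetres. The volume is
#' padded with one layer of air (-1024 HU) so surfaces touching the grid
#' boundary close. A voxel is inside when its value is at or above the level.
#'
#' @param volume an [hu_volume()] or a 3D array with `spacing`/`origin`
#'   attributes.
#' @param iso iso level (HU for HU volumes).
#' @return A [tri_mesh()].
#' @export
extract_isosurface <- function(volume, iso) {
  if (inherits(volume, "hu_volume")) {
    vox <- volume$voxels
    spacing <- volume$spacing
    origin <- volume$origin
  } else {
    vox <- volume
    spacing <- attr(volume, "spacing")
    origin <- attr(volume, "origin")
    if (is.null(spacing)) stop("array volume needs a `spacing` attribute", call. = FALSE)
    if (is.null(origin)) origin <- c(0, 0, 0)
  }
  extract_isosurface_raw(vox, iso, spacing, origin, pad_value = -1024)
}

#' Threshold segmentation of an HU volume
#'
#' Labels voxels with HU at or above the threshold as object and extracts the
#' surface with sub-voxel interpolation on the continuous HU field (the
#' behaviour of the interactive tools this emulates). A binary-mask surface is
#' available via `surface = "binary"` for staircase studies. Island handling:
#' `keep_all` retains every closed component, reproducing island formation in
#' noisy data; `largest_component` keeps only the largest-volume solid.
#'
#' @param volume an [hu_volume()].
#' @param threshold_hu segmentation threshold, HU; must lie within the
#'   volume's dynamic range.
#' @param island_policy `"keep_all"` or `"largest_component"`.
#' @param reference_volume_mm3 optional ground-truth volume; fills
#'   `rel_volume_error_pct`.
#' @param v_min_mm3 volume cut-off below which the result is flagged as
#'   excluded from surface-deviation analysis.
#' @param surface `"subvoxel"` (default) or `"binary"`.
#' @return A `segmentation_result`: list with `mesh`, `threshold_hu`,
#'   `island_policy`, `n_components`, `metrics` (one-row tibble),
#'   `rel_volume_error_pct` and `included`.
#' @export
segment_threshold <- function(volume, threshold_hu,
                              island_policy = c("keep_all", "largest_component"),
                              reference_volume_mm3 = NULL, v_min_mm3 = 30000,
                              surface = c("subvoxel", "binary")) {
  if (!inherits(volume, "hu_volume")) stop("`volume` must be a hu_volume", call. = FALSE)
  island_policy <- match.arg(island_policy)
  surface <- match.arg(surface)
  stopifnot_scalar_num(threshold_hu, "threshold_hu")
  rng <- range(volume$voxels)
  if (threshold_hu > rng[2]) {
    stop(sprintf(
      "empty segmentation: no voxel at or above %.1f HU (volume maximum %.1f HU)",
      threshold_hu, rng[2]), call. = FALSE)
  }
  mesh <- if (surface == "subvoxel") {
    extract_isosurface(volume, threshold_hu)
  } else {
    mask <- volume$voxels
    mask[] <- as.double(volume$voxels >= threshold_hu)
    attr(mask, "spacing") <- volume$spacing
    attr(mask, "origin") <- volume$origin
    extract_isosurface_raw(mask, 0.5, volume$spacing, volume$origin, pad_value = 0)
  }
  if (nrow(mesh$faces) == 0L) {
    stop("empty segmentation: iso-surface has no triangles", call. = FALSE)
  }
  labels <- cpp_face_components(mesh$faces - 1L, nrow(mesh$vertices))
  n_components <- max(labels)
  if (island_policy == "largest_component" && n_components > 1L) {
    fv <- cpp_face_signed_volumes(mesh$vertices, mesh$faces - 1L)
    comp_vol <- rowsum(fv, labels)
    keep <- as.integer(rownames(comp_vol))[which.max(comp_vol)]
    mesh <- subset_faces(mesh, labels == keep)
  }
  vol_mm3 <- mesh_volume(mesh)
  metrics <- tibble::tibble(
    volume_mm3 = vol_mm3,
    n_triangles = nrow(mesh$faces),
    file_size_bytes = file_size_proxy(mesh)
  )
  rel <- if (!is.null(reference_volume_mm3)) {
    relative_volume_error(vol_mm3, reference_volume_mm3)
  } else {
    NA_real_
  }
  structure(
    list(mesh = mesh, threshold_hu = threshold_hu, island_policy = island_policy,
         n_components = n_components, metrics = metrics,
         rel_volume_error_pct = rel,
         included = passes_cutoff(vol_mm3, v_min_mm3)),
    class = "segmentation_result"
  )
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "<segmentation_result> threshold %.0f HU, %s: %d component(s), %.0f mm^3, %d triangles, %s\n",
    x$threshold_hu, x$island_policy, x$n_components, x$metrics$volume_mm3,
    x$metrics$n_triangles,
    if (x$included) "included" else "excluded (below volume cut-off)"))
  invisible(x)
}

# iso-surface of a raw array (already padded value supplied)
extract_isosurface_raw <- function(arr, iso, spacing, origin, pad_value) {
  d <- dim(arr)
  pad <- array(pad_value, d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- arr
  porigin <- origin - spacing
  res <- cpp_marching_tets(pad, dim(pad), spacing, porigin, iso)
  tri_mesh(res$vertices, res$faces + 1L)
}

subset_faces <- function(mesh, keep) {
  f <- mesh$faces[keep, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  map <- integer(nrow(mesh$vertices))
  map[used] <- seq_along(used)
  tri_mesh(mesh$vertices[used, , drop = FALSE], matrix(map[f], ncol = 3L))
}

#' Relative volume error
#'
#' `100 * (v_seg - v_ref) / v_ref`, in percent. Negative values indicate that
#' the segmentation result is smaller than the reference.
#'
#' @param v_seg segmented volume, mm^3.
#' @param v_ref reference volume, mm^3 (> 0).
#' @return Relative volume error in percent.
#' @examples
#' relative_volume_error(30000, 51955)  # -42.26 %
#' @export
relative_volume_error <- function(v_seg, v_ref) {
  if (!all(is.finite(v_ref)) || any(v_ref <= 0)) {
    stop("`v_ref` must be > 0", call. = FALSE)
  }
  100 * (v_seg - v_ref) / v_ref
}

#' Volume cut-off for surface-deviation analysis
#'
#' Below the cut-off the surfaces differ too much for reliable alignment and
#' the cell is excluded from deviation analysis (a gap in the study tables).
#' Equality passes: only results *less than* the cut-off are excluded.
#'
#' @param v_seg segmented volume, mm^3 (>= 0).
#' @param v_min_mm3 cut-off volume, mm^3.
#' @return `TRUE` when `v_seg >= v_min_mm3`.
#' @export
passes_cutoff <- function(v_seg, v_min_mm3 = 30000) {
  if (any(v_seg < 0)) stop("`v_seg` must be >= 0", call. = FALSE)
  v_seg >= v_min_mm3
}
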