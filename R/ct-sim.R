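#' CT acquisition protocol
#'
#' Describes a simulated CT acquisition: slice thickness, in-plane spacing and
#' the stylized reconstruction-kernel character. The soft-tissue kernel blurs
#' more (wider point-spread function) but is quiet; the bone kernel is sharper
#' (narrower PSF plus an unsharp-mask edge boost) but noisier. Defaults
#' reproduce that ordering, not any specific scanner.
#'
#' @param slice_thickness_mm slice thickness (z spacing), mm. The study grid
#'   uses 0.4, 0.6, 1.5, 3.0 and 5.0 mm.
#' @param kernel `"soft"` or `"bone"`.
#' @param in_plane_mm in-plane (x, y) voxel spacing, mm.
#' @param psf_fwhm_mm full width at half maximum of the Gaussian PSF, mm.
#'   Defaults: soft 1.2, bone 0.6.
#' @param noise_sd_hu additive Gaussian noise, HU. Defaults: soft 15, bone 60.
#' @param edge_boost unsharp-mask weight for the bone kernel.
#' @param slice_profile_fwhm_factor width of the Gaussian component of the
#'   slice sensitivity profile as a fraction of the slice thickness. Real
#'   slice profiles are not perfect boxes (helical interpolation, focal
#'   spot); the default 1.0 gives a profile of roughly one nominal slice
#'   width. Set to 0 for an ideal box profile.
#' @param seed seed for the noise realization.
#' @return An object of class `ct_protocol`.
#' @export
ct_protocol <- function(slice_thickness_mm, kernel = c("soft", "bone"),
                        in_plane_mm = 0.5, psf_fwhm_mm = NULL,
                        noise_sd_hu = NULL, edge_boost = 0.5,
                        slice_profile_fwhm_factor = 1.0, seed = 1) {
  kernel <- match.arg(kernel)
  stopifnot_scalar_num(slice_thickness_mm, "slice_thickness_mm", positive = TRUE)
  stopifnot_scalar_num(in_plane_mm, "in_plane_mm", positive = TRUE)
  if (is.null(psf_fwhm_mm)) psf_fwhm_mm <- if (kernel == "soft") 1.2 else 0.6
  if (is.null(noise_sd_hu)) noise_sd_hu <- if (kernel == "soft") 15 else 60
  stopifnot_scalar_num(psf_fwhm_mm, "psf_fwhm_mm", nonneg = TRUE)
  stopifnot_scalar_num(noise_sd_hu, "noise_sd_hu", nonneg = TRUE)
  stopifnot_scalar_num(edge_boost, "edge_boost", nonneg = TRUE)
  stopifnot_scalar_num(slice_profile_fwhm_factor, "slice_profile_fwhm_factor",
                       nonneg = TRUE)
  structure(
    list(slice_thickness_mm = slice_thickness_mm, kernel = kernel,
         in_plane_mm = in_plane_mm, psf_fwhm_mm = psf_fwhm_mm,
         noise_sd_hu = noise_sd_hu, edge_boost = edge_boost,
         slice_profile_fwhm_factor = slice_profile_fwhm_factor,
         seed = as.integer(seed)),
    class = "ct_protocol"
  )
}

#' @export
print.ct_protocol <- function(x, ...) {
  cat(sprintf(
    "<ct_protocol> %s kernel, slices %.1f mm, in-plane %.2f mm, PSF %.2f mm, noise %.0f HU, seed %d\n",
    x$kernel, x$slice_thickness_mm, x$in_plane_mm, x$psf_fwhm_mm,
    x$noise_sd_hu, x$seed))
  invisible(x)
}

#' Hounsfield-unit volume
#'
#' A 3D scalar grid of Hounsfield units with anisotropic voxel spacing. The
#' array is indexed `(slice, row, col)`; the world coordinate of voxel center
#' `(i, j, k)` (1-based) is `origin + ((k-1) dx, (j-1) dy, (i-1) dz)`, with the
#' z axis along slices. Values are clamped to the scanner range
#' `[-1024, 3071]` HU.
#'
#' @param voxels 3D numeric array, dimensions `(n_slices, n_rows, n_cols)`.
#' @param spacing voxel spacing `(dx, dy, dz)` in mm.
#' @param origin world coordinate (mm) of the center of voxel `(1, 1, 1)`.
#' @return An object of class `hu_volume`.
#' @export
hu_volume <- function(voxels, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L,
            length(spacing) == 3L, all(spacing > 0), length(origin) == 3L)
  voxels[] <- pmin(pmax(voxels, -1024), 3071)
  structure(list(voxels = voxels, spacing = as.double(spacing),
                 origin = as.double(origin)),
            class = "hu_volume")
}

#' @export
print.hu_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<hu_volume> %d x %d x %d voxels (slice, row, col), spacing %.2f x %.2f x %.2f mm, HU range [%.0f, %.0f]\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
    min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Voxel occupancy fractions of a mesh
#'
#' For every voxel, the fraction of its volume inside the solid, computed with
#' `subsamples^2` vertical sub-rays per voxel column and exact integration of
#' the inside intervals across each voxel's z extent (through-slice
#' averaging). This is the partial-volume model feeding [simulate_ct()].
#'
#' @param mesh watertight [tri_mesh()].
#' @param spacing voxel spacing `(dx, dy, dz)` mm.
#' @param origin center of voxel `(1,1,1)`; defaults to the mesh bounding box
#'   minus `margin_mm`.
#' @param dim grid dimensions `(n_slices, n_rows, n_cols)`; default sized to
#'   contain the mesh plus `margin_mm`.
#' @param margin_mm margin added around the mesh for the default grid.
#' @param subsamples in-plane sub-rays per voxel edge (>= 4 recommended).
#' @return A 3D array of occupancy fractions with attributes `spacing` and
#'   `origin`.
#' @export
mesh_occupancy <- function(mesh, spacing, origin = NULL, dim = NULL,
                           margin_mm = 2, subsamples = 4) {
  assert_mesh(mesh)
  if (count_open_edges(mesh) > 0L) stop("mesh must be watertight", call. = FALSE)
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  bb_lo <- apply(mesh$vertices, 2, min)
  bb_hi <- apply(mesh$vertices, 2, max)
  if (is.null(origin) != is.null(dim)) {
    stop("supply both `origin` and `dim`, or neither", call. = FALSE)
  }
  if (is.null(origin)) {
    origin <- bb_lo - margin_mm
    n <- ceiling((bb_hi - bb_lo + 2 * margin_mm) / spacing) + 1L
    dim <- as.integer(c(n[3], n[2], n[1]))
  } else {
    hi <- origin + (rev(dim) - 1L) * spacing
    if (any(bb_lo < origin) || any(bb_hi > hi)) {
      stop("grid too small: it does not contain the mesh", call. = FALSE)
    }
  }
  res <- cpp_voxelize(mesh$vertices, mesh$faces - 1L, as.integer(dim),
                      as.double(spacing), as.double(origin),
                      as.integer(subsamples))
  if (res$odd_rays > 0L) {
    warning(sprintf("%d sub-rays had odd crossing parity and were skipped",
                    res$odd_rays))
  }
  occ <- res$occupancy
  attr(occ, "spacing") <- as.double(spacing)
  attr(occ, "origin") <- as.double(origin)
  occ
}

#' Simulate a CT acquisition of a mesh
#'
#' Maps per-voxel occupancy `f` to noiseless Hounsfield units
#' `HU = -1000 + f * (hu_object + 1000)`, so air is -1000 HU, the object
#' interior is `hu_object`, and the half-occupancy surface sits at the HU
#' midpoint (-400 HU for the default `hu_object = 200`). The soft kernel then
#' applies an in-plane Gaussian blur of FWHM `psf_fwhm_mm` (the
#' reconstruction kernel acts within each slice; through-slice resolution is
#' the slice profile, modelled by the exact z averaging of the occupancy) and
#' adds noise; the bone kernel applies its (narrower) blur, an unsharp-mask
#' edge boost, and higher noise. The grid must contain the mesh plus a margin of three PSF widths; by
#' default it is sized automatically.
#'
#' @param mesh watertight [tri_mesh()].
#' @param protocol a [ct_protocol()].
#' @param hu_object interior HU of the scanned object (printed PLA in air).
#' @param origin,dim optional explicit grid (see [mesh_occupancy()]); an
#'   explicit grid that cannot hold the mesh plus margin is an error.
#' @param subsamples in-plane sub-rays per voxel edge for occupancy.
#' @return An [hu_volume()] with the protocol stored as attribute `protocol`.
#' @export
simulate_ct <- function(mesh, protocol, hu_object = 200, origin = NULL,
                        dim = NULL, subsamples = 4) {
  assert_mesh(mesh)
  if (!inherits(protocol, "ct_protocol")) {
    stop("`protocol` must be a ct_protocol", call. = FALSE)
  }
  spacing <- c(protocol$in_plane_mm, protocol$in_plane_mm,
               protocol$slice_thickness_mm)
  margin <- 3 * protocol$psf_fwhm_mm + 2 * max(spacing)
  if (!is.null(origin) || !is.null(dim)) {
    bb_lo <- apply(mesh$vertices, 2, min)
    bb_hi <- apply(mesh$vertices, 2, max)
    hi <- origin + (rev(dim) - 1L) * spacing
    if (any(bb_lo - margin < origin) || any(bb_hi + margin > hi)) {
      stop("grid too small: mesh plus 3 PSF margin does not fit", call. = FALSE)
    }
    occ <- mesh_occupancy(mesh, spacing, origin, dim, subsamples = subsamples)
  } else {
    occ <- mesh_occupancy(mesh, spacing, margin_mm = margin,
                          subsamples = subsamples)
  }
  origin <- attr(occ, "origin")
  dims <- base::dim(occ)
  hu <- -1000 + occ * (hu_object + 1000)
  # the reconstruction kernel acts in-plane; through-slice resolution is set
  # by the slice profile, which the exact z integration of the occupancy
  # already models
  sigma_mm <- protocol$psf_fwhm_mm / (2 * sqrt(2 * log(2)))
  # Gaussian slice-profile component: sigma in voxels is constant, so its
  # width in mm scales with the slice thickness
  sigma_z_vox <- protocol$slice_profile_fwhm_factor / (2 * sqrt(2 * log(2)))
  sigma_vox <- c(sigma_z_vox, sigma_mm / spacing[2], sigma_mm / spacing[1])
  if (any(sigma_vox > 0)) {
    hu <- cpp_gauss_blur3(hu, dims, sigma_vox)
  }
  if (protocol$kernel == "bone" && protocol$edge_boost > 0) {
    wide <- cpp_gauss_blur3(hu, dims, 2 * c(0, sigma_vox[2], sigma_vox[3]))
    hu <- hu + protocol$edge_boost * (hu - wide)
  }
  if (protocol$noise_sd_hu > 0) {
    noise <- with_seed(protocol$seed, rnorm(length(hu)))
    if (sigma_z_vox > 0) {
      # overlapping slice profiles correlate noise across slices; rescale so
      # noise_sd_hu stays the observed image noise
      noise <- cpp_gauss_blur3(noise, dims, c(sigma_z_vox, 0, 0))
      noise <- noise / sd(noise)
    }
    hu <- hu + protocol$noise_sd_hu * noise
  }
  base::dim(hu) <- dims
  vol <- hu_volume(hu, spacing, origin)
  attr(vol, "protocol") <- protocol
  vol
}

#' Export an HU volume as NIfTI
#'
#' Writes the volume with its voxel spacing in the NIfTI header. Needs the
#' suggested RNifti package.
#'
#' @param volume an [hu_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(volume, path) {
  if (!inherits(volume, "hu_volume")) stop("`volume` must be a hu_volume", call. = FALSE)
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("write_volume_nifti() needs the RNifti package", call. = FALSE)
  }
  # NIfTI expects (x, y, z) ordering; our array is (z, y, x)
  arr <- aperm(volume$voxels, c(3, 2, 1))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
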