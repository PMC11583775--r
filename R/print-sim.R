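#' FFF print specification
#'
#' Parameters of the simulated fused-filament print: the discrete layer
#' height driving the staircase artefact, and a bed-adhesion warping model in
#' which the base of the part lifts vertically near the outline of its
#' footprint (strongest at corners and edges), decaying with horizontal
#' distance into the part and with height above the build plate.
#'
#' @param layer_height_mm print layer height (> 0).
#' @param warp_amplitude_mm peak vertical lift-off at the footprint boundary;
#'   0 for an accurate, well-adhered print, around 1.0-1.5 for a printer with
#'   poor bed adhesion.
#' @param warp_decay_mm lateral decay length of the lift-off.
#' @param warp_height_mm vertical extent of the affected zone.
#' @param seed seed used when replicate amplitudes are drawn in the study
#'   runner.
#' @return A `print_spec`.
#' @export
print_spec <- function(layer_height_mm = 0.3, warp_amplitude_mm = 0,
                       warp_decay_mm = 10, warp_height_mm = 5, seed = 1) {
  stopifnot_scalar_num(layer_height_mm, "layer_height_mm", positive = TRUE)
  stopifnot_scalar_num(warp_amplitude_mm, "warp_amplitude_mm", nonneg = TRUE)
  stopifnot_scalar_num(warp_decay_mm, "warp_decay_mm", positive = TRUE)
  stopifnot_scalar_num(warp_height_mm, "warp_height_mm", positive = TRUE)
  structure(
    list(layer_height_mm = layer_height_mm,
         warp_amplitude_mm = warp_amplitude_mm,
         warp_decay_mm = warp_decay_mm, warp_height_mm = warp_height_mm,
         seed = as.integer(seed)),
    class = "print_spec"
  )
}

#' @export
print.print_spec <- function(x, ...) {
  cat(sprintf(
    "<print_spec> layer %.2f mm, warp %.2f mm (decay %.1f mm, height %.1f mm)\n",
    x$layer_height_mm, x$warp_amplitude_mm, x$warp_decay_mm, x$warp_height_mm))
  invisible(x)
}

#' Simulate printing a mesh
#'
#' Returns a deformed copy of the print-STL. Two effects are modelled on the
#' surface:
#'
#' * staircase: each point's height above the base plane is displaced toward
#'   the floor of its print layer with a sub-layer blending weight of 0.5
#'   (a monotone map in z, so no self-intersection is introduced);
#' * warping: vertical lift-off
#'   `w = A * exp(-d_interior / decay) * max(0, 1 - (z - z_min) / height)`,
#'   where `d_interior` is the horizontal distance from the footprint
#'   boundary inward, so corners and edges of the base lift most.
#'
#' The deformation keeps the connectivity, hence watertightness. Amplitudes
#' larger than the warp height would fold the surface and are an error.
#'
#' @param mesh watertight [tri_mesh()] resting on its base plane
#'   `z = min(z)`.
#' @param spec a [print_spec()].
#' @param footprint_res_mm grid resolution for the footprint distance field.
#' @return The printed-model [tri_mesh()].
#' @export
simulate_print <- function(mesh, spec, footprint_res_mm = 1) {
  assert_mesh(mesh)
  if (!inherits(spec, "print_spec")) stop("`spec` must be a print_spec", call. = FALSE)
  if (spec$warp_amplitude_mm > spec$warp_height_mm) {
    stop("warp amplitude exceeds warp height: deformation would self-intersect",
         call. = FALSE)
  }
  v <- mesh$vertices
  z_min <- min(v[, 3])
  h <- spec$layer_height_mm
  z_rel <- v[, 3] - z_min
  # staircase: blend halfway toward the layer floor
  z_new <- z_min + z_rel - 0.5 * (z_rel %% h)
  if (spec$warp_amplitude_mm > 0) {
    d_int <- footprint_interior_distance(mesh, z_min, spec$warp_height_mm,
                                         footprint_res_mm)
    d <- d_int$lookup(v[, 1], v[, 2])
    lift <- spec$warp_amplitude_mm * exp(-d / spec$warp_decay_mm) *
      pmax(0, 1 - (v[, 3] - z_min) / spec$warp_height_mm)
    z_new <- z_new + lift
  }
  tri_mesh(cbind(v[, 1], v[, 2], z_new), mesh$faces)
}

# Distance field (mm) from the base-footprint boundary inward, sampled on a
# 2D grid; returns a bilinear lookup function.
footprint_interior_distance <- function(mesh, z_min, slab_mm, res_mm) {
  slab <- max(slab_mm, 1)
  bb_lo <- apply(mesh$vertices, 2, min)
  bb_hi <- apply(mesh$vertices, 2, max)
  margin <- 2 * res_mm
  origin <- c(bb_lo[1] - margin, bb_lo[2] - margin, z_min + slab / 2)
  nx <- ceiling((bb_hi[1] - bb_lo[1] + 2 * margin) / res_mm) + 1L
  ny <- ceiling((bb_hi[2] - bb_lo[2] + 2 * margin) / res_mm) + 1L
  # single z slab [z_min, z_min + slab]: occupancy of the base zone per column
  occ <- cpp_voxelize(mesh$vertices, mesh$faces - 1L,
                      c(1L, as.integer(ny), as.integer(nx)),
                      c(res_mm, res_mm, slab), origin, 4L)$occupancy
  base_layer <- array(occ, c(ny, nx))
  mask <- base_layer >= 0.25 # (row = y, col = x)
  d_pix <- cpp_edt2d(mask)
  dist_mm <- d_pix * res_mm
  ys <- origin[2] + (seq_len(nrow(mask)) - 1L) * res_mm
  xs <- origin[1] + (seq_len(ncol(mask)) - 1L) * res_mm
  lookup <- function(x, y) {
    fx <- (x - xs[1]) / res_mm
    fy <- (y - ys[1]) / res_mm
    i0 <- pmin(pmax(floor(fy), 0), length(ys) - 2L)
    j0 <- pmin(pmax(floor(fx), 0), length(xs) - 2L)
    ty <- pmin(pmax(fy - i0, 0), 1)
    tx <- pmin(pmax(fx - j0, 0), 1)
    n <- nrow(dist_mm)
    idx <- function(i, j) dist_mm[cbind(i + 1L, j + 1L)]
    (1 - ty) * ((1 - tx) * idx(i0, j0) + tx * idx(i0, j0 + 1L)) +
      ty * ((1 - tx) * idx(i0 + 1L, j0) + tx * idx(i0 + 1L, j0 + 1L))
  }
  list(lookup = lookup)
}
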