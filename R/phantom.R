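#' Generate the femur-like test phantom
#'
#' Builds the watertight solid used as ground truth throughout the pipeline.
#' Like the proximal femur it combines a spherical head, an angled cylindrical
#' neck and a shaft; the shaft is a box (flat faces, sharp edges), the neck
#' joins head and shaft through smooth-union fillets (concave blends), and a
#' seeded set of shallow bumps on the head provides freeform surface detail.
#' The base is flat at z = 0 so the solid sits on a build plate. The surface
#' is extracted from the signed-distance field of this construction, so the
#' mesh is watertight by construction and deterministic for a fixed
#' `(complexity, seed)` pair.
#'
#' @param complexity integer >= 1; controls the sampling resolution of the
#'   distance field (cell size `1.6 / complexity` mm). Higher values refine
#'   the surface; enclosed volume converges with increasing complexity.
#' @param seed integer seed for the freeform head bumps.
#' @return A watertight [tri_mesh()], roughly 56 x 34 x 90 mm.
#' @examples
#' \donttest{
#' ph <- femur_phantom(complexity = 1, seed = 42)
#' mesh_volume(ph)
#' }
#' @export
femur_phantom <- function(complexity = 3, seed = 1) {
  if (!is.numeric(complexity) || length(complexity) != 1L || complexity < 1) {
    stop("`complexity` must be an integer >= 1", call. = FALSE)
  }
  complexity <- as.integer(complexity)
  cell <- 1.6 / complexity

  bumps <- with_seed(seed, {
    n_b <- 8L
    u <- matrix(rnorm(3L * n_b), ncol = 3L)
    u <- u / sqrt(rowSums(u^2))
    list(
      center = sweep(u * phantom_geom$head_r, 2, phantom_geom$head_c, "+"),
      amp = runif(n_b, -0.8, 0.8),
      width = runif(n_b, 4, 7)
    )
  })

  lo <- c(-17, -19, -1.5)
  hi <- c(43, 19, 91)
  nx <- ceiling((hi[1] - lo[1]) / cell) + 1L
  ny <- ceiling((hi[2] - lo[2]) / cell) + 1L
  nz <- ceiling((hi[3] - lo[3]) / cell) + 1L
  xs <- lo[1] + (seq_len(nx) - 1L) * cell
  ys <- lo[2] + (seq_len(ny) - 1L) * cell
  zs <- lo[3] + (seq_len(nz) - 1L) * cell
  # array indexed (slice i = z, row j = y, col k = x)
  px <- rep(xs, each = nz * ny)
  py <- rep(rep(ys, each = nz), times = nx)
  pz <- rep(zs, times = ny * nx)

  d <- phantom_sdf(px, py, pz, bumps)
  dim(d) <- c(nz, ny, nx)
  res <- cpp_marching_tets(-d, c(nz, ny, nx), c(cell, cell, cell), lo, 0)
  tri_mesh(res$vertices, res$faces + 1L)
}

# fixed construction parameters (mm)
phantom_geom <- list(
  shaft_half = c(14, 11, 25),
  shaft_c = c(0, 0, 25),
  neck_a = c(0, 0, 42),
  neck_b = c(20, 0, 64),
  neck_r = 9,
  head_c = c(24, 0, 72),
  head_r = 16,
  blend_k = 5
)

# signed distance of the phantom (negative inside)
phantom_sdf <- function(px, py, pz, bumps) {
  g <- phantom_geom
  # shaft: box
  qx <- abs(px - g$shaft_c[1]) - g$shaft_half[1]
  qy <- abs(py - g$shaft_c[2]) - g$shaft_half[2]
  qz <- abs(pz - g$shaft_c[3]) - g$shaft_half[3]
  d_box <- sqrt(pmax(qx, 0)^2 + pmax(qy, 0)^2 + pmax(qz, 0)^2) +
    pmin(pmax(qx, pmax(qy, qz)), 0)
  # neck: capsule from a to b
  ab <- g$neck_b - g$neck_a
  apx <- px - g$neck_a[1]; apy <- py - g$neck_a[2]; apz <- pz - g$neck_a[3]
  t <- pmin(pmax((apx * ab[1] + apy * ab[2] + apz * ab[3]) / sum(ab^2), 0), 1)
  d_neck <- sqrt((apx - t * ab[1])^2 + (apy - t * ab[2])^2 + (apz - t * ab[3])^2) -
    g$neck_r
  # head: sphere
  d_head <- sqrt((px - g$head_c[1])^2 + (py - g$head_c[2])^2 +
                 (pz - g$head_c[3])^2) - g$head_r
  # smooth union (concave fillets at the neck junctions)
  d <- smooth_min(d_box, d_neck, g$blend_k)
  d <- smooth_min(d, d_head, g$blend_k)
  # seeded freeform bumps on the head
  for (i in seq_along(bumps$amp)) {
    r2 <- (px - bumps$center[i, 1])^2 + (py - bumps$center[i, 2])^2 +
      (pz - bumps$center[i, 3])^2
    d <- d + bumps$amp[i] * exp(-r2 / bumps$width[i]^2)
  }
  # flat base: intersect with half-space z >= 0
  pmax(d, -pz)
}

# polynomial smooth minimum with blend radius k
smooth_min <- function(a, b, k) {
  h <- pmax(k - abs(a - b), 0) / k
  pmin(a, b) - h * h * k * 0.25
}
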