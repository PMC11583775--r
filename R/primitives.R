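#' Axis-aligned cube mesh
#'
#' @param edge edge length in mm.
#' @param origin corner with the smallest coordinates.
#' @return A watertight [tri_mesh()] with 12 triangles.
#' @export
mesh_cube <- function(edge = 1, origin = c(0, 0, 0)) {
  mesh_box(c(edge, edge, edge), origin)
}

#' Axis-aligned box mesh
#'
#' @param size edge lengths (x, y, z) in mm.
#' @param origin corner with the smallest coordinates.
#' @param subdivisions midpoint subdivisions of the 12 base triangles (kept
#'   planar), giving interior vertices on the faces.
#' @return A watertight [tri_mesh()] with `12 * 4^subdivisions` triangles.
#' @export
mesh_box <- function(size = c(1, 1, 1), origin = c(0, 0, 0), subdivisions = 0) {
  stopifnot(length(size) == 3L, all(size > 0))
  bits <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  # vertex order: (0,0,0),(1,0,0),(0,1,0),(1,1,0),(0,0,1),...
  v <- sweep(sweep(bits, 2, size, "*"), 2, origin, "+")
  f <- rbind(
    c(1, 4, 2), c(1, 3, 4),  # z = 0
    c(5, 6, 8), c(5, 8, 7),  # z = 1
    c(1, 2, 6), c(1, 6, 5),  # y = 0
    c(3, 8, 4), c(3, 7, 8),  # y = 1
    c(1, 5, 7), c(1, 7, 3),  # x = 0
    c(2, 4, 8), c(2, 8, 6)   # x = 1
  )
  for (s in seq_len(subdivisions)) {
    sub <- subdivide_midpoint(v, f)
    v <- sub$vertices
    f <- sub$faces
  }
  tri_mesh(v, f)
}

#' Icosphere mesh
#'
#' Subdivided icosahedron projected onto a sphere; the inscribed polyhedron is
#' slightly smaller than the analytic sphere, converging with subdivision.
#'
#' @param radius sphere radius (mm).
#' @param subdivisions number of 4-to-1 triangle subdivisions (0 = icosahedron).
#' @param center sphere center.
#' @return A watertight [tri_mesh()] with `20 * 4^subdivisions` triangles.
#' @export
icosphere <- function(radius = 1, subdivisions = 2, center = c(0, 0, 0)) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t, 0), c(1,  t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1,  t), c(0, 1,  t), c(0, -1, -t), c(0, 1, -t),
    c( t, 0, -1), c(t, 0,  1), c(-t, 0, -1), c(-t, 0,  1)
  )
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(subdivisions)) {
    sub <- subdivide_midpoint(v, f)
    v <- sub$vertices
    f <- sub$faces
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  # orient all faces outward (convex solid centered at the origin)
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  n <- cross3(b - a, cc - a)
  centroid <- (a + b + cc) / 3
  flip <- rowSums(n * centroid) < 0
  f[flip, c(2, 3)] <- f[flip, c(3, 2)]
  tri_mesh(sweep(v, 2, center, "+"), f)
}

cross3 <- function(u, w) {
  cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
        u[, 3] * w[, 1] - u[, 1] * w[, 3],
        u[, 1] * w[, 2] - u[, 2] * w[, 1])
}

# 4-to-1 midpoint subdivision with edge-keyed midpoint sharing
subdivide_midpoint <- function(v, f) {
  n <- nrow(v)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- pmin(e[, 1], e[, 2]) * (n + 1) + pmax(e[, 1], e[, 2])
  uk <- unique(key)
  mid_idx <- match(key, uk) + n
  first <- match(uk, key)
  mids <- (v[e[first, 1], , drop = FALSE] + v[e[first, 2], , drop = FALSE]) / 2
  v2 <- rbind(v, mids)
  m <- nrow(f)
  m12 <- mid_idx[seq_len(m)]
  m23 <- mid_idx[m + seq_len(m)]
  m31 <- mid_idx[2 * m + seq_len(m)]
  f2 <- rbind(
    cbind(f[, 1], m12, m31),
    cbind(m12, f[, 2], m23),
    cbind(m31, m23, f[, 3]),
    cbind(m12, m23, m31)
  )
  list(vertices = v2, faces = f2)
}
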