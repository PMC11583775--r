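#' Triangle mesh in millimetres
#'
#' The carrier type for every surface in the pipeline: the phantom, the
#' segmentation results, the print-STLs and the simulated printed models.
#' Faces are triples of vertex indices wound counter-clockwise when seen from
#' outside the solid, so the signed enclosed volume of a valid solid is
#' positive.
#'
#' @param vertices numeric matrix with three columns (x, y, z in mm).
#' @param faces integer matrix with three columns of 1-based vertex indices.
#' @return An object of class `tri_mesh` with elements `vertices` and `faces`.
#' @examples
#' m <- mesh_cube(edge = 1)
#' mesh_volume(m)
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("`vertices` must have 3 columns", call. = FALSE)
  if (ncol(faces) != 3L) stop("`faces` must have 3 columns", call. = FALSE)
  if (anyNA(vertices)) stop("`vertices` contains missing values", call. = FALSE)
  if (nrow(faces) > 0L) {
    rng <- range(faces)
    if (anyNA(faces) || rng[1] < 1L || rng[2] > nrow(vertices)) {
      stop("`faces` contains indices outside 1..n_vertices", call. = FALSE)
    }
  }
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  audit <- cpp_edge_audit(x$faces - 1L, nrow(x$vertices))
  cat(sprintf("<tri_mesh> %d vertices, %d faces (%s)\n",
              nrow(x$vertices), nrow(x$faces),
              if (audit$n_open_edges == 0L) "watertight" else
                sprintf("%d open edges", audit$n_open_edges)))
  invisible(x)
}

is_tri_mesh <- function(x) inherits(x, "tri_mesh")

assert_mesh <- function(mesh, arg = "mesh") {
  if (!is_tri_mesh(mesh)) stop(sprintf("`%s` must be a tri_mesh", arg), call. = FALSE)
  mesh
}

#' Count edges not shared by exactly two faces
#'
#' A mesh is watertight when every edge is shared by exactly two faces.
#'
#' @param mesh a [tri_mesh()].
#' @return Integer count of open (boundary or non-manifold) edges.
#' @export
count_open_edges <- function(mesh) {
  assert_mesh(mesh)
  cpp_edge_audit(mesh$faces - 1L, nrow(mesh$vertices))$n_open_edges
}

#' Is a mesh watertight?
#'
#' @inheritParams count_open_edges
#' @return `TRUE` when every edge is shared by exactly two faces.
#' @export
mesh_is_watertight <- function(mesh) count_open_edges(mesh) == 0L

#' Enclosed volume of a watertight mesh
#'
#' Signed volume via the divergence theorem, summed over faces. Positive for
#' consistently outward-wound solids. Non-watertight input is an error: an
#' open surface has no well-defined enclosed volume.
#'
#' @inheritParams count_open_edges
#' @return Volume in mm^3 (signed).
#' @examples
#' mesh_volume(mesh_cube(edge = 2))  # 8
#' @export
mesh_volume <- function(mesh) {
  assert_mesh(mesh)
  n_open <- count_open_edges(mesh)
  if (n_open > 0L) {
    stop(sprintf("mesh is not watertight: %d open edges", n_open), call. = FALSE)
  }
  sum(cpp_face_signed_volumes(mesh$vertices, mesh$faces - 1L))
}

#' Total surface area of a mesh
#'
#' @inheritParams count_open_edges
#' @return Area in mm^2.
#' @export
mesh_area <- function(mesh) {
  assert_mesh(mesh)
  sum(cpp_face_areas(mesh$vertices, mesh$faces - 1L))
}

#' Binary-STL file size proxy (Fi)
#'
#' The file size of a binary STL is fully determined by its triangle count:
#' an 80-byte header, a 4-byte triangle count and 50 bytes per triangle.
#' The proxy equals the on-disk size produced by [write_stl()] in binary mode
#' and is the complexity measure Fi used throughout the study tables.
#'
#' @inheritParams count_open_edges
#' @return File size in bytes: `84 + 50 * n_triangles`.
#' @examples
#' file_size_proxy(mesh_cube())  # 684
#' @export
file_size_proxy <- function(mesh) {
  assert_mesh(mesh)
  84 + 50 * nrow(mesh$faces)
}

#' Volume and complexity metrics of a mesh
#'
#' @inheritParams count_open_edges
#' @return A one-row tibble with `volume_mm3`, `n_triangles` and
#'   `file_size_bytes`.
#' @export
mesh_metrics <- function(mesh) {
  tibble::tibble(
    volume_mm3 = mesh_volume(mesh),
    n_triangles = nrow(mesh$faces),
    file_size_bytes = file_size_proxy(mesh)
  )
}

#' Apply a rigid transform to a mesh or point matrix
#'
#' @param x a [tri_mesh()] or an n x 3 point matrix.
#' @param transform a `rigid_transform` (see [icp_align()]).
#' @return Object of the same kind as `x`, transformed.
#' @export
apply_transform <- function(x, transform) {
  if (!inherits(transform, "rigid_transform")) {
    stop("`transform` must be a rigid_transform", call. = FALSE)
  }
  tp <- function(p) sweep(p %*% t(transform$rotation), 2, transform$translation, "+")
  if (is_tri_mesh(x)) {
    tri_mesh(tp(x$vertices), x$faces)
  } else {
    tp(as.matrix(x))
  }
}

# Weld vertices with identical coordinates and reindex faces.
weld_vertices <- function(vertices, faces) {
  n <- nrow(vertices)
  if (n == 0L) return(list(vertices = vertices, faces = faces))
  ord <- order(vertices[, 1], vertices[, 2], vertices[, 3])
  sv <- vertices[ord, , drop = FALSE]
  new_group <- c(TRUE, rowSums(abs(sv[-1, , drop = FALSE] - sv[-n, , drop = FALSE])) > 0)
  group_id <- cumsum(new_group)
  map <- integer(n)
  map[ord] <- group_id
  keep <- ord[new_group]
  list(
    vertices = vertices[keep, , drop = FALSE],
    faces = matrix(map[faces], ncol = 3L)
  )
}

# Drop faces with repeated vertex indices or zero area; returns mesh + count.
drop_degenerate_faces <- function(vertices, faces) {
  if (nrow(faces) == 0L) return(list(vertices = vertices, faces = faces, dropped = 0L))
  repeated <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] | faces[, 1] == faces[, 3]
  areas <- cpp_face_areas(vertices, faces - 1L)
  bad <- repeated | areas == 0
  list(vertices = vertices, faces = faces[!bad, , drop = FALSE], dropped = sum(bad))
}
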