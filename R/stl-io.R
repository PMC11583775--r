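#' Read an STL file
#'
#' Auto-detects the binary and ASCII dialects. Identical vertex coordinates
#' are welded into shared vertices so that watertightness checks and the
#' enclosed-volume computation work on the loaded mesh; degenerate
#' (zero-area) triangles are dropped with a message, since iso-surfacing and
#' some exporters can emit them and they corrupt normals.
#'
#' @param path file path.
#' @return A [tri_mesh()].
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  size <- file.size(path)
  head_raw <- readBin(path, "raw", n = min(size, 512L))
  is_ascii <- FALSE
  if (size >= 6 && identical(rawToChar(head_raw[1:5]), "solid")) {
    # binary files may also start with "solid": require a facet keyword in text
    txt <- suppressWarnings(rawToChar(head_raw))
    if (grepl("facet", txt, fixed = TRUE) || size < 84) is_ascii <- TRUE
  }
  raw_mesh <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path, size)
  welded <- weld_vertices(raw_mesh$vertices, raw_mesh$faces)
  cleaned <- drop_degenerate_faces(welded$vertices, welded$faces)
  if (cleaned$dropped > 0L) {
    message(sprintf("read_stl: dropped %d degenerate triangle(s)", cleaned$dropped))
  }
  tri_mesh(cleaned$vertices, cleaned$faces)
}

read_stl_binary <- function(path, size) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", n = 80L))
  count <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (is.na(count) || count < 0) stop("invalid binary STL triangle count", call. = FALSE)
  if (size != 84 + 50 * as.double(count)) {
    stop(sprintf(
      "truncated or corrupt binary STL: %d triangles declared, expected %.0f bytes, file has %.0f",
      count, 84 + 50 * as.double(count), as.double(size)), call. = FALSE)
  }
  if (count == 0L) {
    return(list(vertices = matrix(numeric(0), 0, 3), faces = matrix(integer(0), 0, 3)))
  }
  body <- readBin(con, "raw", n = 50L * count)
  # each record: 12 float32 (normal + 3 vertices) then 2 attribute bytes
  float_idx <- rep(seq(0L, by = 50L, length.out = count), each = 48L) + seq_len(48L)
  floats <- readBin(body[float_idx], "numeric", n = 12L * count, size = 4L,
                    endian = "little")
  rec <- matrix(floats, nrow = 12L) # columns are triangles
  v <- rbind(t(rec[4:6, , drop = FALSE]), t(rec[7:9, , drop = FALSE]),
             t(rec[10:12, , drop = FALSE]))
  # interleave so that triangle i owns rows (3i-2, 3i-1, 3i)
  ord <- as.vector(t(matrix(seq_len(3L * count), ncol = 3L)))
  v <- v[ord, , drop = FALSE]
  f <- matrix(seq_len(3L * count), ncol = 3L, byrow = TRUE)
  list(vertices = v, faces = f)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vlines) %% 3L != 0L) {
    stop("ASCII STL: vertex count is not a multiple of 3", call. = FALSE)
  }
  if (length(vlines) == 0L) {
    return(list(vertices = matrix(numeric(0), 0, 3), faces = matrix(integer(0), 0, 3)))
  }
  nums <- vapply(strsplit(trimws(vlines), "\\s+"), function(x) as.numeric(x[2:4]),
                 numeric(3))
  v <- t(nums)
  f <- matrix(seq_len(nrow(v)), ncol = 3L, byrow = TRUE)
  list(vertices = v, faces = f)
}

#' Write an STL file
#'
#' Vertices are held at full double precision inside the package and reduced
#' to 32-bit floats only here, as the binary STL format mandates.
#'
#' @param mesh a [tri_mesh()].
#' @param path output path.
#' @param format `"binary"` (default) or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, format = c("binary", "ascii")) {
  assert_mesh(mesh)
  format <- match.arg(format)
  v <- mesh$vertices
  f <- mesh$faces
  m <- nrow(f)
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  u <- b - a
  w <- cc - a
  n <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
             u[, 3] * w[, 1] - u[, 1] * w[, 3],
             u[, 1] * w[, 2] - u[, 2] * w[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n <- n / len
  if (format == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", "printqa binary STL"))[1:80]
    writeBin(header, con)
    writeBin(as.integer(m), con, size = 4L, endian = "little")
    if (m > 0L) {
      rec <- t(cbind(n, a, b, cc)) # 12 floats per column/triangle
      floats <- writeBin(as.vector(rec), raw(), size = 4L, endian = "little")
      out <- matrix(as.raw(0L), nrow = 50L, ncol = m)
      out[1:48, ] <- matrix(floats, nrow = 48L)
      writeBin(as.vector(out), con)
    }
  } else {
    fmt <- paste0(
      "facet normal %.9g %.9g %.9g\n outer loop\n",
      "  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n",
      " endloop\nendfacet")
    body <- if (m > 0L) {
      sprintf(fmt, n[, 1], n[, 2], n[, 3], a[, 1], a[, 2], a[, 3],
              b[, 1], b[, 2], b[, 3], cc[, 1], cc[, 2], cc[, 3])
    } else character(0)
    writeLines(c("solid printqa", body, "endsolid printqa"), path)
  }
  invisible(path)
}
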