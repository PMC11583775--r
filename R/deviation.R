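#' Rigid transform (rotation + translation)
#'
#' @param rotation 3 x 3 proper rotation matrix (orthonormal, det +1).
#' @param translation length-3 translation, mm.
#' @param rms final alignment RMS (mm), when produced by [icp_align()].
#' @param converged logical convergence flag.
#' @param iterations iteration count.
#' @return A `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            rms = NA_real_, converged = NA, iterations = NA_integer_) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      det(rotation) < 0) {
    stop("`rotation` must be orthonormal with det +1", call. = FALSE)
  }
  structure(list(rotation = rotation, translation = as.double(translation),
                 rms = rms, converged = converged,
                 iterations = as.integer(iterations)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(pmax((sum(diag(x$rotation)) - 1) / 2, -1), 1))
  cat(sprintf(
    "<rigid_transform> rotation %.3f rad, translation (%.3f, %.3f, %.3f) mm%s\n",
    ang, x$translation[1], x$translation[2], x$translation[3],
    if (is.na(x$rms)) "" else sprintf(", RMS %.5f mm (%s)", x$rms,
                                      if (isTRUE(x$converged)) "converged" else "not converged")))
  invisible(x)
}

#' Sample points on a mesh surface
#'
#' All vertices when the vertex count is within the budget, otherwise
#' area-weighted uniform sampling on the triangles.
#'
#' @param mesh a [tri_mesh()].
#' @param n_samples sample budget.
#' @param seed sampling seed.
#' @return An n x 3 point matrix.
#' @export
sample_surface <- function(mesh, n_samples, seed = 1) {
  assert_mesh(mesh)
  if (nrow(mesh$vertices) <= n_samples) return(mesh$vertices)
  areas <- cpp_face_areas(mesh$vertices, mesh$faces - 1L)
  with_seed(seed, {
    f <- sample.int(nrow(mesh$faces), n_samples, replace = TRUE, prob = areas)
    r1 <- runif(n_samples)
    r2 <- runif(n_samples)
    u <- sqrt(r1)
    a <- mesh$vertices[mesh$faces[f, 1], , drop = FALSE]
    b <- mesh$vertices[mesh$faces[f, 2], , drop = FALSE]
    cc <- mesh$vertices[mesh$faces[f, 3], , drop = FALSE]
    (1 - u) * a + u * (1 - r2) * b + u * r2 * cc
  })
}

bbox_diagonal <- function(mesh) {
  sqrt(sum((apply(mesh$vertices, 2, max) - apply(mesh$vertices, 2, min))^2))
}

#' Rigid ICP alignment of two meshes
#'
#' Iterative closest point: area-sampled points on the moving mesh are matched
#' to their exact closest points on the reference surface and a rigid
#' (rotation + translation, no scaling) transform is re-fitted by SVD until
#' the RMS improvement falls below `tol` or the iteration cap is reached.
#' Initialization matches centroids and principal axes; all four proper
#' axis-sign combinations are tried and the best post-ICP RMS kept. The
#' result is deterministic for a fixed sampling seed.
#'
#' @param moving mesh to be aligned.
#' @param reference fixed reference mesh.
#' @param n_samples number of sampled points on the moving surface.
#' @param max_iter iteration cap per initialization.
#' @param tol RMS improvement threshold, mm.
#' @param seed sampling seed.
#' @return A [rigid_transform()]; applying it to `moving` aligns it onto
#'   `reference`. When the final RMS exceeds 25% of the reference
#'   bounding-box diagonal the surfaces differ too much for a reliable
#'   alignment and an error is raised.
#' @export
icp_align <- function(moving, reference, n_samples = 2000, max_iter = 200,
                      tol = 1e-6, seed = 1) {
  assert_mesh(moving, "moving")
  assert_mesh(reference, "reference")
  if (nrow(moving$faces) == 0L || nrow(reference$faces) == 0L) {
    stop("both meshes must be non-empty", call. = FALSE)
  }
  p <- sample_surface(moving, n_samples, seed = seed)
  q <- sample_surface(reference, n_samples, seed = seed + 1L)
  bvh <- cpp_bvh_build(reference$vertices, reference$faces - 1L)

  axes <- function(x) {
    e <- eigen(stats::cov(x), symmetric = TRUE)
    u <- e$vectors
    if (det(u) < 0) u[, 3] <- -u[, 3]
    u
  }
  um <- axes(p)
  ur <- axes(q)
  cm <- colMeans(p)
  cr <- colMeans(q)
  signs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))

  best <- NULL
  for (s in seq_len(nrow(signs))) {
    r0 <- ur %*% diag(signs[s, ]) %*% t(um)
    t0 <- cr - r0 %*% cm
    fit <- icp_refine(p, bvh, r0, as.double(t0), max_iter, tol)
    if (is.null(best) || fit$rms < best$rms) best <- fit
  }
  diag_len <- bbox_diagonal(reference)
  if (best$rms > 0.25 * diag_len) {
    stop(sprintf(
      "alignment unreliable: residual RMS %.2f mm exceeds 25%% of the reference diagonal (%.2f mm)",
      best$rms, diag_len), call. = FALSE)
  }
  rigid_transform(best$rotation, best$translation, rms = best$rms,
                  converged = best$converged, iterations = best$iterations)
}

icp_refine <- function(p, bvh, r, t, max_iter, tol) {
  rms_prev <- Inf
  converged <- FALSE
  it <- 0L
  cp <- colMeans(p)
  pc <- sweep(p, 2, cp)
  for (it in seq_len(max_iter)) {
    x <- sweep(p %*% t(r), 2, t, "+")
    cl <- cpp_bvh_closest(bvh, x)
    rms <- sqrt(mean(cl$distance^2))
    if (is.finite(rms_prev) && rms_prev - rms < tol) {
      converged <- TRUE
      rms_prev <- min(rms, rms_prev)
      break
    }
    rms_prev <- rms
    y <- cl$point
    cy <- colMeans(y)
    h <- crossprod(pc, sweep(y, 2, cy))
    sv <- svd(h)
    d <- sign(det(sv$v %*% t(sv$u)))
    r <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    t <- as.double(cy - r %*% cp)
  }
  if (!converged) {
    x <- sweep(p %*% t(r), 2, t, "+")
    rms_prev <- sqrt(mean(cpp_bvh_closest(bvh, x)$distance^2))
  }
  list(rotation = r, translation = t, rms = rms_prev, converged = converged,
       iterations = it)
}

#' Signed surface deviation between two meshes
#'
#' From every sample point on the analyzed surface, the closest point on the
#' reference surface is found (exact point-to-triangle distance on a BVH);
#' the sign is +1 when the analyzed point lies outside the reference solid
#' and -1 inside (ray-parity test), so a negative mean indicates the
#' analyzed object is smaller than the reference. Sampling uses all analyzed
#' vertices when they fit the budget, else seeded area-weighted sampling.
#' Meshes are assumed pre-aligned (see [icp_align()]).
#'
#' @param analyzed mesh whose surface is sampled.
#' @param reference watertight reference mesh.
#' @param n_samples sample budget (default 1e5).
#' @param seed sampling seed (recorded in the result).
#' @param direction correspondence direction; the default follows the
#'   analyzed-to-reference convention. The reverse direction samples the
#'   reference surface instead, keeping the sign convention (negative mean =
#'   analyzed smaller).
#' @return A `deviation_stats`: tibble of per-sample signed deviations plus
#'   `mean_dS`, `sigma`, `six_sigma_dS` (= 6 * sigma) and `n_samples`.
#' @export
signed_surface_deviation <- function(analyzed, reference, n_samples = 1e5,
                                     seed = 1,
                                     direction = c("analyzed_to_reference",
                                                   "reference_to_analyzed")) {
  assert_mesh(analyzed, "analyzed")
  assert_mesh(reference, "reference")
  direction <- match.arg(direction)
  src <- if (direction == "analyzed_to_reference") analyzed else reference
  dst <- if (direction == "analyzed_to_reference") reference else analyzed
  n_open <- count_open_edges(dst)
  if (n_open > 0L) {
    stop(sprintf(
      "inside/outside test impossible: target mesh is not watertight (%d open edges)",
      n_open), call. = FALSE)
  }
  pts <- sample_surface(src, n_samples, seed = seed)
  bvh <- cpp_bvh_build(dst$vertices, dst$faces - 1L)
  cl <- cpp_bvh_closest(bvh, pts)
  inside <- cpp_bvh_inside(bvh, pts)
  sgn <- ifelse(inside, -1, 1)
  if (direction == "reference_to_analyzed") sgn <- -sgn
  dev <- sgn * cl$distance
  new_deviation_stats(
    tibble::tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3], deviation = dev),
    seed = seed, direction = direction
  )
}

new_deviation_stats <- function(samples, seed = NA_integer_,
                                direction = "analyzed_to_reference") {
  n <- nrow(samples)
  m <- if (n > 0) mean(samples$deviation) else NA_real_
  s <- if (n > 1) sd(samples$deviation) else if (n == 1) 0 else NA_real_
  structure(
    list(samples = samples, mean_dS = m, sigma = s,
         six_sigma_dS = if (is.na(s)) NA_real_ else 6 * s,
         n_samples = n, seed = seed, direction = direction),
    class = "deviation_stats"
  )
}

#' @export
print.deviation_stats <- function(x, ...) {
  cat(sprintf(
    "<deviation_stats> n = %d: mean dS %.4f mm, sigma %.4f mm, 6-sigma dS %.4f mm\n",
    x$n_samples, x$mean_dS, x$sigma, x$six_sigma_dS))
  invisible(x)
}

#' @export
tidy.deviation_stats <- function(x, ...) x$samples

#' @export
glance.deviation_stats <- function(x, ...) {
  tibble::tibble(mean_dS = x$mean_dS, sigma = x$sigma,
                 six_sigma_dS = x$six_sigma_dS, n_samples = x$n_samples)
}

#' Export deviation results as an ASCII table
#'
#' Plain-text dialect: `#`-prefixed header lines carrying the summary
#' statistics, a column-name line, then one line per sample with the analyzed
#' point and its signed deviation at six decimals.
#'
#' @param stats a `deviation_stats`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_deviation_ascii <- function(stats, path) {
  if (!inherits(stats, "deviation_stats")) {
    stop("`stats` must be a deviation_stats", call. = FALSE)
  }
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.6f", v))
  header <- c(
    "# printqa surface deviation export",
    sprintf("# n_samples %d", stats$n_samples),
    sprintf("# mean_dS %s", fmt(stats$mean_dS)),
    sprintf("# sigma %s", fmt(stats$sigma)),
    sprintf("# six_sigma_dS %s", fmt(stats$six_sigma_dS)),
    "x y z deviation"
  )
  body <- if (stats$n_samples > 0) {
    sprintf("%.6f %.6f %.6f %.6f", stats$samples$x, stats$samples$y,
            stats$samples$z, stats$samples$deviation)
  } else {
    character(0)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Re-import an ASCII deviation export
#'
#' @param path file written by [write_deviation_ascii()].
#' @return A `deviation_stats` rebuilt from the per-sample table.
#' @export
read_deviation_ascii <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  body <- body[-1] # column header
  samples <- if (length(body) > 0) {
    m <- matrix(scan(text = body, quiet = TRUE), ncol = 4L, byrow = TRUE)
    tibble::tibble(x = m[, 1], y = m[, 2], z = m[, 3], deviation = m[, 4])
  } else {
    tibble::tibble(x = numeric(0), y = numeric(0), z = numeric(0),
                   deviation = numeric(0))
  }
  new_deviation_stats(samples)
}
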