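#' Partial error of a pipeline stage
#'
#' A stage's contribution to the total geometric error, characterized by the
#' mean signed surface deviation and its standard deviation. The three stages
#' are segmentation (SegE: ground truth vs. direct segmentation), digital
#' editing (DEE: direct segmentation vs. print-STL) and printing (PrE:
#' print-STL vs. printed model).
#'
#' @param label one of `"SegE"`, `"DEE"`, `"PrE"`.
#' @param d_mean mean surface deviation, mm.
#' @param sigma standard deviation of the surface deviation, mm (>= 0).
#' @return A `partial_error`.
#' @export
partial_error <- function(label, d_mean, sigma) {
  label <- match.arg(label, c("SegE", "DEE", "PrE"))
  stopifnot_scalar_num(d_mean, "d_mean")
  stopifnot_scalar_num(sigma, "sigma", nonneg = TRUE)
  structure(list(label = label, d_mean = d_mean, sigma = sigma),
            class = "partial_error")
}

#' @export
print.partial_error <- function(x, ...) {
  cat(sprintf("<partial_error> %s: %.4f mm +/- %.4f mm\n", x$label, x$d_mean, x$sigma))
  invisible(x)
}

#' @export
tidy.partial_error <- function(x, ...) {
  tibble::tibble(label = x$label, d_mean = x$d_mean, sigma = x$sigma)
}

#' Gaussian error propagation of the three partial errors
#'
#' The total error of the pipeline: means add, variances add (the partial
#' errors are treated as independent; no covariance terms). The mean
#' contributions can cancel, but the spread can only grow with each
#' processing step, so the total sigma is at least as large as each partial
#' sigma.
#'
#' @param ... exactly three [partial_error()] objects with labels SegE, DEE
#'   and PrE (any order). Duplicated or missing labels are an error.
#' @return A `total_error` with `d_mean_total`, `sigma_total` and
#'   `six_sigma` (= 6 * sigma_total); the partials are kept in `$partials`.
#' @examples
#' propagate_total(
#'   partial_error("SegE", 0.1, 3),
#'   partial_error("DEE", 0.1, 4),
#'   partial_error("PrE", 0.1, 0)
#' ) # mean 0.3, sigma 5
#' @export
propagate_total <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) && !inherits(parts[[1]], "partial_error")) {
    parts <- parts[[1]]
  }
  if (!all(vapply(parts, inherits, logical(1), "partial_error"))) {
    stop("all inputs must be partial_error objects", call. = FALSE)
  }
  labels <- vapply(parts, `[[`, character(1), "label")
  if (!setequal(labels, c("SegE", "DEE", "PrE")) || anyDuplicated(labels)) {
    stop(sprintf("need exactly one SegE, one DEE and one PrE (got: %s)",
                 paste(labels, collapse = ", ")), call. = FALSE)
  }
  parts <- parts[match(c("SegE", "DEE", "PrE"), labels)]
  d_mean <- sum(vapply(parts, `[[`, numeric(1), "d_mean"))
  sigma <- sqrt(sum(vapply(parts, `[[`, numeric(1), "sigma")^2))
  structure(
    list(d_mean_total = d_mean, sigma_total = sigma, six_sigma = 6 * sigma,
         partials = parts),
    class = "total_error"
  )
}

#' @export
print.total_error <- function(x, ...) {
  cat(sprintf("<total_error> %.4f mm +/- %.4f mm (6-sigma %.4f mm)\n",
              x$d_mean_total, x$sigma_total, x$six_sigma))
  invisible(x)
}

#' @export
tidy.total_error <- function(x, ...) {
  dplyr::bind_rows(
    lapply(x$partials, tidy),
    tibble::tibble(label = "Total", d_mean = x$d_mean_total, sigma = x$sigma_total)
  )
}

#' @export
glance.total_error <- function(x, ...) {
  tibble::tibble(d_mean_total = x$d_mean_total, sigma_total = x$sigma_total,
                 six_sigma = x$six_sigma)
}

#' Width of the 6-sigma interval
#'
#' The spread descriptor used throughout the study: the width of
#' `[mean - 3 sigma, mean + 3 sigma]`, which is `6 * sigma` (the mean
#' cancels).
#'
#' @param mean mean deviation, mm (does not affect the width).
#' @param sigma standard deviation, mm (>= 0).
#' @return `6 * sigma`, mm.
#' @examples
#' six_sigma_interval(0.0093, 0.2265)
#' @export
six_sigma_interval <- function(mean, sigma) {
  if (any(sigma < 0)) stop("`sigma` must be >= 0", call. = FALSE)
  (mean + 3 * sigma) - (mean - 3 * sigma)
}

#' Normal probability mass within 3 sigma
#'
#' Fraction of a normal distribution inside `[mean - 3 sigma, mean + 3 sigma]`
#' (about 99.7%), via the normal CDF.
#'
#' @return `pnorm(3) - pnorm(-3)`, about 0.99730.
#' @export
normal_coverage_3sigma <- function() {
  pnorm(3) - pnorm(-3)
}
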