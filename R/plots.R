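#' Plot a segmentation-error sweep
#'
#' Threshold response curves per slice thickness, faceted by kernel, for a
#' chosen metric. Cells excluded by the volume cut-off appear as gaps in the
#' deviation metrics.
#'
#' @param object a [run_sege_sweep()] table.
#' @param metric column to plot.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.sege_sweep <- function(object,
                                metric = c("dV_rel_pct", "mean_dS",
                                           "six_sigma_dS", "Fi_bytes"),
                                ...) {
  metric <- match.arg(metric)
  df <- dplyr::filter(object, .data$software_profile == object$software_profile[1])
  df$thickness <- factor(df$slice_thickness_mm)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold_hu,
                                   y = .data[[metric]],
                                   colour = .data$thickness)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~kernel) +
    ggplot2::labs(x = "threshold (HU)", y = metric,
                  colour = "slice thickness (mm)") +
    ggplot2::theme_minimal()
}

#' Plot a digital-editing study
#'
#' @param object a [run_dee_study()] table.
#' @param metric column to plot.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.dee_study <- function(object,
                               metric = c("dV_rel_pct", "dFi_rel_pct",
                                          "mean_dS", "six_sigma_dS"),
                               ...) {
  metric <- match.arg(metric)
  df <- object
  df$level <- factor(df$level, levels = c("low", "medium", "high", "none"))
  df$thickness <- factor(df$slice_thickness_mm)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level, y = .data[[metric]],
                                   fill = .data$thickness)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~software_profile, scales = "free_x") +
    ggplot2::labs(x = "smoothing level", y = metric,
                  fill = "slice thickness (mm)") +
    ggplot2::theme_minimal()
}

#' Plot a printing-error study
#'
#' Mean deviation with 3-sigma whiskers per print replicate.
#'
#' @param object a [run_pre_study()] table.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.pre_study <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$replicate),
                                       y = .data$mean_dS)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_dS - 3 * .data$sigma_dS,
                                          ymax = .data$mean_dS + 3 * .data$sigma_dS)) +
    ggplot2::facet_wrap(~printer) +
    ggplot2::labs(x = "replicate", y = "surface deviation (mm)") +
    ggplot2::theme_minimal()
}

#' Plot a total-error report
#'
#' Partial and total errors per configuration as mean +/- 3 sigma.
#'
#' @param object a [run_total_error()] table.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.total_error_report <- function(object, ...) {
  long <- dplyr::bind_rows(lapply(seq_len(nrow(object)), function(i) {
    r <- object[i, ]
    tibble::tibble(
      configuration = r$configuration,
      stage = factor(c("SegE", "DEE", "PrE", "Total"),
                     levels = c("SegE", "DEE", "PrE", "Total")),
      mean = c(r$sege_mean, r$dee_mean, r$pre_mean, r$d_mean_total),
      sigma = c(r$sege_sigma, r$dee_sigma, r$pre_sigma, r$sigma_total)
    )
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stage, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - 3 * .data$sigma,
                                          ymax = .data$mean + 3 * .data$sigma)) +
    ggplot2::facet_wrap(~configuration) +
    ggplot2::labs(x = NULL, y = "surface deviation (mm)") +
    ggplot2::theme_minimal()
}
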