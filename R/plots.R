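#' Plot a calibration curve as per-bin boxes
#'
#' Draws the classic score-vs-accuracy panel: one box per score bin
#' (quartiles with 1.5 x IQR whiskers), the per-bin mean as a line, and the
#' identity diagonal for reference.
#'
#' @param object A `calibration_curve` from [build_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot calibration_curve
#' @export
autoplot.calibration_curve <- function(object, ...) {
  d <- tidy(object)
  d <- d[d$n > 0, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin_mid)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$whisker_lo,
                                        ymax = .data$whisker_hi),
                           width = 0.01, colour = "grey40") +
    ggplot2::geom_crossbar(ggplot2::aes(y = .data$median, ymin = .data$q25,
                                        ymax = .data$q75),
                           width = 0.035, fill = "grey85", colour = "grey30") +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_rsq_emp), colour = "blue") +
    ggplot2::labs(x = "software quality score (Rsq_soft bin midpoint)",
                  y = "empirical accuracy (Rsq_emp)") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Plot mean accuracy along chromosome windows
#'
#' @param windows A window summary tibble from [window_summary()] or a
#'   before/after tibble from [before_after_filter_summary()] with
#'   `group_by = "windows"`.
#' @return A ggplot object.
#' @export
plot_window_accuracy <- function(windows) {
  if ("mean_rsq_emp_before" %in% names(windows)) {
    d <- tidyr::pivot_longer(
      windows, c("mean_rsq_emp_before", "mean_rsq_emp_after"),
      names_to = "filter", values_to = "mean_rsq_emp",
      names_prefix = "mean_rsq_emp_")
  } else {
    d <- dplyr::mutate(windows, filter = "all")
  }
  ggplot2::ggplot(d, ggplot2::aes(x = (.data$window_start +
                                         .data$window_end) / 2e6,
                                  y = .data$mean_rsq_emp,
                                  colour = .data$filter)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(size = 0.8, na.rm = TRUE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "mean Rsq_emp") +
    ggplot2::theme_minimal()
}

#' Plot mean accuracy by MAF bin
#'
#' @param bins A MAF summary tibble from [maf_summary()] or a before/after
#'   tibble from [before_after_filter_summary()] with
#'   `group_by = "maf_bins"`.
#' @return A ggplot object.
#' @export
plot_maf_accuracy <- function(bins) {
  if ("mean_rsq_emp_before" %in% names(bins)) {
    d <- tidyr::pivot_longer(
      bins, c("mean_rsq_emp_before", "mean_rsq_emp_after"),
      names_to = "filter", values_to = "mean_rsq_emp",
      names_prefix = "mean_rsq_emp_")
    ggplot2::ggplot(d, ggplot2::aes(x = .data$bin, y = .data$mean_rsq_emp,
                                    fill = .data$filter)) +
      ggplot2::geom_col(position = "dodge", na.rm = TRUE) +
      ggplot2::labs(x = "reference MAF bin", y = "mean Rsq_emp") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                         hjust = 1))
  } else {
    ggplot2::ggplot(bins, ggplot2::aes(x = .data$bin,
                                       y = .data$mean_rsq_emp)) +
      ggplot2::geom_col(na.rm = TRUE) +
      ggplot2::labs(x = "reference MAF bin", y = "mean Rsq_emp") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                         hjust = 1))
  }
}
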