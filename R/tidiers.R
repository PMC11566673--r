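#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a calibration curve
#'
#' @param x A `calibration_curve`.
#' @param ... Unused.
#' @return A plain tibble of per-bin summaries.
#' @method tidy calibration_curve
#' @export
tidy.calibration_curve <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "calibration_curve")
  as_tibble(out)
}

#' @rdname tidy.calibration_curve
#' @method glance calibration_curve
#' @export
glance.calibration_curve <- function(x, ...) {
  tibble(
    n_bins = nrow(x),
    n_bins_populated = sum(x$n > 0),
    bin_width = attr(x, "bin_width"),
    mode = attr(x, "mode"),
    n_variants = attr(x, "n_variants"),
    n_excluded = attr(x, "n_excluded")
  )
}

#' Tidy an equivalent-threshold result
#'
#' @param x An `equivalent_threshold`.
#' @param ... Unused.
#' @return `tidy()` returns the eligible-bin diagnostics; `glance()` a
#'   one-row summary with the recovered thresholds.
#' @method tidy equivalent_threshold
#' @export
tidy.equivalent_threshold <- function(x, ...) x$diagnostics

#' @rdname tidy.equivalent_threshold
#' @method glance equivalent_threshold
#' @export
glance.equivalent_threshold <- function(x, ...) {
  tibble(
    threshold = x$threshold,
    cumulative_threshold = x$cumulative_threshold,
    target = x$target, min_bin_n = x$min_bin_n,
    bin_width = x$bin_width, n_eligible_bins = x$n_eligible_bins
  )
}

#' Tidy a score calibration
#'
#' @param x A `score_calibration` from [calibrate_scores()].
#' @param ... Unused.
#' @return `tidy()` returns the per-bin curve; `glance()` a one-row summary
#'   (thresholds plus overall confusion percentages when available).
#' @method tidy score_calibration
#' @export
tidy.score_calibration <- function(x, ...) tidy(x$curve)

#' @rdname tidy.score_calibration
#' @method glance score_calibration
#' @export
glance.score_calibration <- function(x, ...) {
  out <- glance(x$threshold)
  if (!is.null(x$confusion)) {
    cf <- x$confusion[x$confusion$group == "ALL",
                      c("pct_pass", "pct_tp_of_pass", "pct_fp_of_pass",
                        "pct_fn_of_notpass")]
    out <- dplyr::bind_cols(out, cf)
  }
  out
}

#' Tidy an imputation evaluation
#'
#' @param x An `imputation_evaluation` from [evaluate_imputation()].
#' @param ... Unused.
#' @return `tidy()` binds the per-variant statistics of all call sets with
#'   a `software` column; `glance()` gives one row per call set with the
#'   headline means.
#' @method tidy imputation_evaluation
#' @export
tidy.imputation_evaluation <- function(x, ...) {
  dplyr::bind_rows(x$stats, .id = "software")
}

#' @rdname tidy.imputation_evaluation
#' @method glance imputation_evaluation
#' @export
glance.imputation_evaluation <- function(x, ...) {
  purrr::map_dfr(x$stats, function(s) {
    tibble(
      n_variants = nrow(s),
      n_estimable_gt = sum(s$est_gt),
      mean_r_gt = mean(s$r_gt[s$est_gt]),
      mean_r_ds = mean(s$r_ds[s$est_ds]),
      mean_concordance = mean(s$concordance, na.rm = TRUE),
      mean_aer = mean(s$aer, na.rm = TRUE)
    )
  }, .id = "software")
}
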