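as_truth <- function(x, config) {
  if (inherits(x, "truth_matrix")) x else read_truth_vcf(x, config)
}

as_imputed <- function(x, dialect = "custom", info_key = NULL) {
  if (inherits(x, "imputed_callset")) x
  else read_imputed_vcf(x, dialect, info_key)
}

#' Evaluate one or more imputed call sets against a truth set
#'
#' End-to-end evaluation: aligns each imputed call set with the truth,
#' computes per-variant accuracy statistics, derives the common estimable
#' variant set across all call sets, and summarises mean empirical accuracy
#' by region for three comparisons: GT mode on the common set, DS mode on
#' the same (GT-estimable common) set, and DS mode on the full estimable
#' set of each software.
#'
#' @param truth A `truth_matrix` or path to a truth VCF.
#' @param imputed A single `imputed_callset`/path, or a (preferably named)
#'   list of them — one per imputation program.
#' @param config A [region_config()] used when reading from file.
#' @return An `imputation_evaluation` list: `stats` (named list of
#'   per-variant tibbles), `reports` (match reports), `common_keys`
#'   (common estimable variant set), `overview` (region x software x mode
#'   mean r), `segregation` (per-software segregation error rates) and
#'   `manifest`.
#' @export
evaluate_imputation <- function(truth, imputed, config = region_config()) {
  truth <- as_truth(truth, config)
  if (!is.list(imputed) || inherits(imputed, "imputed_callset"))
    imputed <- list(imputed)
  imputed <- purrr::map(imputed, as_imputed)
  nm <- names(imputed)
  if (is.null(nm) || any(nm == ""))
    nm <- purrr::imap_chr(imputed, function(x, i)
      paste0(x$dialect, if (is.character(i)) "" else paste0("_", i)))
  names(imputed) <- make.unique(nm)

  aligned <- purrr::map(imputed, function(im) match_variants(truth, im))
  stats <- purrr::map(aligned, per_variant_stats)
  reports <- purrr::map_dfr(aligned, function(a) a$report, .id = "software")
  common <- common_estimable_set(stats)
  common_keys <- variant_key_chr(common)
  seg <- purrr::map_dfr(aligned, segregation_errors, .id = "software")

  overview <- purrr::map_dfr(stats, function(s) {
    on_common <- variant_key_chr(s) %in% common_keys
    dplyr::bind_rows(
      s |> dplyr::filter(on_common, .data$est_gt) |>
        dplyr::group_by(.data$region) |>
        dplyr::summarise(mode = "GT_common", n = dplyr::n(),
                         mean_r = mean(.data$r_gt),
                         sd_r = stats::sd(.data$r_gt), .groups = "drop"),
      s |> dplyr::filter(on_common, .data$est_ds) |>
        dplyr::group_by(.data$region) |>
        dplyr::summarise(mode = "DS_common", n = dplyr::n(),
                         mean_r = mean(.data$r_ds),
                         sd_r = stats::sd(.data$r_ds), .groups = "drop"),
      s |> dplyr::filter(.data$est_ds) |>
        dplyr::group_by(.data$region) |>
        dplyr::summarise(mode = "DS_all", n = dplyr::n(),
                         mean_r = mean(.data$r_ds),
                         sd_r = stats::sd(.data$r_ds), .groups = "drop")
    )
  }, .id = "software")

  structure(
    list(stats = stats, reports = reports,
         common_keys = common, overview = overview, segregation = seg,
         manifest = run_manifest(reports)),
    class = "imputation_evaluation"
  )
}

run_manifest <- function(reports) {
  list(
    tool = "imputeval",
    version = as.character(utils::packageVersion("imputeval")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    counts = reports
  )
}

#' @export
print.imputation_evaluation <- function(x, ...) {
  cat("<imputation_evaluation>", length(x$stats), "call set(s):",
      paste(names(x$stats), collapse = ", "), "\n")
  cat("  common estimable variants:", nrow(x$common_keys), "\n")
  print(x$overview, n = 12)
  invisible(x)
}

#' Calibrate a software quality score against empirical accuracy
#'
#' Builds the binned calibration curve, derives the software-equivalent
#' score threshold for a target mean empirical accuracy, and accounts for
#' the true/false positives and false negatives of filtering at that
#' threshold, overall and by variant class x MAF group.
#'
#' @param stats Per-variant statistics tibble from [per_variant_stats()].
#' @param target_rsq_emp Target mean empirical squared accuracy.
#' @param bin_width Score bin width.
#' @param min_bin_n Minimum occupancy for a bin to enter the threshold
#'   scan.
#' @param mode `"ds"` (default) or `"gt"`.
#' @return A `score_calibration` list: `curve`, `threshold`
#'   (an `equivalent_threshold`), `confusion` and `groups` tibbles (or
#'   `NULL` when no threshold achieves the target).
#' @export
calibrate_scores <- function(stats, target_rsq_emp = 0.8, bin_width = 0.05,
                             min_bin_n = 50, mode = c("ds", "gt")) {
  mode <- match.arg(mode)
  curve <- build_curve(stats, bin_width, mode)
  thr <- equivalent_threshold(curve, target_rsq_emp, min_bin_n)
  confusion <- NULL; groups <- NULL
  if (!is.na(thr$threshold)) {
    confusion <- threshold_confusion(stats, thr$threshold, target_rsq_emp,
                                     mode)
    groups <- threshold_confusion(stats, thr$threshold, target_rsq_emp, mode,
                                  by_group = TRUE)
  }
  structure(
    list(curve = curve, threshold = thr, confusion = confusion,
         groups = groups, mode = mode),
    class = "score_calibration"
  )
}

#' @export
print.score_calibration <- function(x, ...) {
  print(x$threshold)
  if (!is.null(x$confusion)) print(x$confusion)
  invisible(x)
}
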