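stat_column <- function(mode = c("ds", "gt")) {
  mode <- match.arg(mode)
  list(rsq = paste0("rsq_emp_", mode), r = paste0("r_", mode),
       est = paste0("est_", mode))
}

#' Mean empirical accuracy in adjacent genomic windows
#'
#' Tiles each chromosome into adjacent half-open windows
#' `[k*w, (k+1)*w)` (0-based multiples of the window size) and averages the
#' squared empirical accuracy of the estimable variants in each window.
#' Windows with no variants are reported with `n = 0` and no mean, so
#' chromosome tracks plot with explicit gaps.
#'
#' @param stats Per-variant statistics tibble from [per_variant_stats()].
#' @param window_size_bp Window width in bp (default 1 Mb).
#' @param mode Which empirical accuracy to summarise: dosage (`"ds"`,
#'   default) or best-guess (`"gt"`).
#' @return Tibble with `chrom`, `window_start`, `window_end`, `n`,
#'   `mean_rsq_emp`, `mean_r`, `sd`.
#' @export
window_summary <- function(stats, window_size_bp = 1e6, mode = c("ds", "gt")) {
  cols <- stat_column(mode)
  if (window_size_bp <= 0) abort("`window_size_bp` must be positive.")
  w <- window_size_bp
  est <- stats[[cols$est]]
  stats |>
    dplyr::mutate(.win = floor(.data$pos / w),
                  .rsq = ifelse(est, .data[[cols$rsq]], NA_real_),
                  .r = ifelse(est, .data[[cols$r]], NA_real_)) |>
    dplyr::group_by(chrom = .data$chrom) |>
    tidyr::complete(.win = tidyr::full_seq(c(0, .data$.win), 1)) |>
    dplyr::group_by(.data$chrom, .data$.win) |>
    dplyr::summarise(
      n = sum(!is.na(.data$.rsq)),
      mean_rsq_emp = if (sum(!is.na(.data$.rsq)) > 0)
        mean(.data$.rsq, na.rm = TRUE) else NA_real_,
      mean_r = if (sum(!is.na(.data$.r)) > 0)
        mean(.data$.r, na.rm = TRUE) else NA_real_,
      sd = if (sum(!is.na(.data$.rsq)) > 1)
        stats::sd(.data$.rsq, na.rm = TRUE) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::transmute(.data$chrom,
                     window_start = .data$.win * w,
                     window_end = (.data$.win + 1) * w,
                     .data$n, .data$mean_rsq_emp, .data$mean_r, .data$sd)
}

default_maf_edges <- c(0, 0.005, 0.01, 0.025, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5)

#' Mean empirical accuracy by minor allele frequency bin
#'
#' Assigns variants to half-open MAF bins `(lower, upper]` on the
#' reference-population minor allele frequency and averages the squared
#' empirical accuracy of the estimable variants in each bin. A MAF of
#' exactly 0 falls in the first bin.
#'
#' @inheritParams window_summary
#' @param maf_edges Increasing bin edges on \[0, 0.5\].
#' @return Tibble with `bin` label, `maf_lo`, `maf_hi`, `n`, `mean_rsq_emp`,
#'   `mean_r`, `sd`.
#' @export
maf_summary <- function(stats, maf_edges = default_maf_edges,
                        mode = c("ds", "gt")) {
  cols <- stat_column(mode)
  maf <- stats$maf_ref
  if (any(maf < 0 | maf > 0.5, na.rm = TRUE))
    abort("maf_ref values must lie in [0, 0.5].")
  stopifnot(length(maf_edges) >= 2, !is.unsorted(maf_edges, strictly = TRUE))
  idx <- cut(maf, breaks = maf_edges, include.lowest = TRUE, right = TRUE)
  est <- stats[[cols$est]]
  rsq <- ifelse(est, stats[[cols$rsq]], NA_real_)
  r <- ifelse(est, stats[[cols$r]], NA_real_)
  tibble(bin_idx = as.integer(idx), rsq = rsq, r = r) |>
    dplyr::filter(!is.na(.data$bin_idx)) |>
    tidyr::complete(bin_idx = seq_len(length(maf_edges) - 1)) |>
    dplyr::group_by(.data$bin_idx) |>
    dplyr::summarise(
      n = sum(!is.na(.data$rsq)),
      mean_rsq_emp = if (sum(!is.na(.data$rsq)) > 0)
        mean(.data$rsq, na.rm = TRUE) else NA_real_,
      mean_r = if (sum(!is.na(.data$r)) > 0)
        mean(.data$r, na.rm = TRUE) else NA_real_,
      sd = if (sum(!is.na(.data$rsq)) > 1)
        stats::sd(.data$rsq, na.rm = TRUE) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::transmute(
      maf_lo = maf_edges[.data$bin_idx],
      maf_hi = maf_edges[.data$bin_idx + 1],
      bin = sprintf("(%g,%g]", .data$maf_lo, .data$maf_hi),
      .data$n, .data$mean_rsq_emp, .data$mean_r, .data$sd)
}

#' Two-group common / less-common MAF split
#'
#' Splits variants at a reference MAF of `split`: "common" means
#' `maf_ref > split`, everything else (including exactly `split`) is
#' "less_common".
#'
#' @inheritParams window_summary
#' @param split MAF split point (default 0.05).
#' @return Tibble with one row per group.
#' @export
maf_group_summary <- function(stats, split = 0.05, mode = c("ds", "gt")) {
  cols <- stat_column(mode)
  est <- stats[[cols$est]]
  stats |>
    dplyr::mutate(
      group = ifelse(.data$maf_ref > split, "common", "less_common"),
      .rsq = ifelse(est, .data[[cols$rsq]], NA_real_)) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_variants = dplyr::n(),
      n_estimable = sum(!is.na(.data$.rsq)),
      mean_rsq_emp = if (sum(!is.na(.data$.rsq)) > 0)
        mean(.data$.rsq, na.rm = TRUE) else NA_real_,
      .groups = "drop")
}
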