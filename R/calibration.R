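#' Binned calibration curve of software score against empirical accuracy
#'
#' Bins variants on their software quality score (`rsq_soft`, x-axis) and
#' summarises the distribution of empirical squared accuracy (`rsq_emp`,
#' y-axis) inside each bin: count, mean, median, quartiles and
#' 1.5 x IQR whisker bounds — the ingredients of the classic score-vs-
#' accuracy boxplot. Variants with a non-estimable empirical accuracy or a
#' missing score are excluded and counted.
#'
#' Bins are half-open `[lo, hi)` on \[0, 1\] with the last bin closed at 1.
#'
#' @param stats Per-variant statistics tibble from [per_variant_stats()].
#' @param bin_width Score bin width (default 0.05).
#' @param mode Empirical accuracy mode: `"ds"` (default) or `"gt"`.
#' @return A `calibration_curve`: a tibble with one row per bin (`bin_lo`,
#'   `bin_hi`, `bin_mid`, `n`, `mean_rsq_emp`, `median`, `q25`, `q75`,
#'   `whisker_lo`, `whisker_hi`) and attributes `bin_width`, `mode`,
#'   `n_excluded`, `n_variants`.
#' @export
build_curve <- function(stats, bin_width = 0.05, mode = c("ds", "gt")) {
  cols <- stat_column(mode)
  if (nrow(stats) == 0) abort("No variants supplied.")
  if (bin_width <= 0 || bin_width > 1) abort("`bin_width` must be in (0, 1].")
  soft <- stats$rsq_soft
  emp <- ifelse(stats[[cols$est]], stats[[cols$rsq]], NA_real_)
  keep <- !is.na(soft) & !is.na(emp)
  n_excluded <- sum(!keep)
  soft <- soft[keep]; emp <- emp[keep]
  if (length(soft) == 0) abort("No variants with both rsq_soft and rsq_emp.")

  n_bins <- ceiling(1 / bin_width - 1e-9)
  idx <- pmin(floor(soft / bin_width) + 1L, n_bins)
  per_bin <- purrr::map(seq_len(n_bins), function(b) {
    x <- emp[idx == b]
    if (length(x) == 0) {
      return(tibble(n = 0L, mean_rsq_emp = NA_real_, median = NA_real_,
                    q25 = NA_real_, q75 = NA_real_,
                    whisker_lo = NA_real_, whisker_hi = NA_real_))
    }
    qs <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- qs[3] - qs[1]
    tibble(
      n = length(x), mean_rsq_emp = mean(x), median = qs[2],
      q25 = qs[1], q75 = qs[3],
      whisker_lo = min(x[x >= qs[1] - 1.5 * iqr]),
      whisker_hi = max(x[x <= qs[3] + 1.5 * iqr])
    )
  })
  out <- dplyr::bind_cols(
    tibble(bin_lo = (seq_len(n_bins) - 1) * bin_width,
           bin_hi = pmin(seq_len(n_bins) * bin_width, 1)),
    dplyr::bind_rows(per_bin)
  )
  out$bin_mid <- (out$bin_lo + out$bin_hi) / 2
  structure(out, class = c("calibration_curve", class(out)),
            bin_width = bin_width, mode = match.arg(mode),
            n_excluded = n_excluded, n_variants = length(soft))
}

#' Software-equivalent quality-score threshold
#'
#' Finds the score cutoff at which retained variants achieve a target mean
#' empirical accuracy, so that filters can be harmonised across imputation
#' programs whose scores are calibrated differently. The canonical
#' definition scans bins from the top of the score range: the threshold is
#' the smallest bin lower edge `t` such that every eligible bin (with at
#' least `min_bin_n` variants) at or above `t` has mean empirical accuracy
#' at or above `target`. A "cumulative" alternative — the smallest edge such
#' that the pooled mean over all variants with score >= edge meets the
#' target — is reported alongside for comparison.
#'
#' @param curve A `calibration_curve` from [build_curve()].
#' @param target_rsq_emp Target mean empirical squared accuracy (default
#'   0.8).
#' @param min_bin_n Minimum bin occupancy for a bin to take part in the
#'   scan; sparsely populated bins have unstable means (default 50).
#' @return An `equivalent_threshold` object: list with `threshold` (`NA` if
#'   no bin meets the target), `cumulative_threshold`, `target`,
#'   `min_bin_n`, `n_eligible_bins`, and `diagnostics` (the eligible bins
#'   with their means).
#' @export
equivalent_threshold <- function(curve, target_rsq_emp = 0.8, min_bin_n = 50) {
  stopifnot(inherits(curve, "calibration_curve"))
  eligible <- curve$n >= min_bin_n
  if (!any(eligible)) abort("No bins with n >= `min_bin_n`.")

  el <- curve[eligible, ]
  meets <- el$mean_rsq_emp >= target_rsq_emp
  # maximal all-meeting suffix of the eligible bins
  if (!meets[nrow(el)]) {
    threshold <- NA_real_
  } else {
    first_bad <- max(c(0, which(!meets)))
    suffix_start <- first_bad + 1
    threshold <- el$bin_lo[suffix_start]
    if (suffix_start == 1) threshold <- 0
  }

  # cumulative: pooled mean over all variants at or above each edge
  w <- curve$n; m <- curve$mean_rsq_emp
  csum_n <- rev(cumsum(rev(w)))
  csum_v <- rev(cumsum(rev(ifelse(w > 0, w * m, 0))))
  cum_mean <- ifelse(csum_n > 0, csum_v / csum_n, NA_real_)
  ok <- which(!is.na(cum_mean) & cum_mean >= target_rsq_emp)
  cumulative <- if (length(ok)) curve$bin_lo[min(ok)] else NA_real_

  structure(
    list(threshold = threshold, cumulative_threshold = cumulative,
         target = target_rsq_emp, min_bin_n = min_bin_n,
         bin_width = attr(curve, "bin_width"),
         n_eligible_bins = sum(eligible),
         diagnostics = as_tibble(el[, c("bin_lo", "bin_hi", "n",
                                        "mean_rsq_emp")])),
    class = "equivalent_threshold"
  )
}

#' @export
print.equivalent_threshold <- function(x, ...) {
  cat("<equivalent_threshold> target mean Rsq_emp >=", x$target, "\n")
  if (is.na(x$threshold)) {
    cat("  no score threshold achieves the target (see $diagnostics)\n")
  } else {
    cat("  threshold (bin scan):", x$threshold, "\n")
  }
  cat("  threshold (cumulative):", x$cumulative_threshold, "\n")
  invisible(x)
}

#' True/false positive and false negative accounting of a score filter
#'
#' Classifies variants against a score threshold and an empirical-accuracy
#' target: passing means `rsq_soft >= threshold`, achieving means
#' `rsq_emp >= target`. True positives pass and achieve; false positives
#' pass but do not achieve (reported as a percentage of passing variants);
#' false negatives do not pass yet achieve (percentage of non-passing
#' variants).
#'
#' @inheritParams build_curve
#' @param threshold Score threshold (pass is inclusive).
#' @param target_rsq_emp Empirical accuracy target (achieve is inclusive).
#' @param by_group Also break down by variant class x common/less-common
#'   MAF group (split at `maf_split`).
#' @param maf_split MAF split for the common group (`maf_ref > maf_split`).
#' @return Tibble with one row per group (`ALL` first): counts and the
#'   percentage conventions above; an undefined percentage (zero
#'   denominator) is `NA`.
#' @export
threshold_confusion <- function(stats, threshold, target_rsq_emp = 0.8,
                                mode = c("ds", "gt"), by_group = FALSE,
                                maf_split = 0.05) {
  cols <- stat_column(mode)
  if (nrow(stats) == 0) abort("No variants supplied.")
  d <- tibble(
    soft = stats$rsq_soft,
    emp = ifelse(stats[[cols$est]], stats[[cols$rsq]], NA_real_),
    vclass = stats$vclass,
    maf_group = ifelse(stats$maf_ref > maf_split, "common", "less_common")
  ) |>
    dplyr::filter(!is.na(.data$soft), !is.na(.data$emp))
  if (nrow(d) == 0) abort("No variants with both rsq_soft and rsq_emp.")

  summarise_grp <- function(dd, label) {
    pass <- dd$soft >= threshold
    ach <- dd$emp >= target_rsq_emp
    n_pass <- sum(pass); n_not <- sum(!pass)
    n_tp <- sum(pass & ach); n_fp <- sum(pass & !ach); n_fn <- sum(!pass & ach)
    tibble(
      group = label, threshold = threshold, target = target_rsq_emp,
      n_variants = nrow(dd),
      n_pass = n_pass, pct_pass = 100 * n_pass / nrow(dd),
      n_tp = n_tp,
      pct_tp_of_pass = if (n_pass > 0) 100 * n_tp / n_pass else NA_real_,
      n_fp = n_fp,
      pct_fp_of_pass = if (n_pass > 0) 100 * n_fp / n_pass else NA_real_,
      n_fn = n_fn,
      pct_fn_of_notpass = if (n_not > 0) 100 * n_fn / n_not else NA_real_
    )
  }
  out <- summarise_grp(d, "ALL")
  if (by_group) {
    groups <- d |>
      dplyr::group_by(.data$vclass, .data$maf_group) |>
      dplyr::group_split()
    out <- dplyr::bind_rows(
      out,
      purrr::map(groups, function(g)
        summarise_grp(g, paste(g$vclass[1], g$maf_group[1], sep = "/")))
    )
  }
  out
}

#' Group-level accuracy before and after score filtering
#'
#' Summarises mean empirical accuracy per group — adjacent genomic windows
#' or MAF bins — before and after discarding variants below a score
#' threshold, showing where the filter rescues poorly imputed regions or
#' frequency classes.
#'
#' @inheritParams threshold_confusion
#' @param group_by `"windows"` or `"maf_bins"`.
#' @param window_size_bp Window width when `group_by = "windows"`.
#' @param maf_edges MAF bin edges when `group_by = "maf_bins"`.
#' @return Tibble with the group columns plus `n_before`,
#'   `mean_rsq_emp_before`, `n_after`, `mean_rsq_emp_after`.
#' @export
before_after_filter_summary <- function(stats, threshold,
                                        group_by = c("windows", "maf_bins"),
                                        mode = c("ds", "gt"),
                                        window_size_bp = 1e6,
                                        maf_edges = default_maf_edges) {
  group_by <- match.arg(group_by)
  mode <- match.arg(mode)
  passed <- stats[!is.na(stats$rsq_soft) & stats$rsq_soft >= threshold, ]
  if (group_by == "windows") {
    before <- window_summary(stats, window_size_bp, mode)
    after <- window_summary(passed, window_size_bp, mode)
    keys <- c("chrom", "window_start", "window_end")
  } else {
    before <- maf_summary(stats, maf_edges, mode)
    after <- maf_summary(passed, maf_edges, mode)
    keys <- c("maf_lo", "maf_hi", "bin")
  }
  dplyr::full_join(
    dplyr::select(before, dplyr::all_of(keys), n_before = "n",
                  mean_rsq_emp_before = "mean_rsq_emp"),
    dplyr::select(after, dplyr::all_of(keys), n_after = "n",
                  mean_rsq_emp_after = "mean_rsq_emp"),
    by = keys
  ) |>
    dplyr::mutate(n_after = dplyr::coalesce(.data$n_after, 0L)) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(keys[1])))
}
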