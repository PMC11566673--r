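#' Observed heterozygosity of one variant
#'
#' Fraction of non-missing calls that are heterozygous. Excess observed
#' heterozygosity over many adjacent variants typically marks collapsed
#' segmental duplications, where misaligned short reads produce false
#' heterozygous calls.
#'
#' @param g_vec Per-sample alternate-allele counts (0/1/2, `NA` allowed).
#' @return Fraction in \[0, 1\].
#' @examples
#' variant_heterozygosity(c(0, 1, 1, 2))  # 0.5
#' @export
variant_heterozygosity <- function(g_vec) {
  ok <- !is.na(g_vec)
  if (!any(ok)) abort("All genotypes missing; heterozygosity undefined.")
  mean(g_vec[ok] == 1)
}

truth_het <- function(truth) {
  n_called <- rowSums(!is.na(truth$g))
  if (any(n_called == 0)) abort("Variant(s) with all genotypes missing.")
  rowSums(truth$g == 1, na.rm = TRUE) / n_called
}

truth_subset <- function(truth, idx) {
  new_truth_matrix(truth$variants[idx, ], truth$g[idx, , drop = FALSE],
                   truth$samples, truth$n_skipped_multiallelic)
}

#' Excess-heterozygosity sliding-window filter
#'
#' Flags windows where at least `flag_pct` percent of the variants have
#' observed heterozygosity strictly above `het_threshold`, and removes all
#' such high-heterozygosity variants inside every flagged window. The
#' default tiles each chromosome with adjacent 0.5 Mb windows (step =
#' window); with a smaller step the removal is the union over all flagged
#' windows, and each variant is removed at most once.
#'
#' @param variants Tibble with `chrom`, `pos` and `het` columns, or a
#'   `truth_matrix` (heterozygosity is then computed from its genotypes).
#' @param window_bp Window width in bp (default 0.5 Mb).
#' @param step_bp Window step in bp (default = `window_bp`, adjacent tiling).
#' @param flag_pct Percentage of high-het variants at or above which a
#'   window is flagged (default 2).
#' @param het_threshold Heterozygosity above which a variant counts as
#'   high-het; the comparison is strict, so a variant at exactly the
#'   threshold is never removed (default 0.55).
#' @return List with `removed` (tibble of removed variants with their
#'   heterozygosity) and `windows` (per-window report: counts, percentage,
#'   flag).
#' @export
het_excess_filter <- function(variants, window_bp = 5e5, step_bp = window_bp,
                              flag_pct = 2, het_threshold = 0.55) {
  if (window_bp <= 0) abort("`window_bp` must be positive.")
  if (step_bp <= 0) abort("`step_bp` must be positive.")
  if (inherits(variants, "truth_matrix")) {
    variants <- dplyr::mutate(variants$variants, het = truth_het(variants))
  }
  stopifnot(all(c("chrom", "pos", "het") %in% names(variants)))

  high <- variants$het > het_threshold
  spans <- variants |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(max_pos = max(.data$pos), .groups = "drop")
  windows <- purrr::map2_dfr(spans$chrom, spans$max_pos, function(ch, mp) {
    tibble(chrom = ch, window_start = seq(0, mp, by = step_bp))
  }) |>
    dplyr::mutate(window_end = .data$window_start + window_bp)

  removed_idx <- logical(nrow(variants))
  win_stats <- purrr::pmap(windows, function(chrom, window_start, window_end) {
    inw <- variants$chrom == chrom & variants$pos >= window_start &
      variants$pos < window_end
    n <- sum(inw)
    nh <- sum(inw & high)
    pct <- if (n > 0) 100 * nh / n else 0
    flagged <- n >= 1 && pct >= flag_pct
    if (flagged) removed_idx[inw & high] <<- TRUE
    list(n_variants = n, n_high_het = nh, pct_high_het = pct, flagged = flagged)
  })
  windows <- dplyr::bind_cols(windows, dplyr::bind_rows(win_stats))
  list(
    removed = as_tibble(variants[removed_idx, ]),
    windows = windows
  )
}

#' Minor-allele-count filter
#'
#' Retains variants whose minor allele count over non-missing calls is at
#' least `min_mac` (inclusive: a variant with exactly `min_mac` copies is
#' kept).
#'
#' @param truth A `truth_matrix`, or a genotype matrix (variants x samples)
#'   of alternate-allele counts.
#' @param min_mac Minimum minor allele count (default 4).
#' @return Logical vector: `TRUE` for retained variants.
#' @export
mac_filter <- function(truth, min_mac = 4) {
  g <- if (inherits(truth, "truth_matrix")) truth$g else truth
  n_called <- rowSums(!is.na(g))
  alt <- rowSums(g, na.rm = TRUE)
  mac <- pmin(alt, 2 * n_called - alt)
  mac >= min_mac
}

#' Apply the reference-panel filters
#'
#' Applies the panel QC chain in order: biallelic (already enforced when
#' reading), minor allele count, then the excess-heterozygosity window
#' filter.
#'
#' @param truth A `truth_matrix` (the reference/truth panel).
#' @inheritParams mac_filter
#' @inheritParams het_excess_filter
#' @return List with the filtered `truth`, `mac_removed` and `het_removed`
#'   variant tibbles, the per-window `windows` report, and a one-row
#'   `counts` tibble.
#' @export
filter_reference_panel <- function(truth, min_mac = 4, window_bp = 5e5,
                                   step_bp = window_bp, flag_pct = 2,
                                   het_threshold = 0.55) {
  stopifnot(inherits(truth, "truth_matrix"))
  keep_mac <- mac_filter(truth, min_mac)
  mac_removed <- truth$variants[!keep_mac, c("chrom", "pos", "ref", "alt")]
  truth2 <- truth_subset(truth, which(keep_mac))

  hf <- het_excess_filter(truth2, window_bp, step_bp, flag_pct, het_threshold)
  if (nrow(hf$removed) > 0) {
    rm_key <- paste(hf$removed$chrom, hf$removed$pos, hf$removed$ref,
                    hf$removed$alt, sep = ":")
    keep <- !(variant_key_chr(truth2$variants) %in% rm_key)
  } else {
    keep <- rep(TRUE, nrow(truth2$variants))
  }
  out <- truth_subset(truth2, which(keep))
  list(
    truth = out,
    mac_removed = as_tibble(mac_removed),
    het_removed = hf$removed[, intersect(c("chrom", "pos", "ref", "alt", "het"),
                                         names(hf$removed))],
    windows = hf$windows,
    counts = tibble(
      n_in = nrow(truth$variants),
      n_mac_removed = sum(!keep_mac),
      n_het_removed = sum(!keep),
      n_out = nrow(out$variants)
    )
  )
}
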