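VAR_TOL <- 1e-12

#' Empirical imputation accuracy for one variant
#'
#' Pearson correlation between true genotypes (alternate-allele counts 0/1/2)
#' and imputed genotypes, either best-guess (`mode = "gt"`) or dosage
#' (`mode = "ds"`). Pairs with a missing value on either side are dropped.
#'
#' A variant must be segregating in both the real and the imputed best-guess
#' genotypes for r to be estimable in GT mode; otherwise the variance for
#' that position is zero and r cannot be estimated. In DS mode only the truth
#' needs to segregate, although a numerically constant dosage vector is also
#' flagged non-estimable.
#'
#' @param truth_vec Per-sample true alternate-allele counts (0/1/2, `NA`
#'   allowed).
#' @param imp_vec Per-sample imputed values: 0/1/2 for GT mode, \[0, 2\]
#'   dosages for DS mode.
#' @param mode `"gt"` or `"ds"`.
#' @return A list with `r` (`NA` when non-estimable), `estimable`, `reason`
#'   (`"ok"`, `"too_few_pairs"`, `"zero_truth_variance"`,
#'   `"zero_imputed_variance"`) and `n_pairs`.
#' @examples
#' empirical_r(c(0, 1, 2, 1), c(0, 1, 1, 1))$r  # ~0.816
#' @export
empirical_r <- function(truth_vec, imp_vec, mode = c("gt", "ds")) {
  mode <- match.arg(mode)
  stopifnot(length(truth_vec) == length(imp_vec))
  ok <- !is.na(truth_vec) & !is.na(imp_vec)
  t <- truth_vec[ok]; y <- imp_vec[ok]
  n <- length(t)
  if (n < 2)
    return(list(r = NA_real_, estimable = FALSE, reason = "too_few_pairs",
                n_pairs = n))
  vt <- sum((t - mean(t))^2) / n
  vy <- sum((y - mean(y))^2) / n
  if (vt <= VAR_TOL)
    return(list(r = NA_real_, estimable = FALSE,
                reason = "zero_truth_variance", n_pairs = n))
  if (vy <= VAR_TOL)
    return(list(r = NA_real_, estimable = FALSE,
                reason = "zero_imputed_variance", n_pairs = n))
  list(r = cor(t, y), estimable = TRUE, reason = "ok", n_pairs = n)
}

#' Allele-level imputation error rates for one variant
#'
#' Decomposes per-sample genotype differences into wrongly imputed alleles:
#' `fp_alleles = sum(max(gt_i - truth_i, 0))` (reference alleles imputed as
#' alternate) and `fn_alleles = sum(max(truth_i - gt_i, 0))` (alternate
#' alleles imputed as reference). Rates are percentages of the corresponding
#' truth allele totals:
#' * FPR = 100 * fp / (total reference alleles in truth),
#' * FNR = 100 * fn / (total alternate alleles in truth),
#' * AER = 100 * (fp + fn) / (2 * n_pairs).
#'
#' A rate with a zero denominator (e.g. FNR at a variant with no alternate
#' alleles in truth) is returned as `NA`, never as 0.
#'
#' @inheritParams empirical_r
#' @param gt_vec Imputed best-guess alternate-allele counts.
#' @return One-row tibble with `n_pairs`, `fp_alleles`, `fn_alleles`,
#'   `ref_alleles`, `alt_alleles`, `fpr`, `fnr`, `aer` (percent).
#' @examples
#' allelic_error_rates(c(0, 1, 2, 1), c(0, 1, 1, 1))
#' @export
allelic_error_rates <- function(truth_vec, gt_vec) {
  stopifnot(length(truth_vec) == length(gt_vec))
  ok <- !is.na(truth_vec) & !is.na(gt_vec)
  t <- truth_vec[ok]; y <- gt_vec[ok]
  n <- length(t)
  if (n == 0) abort("No complete (truth, imputed) pairs.")
  fp <- sum(pmax(y - t, 0))
  fn <- sum(pmax(t - y, 0))
  ref_al <- sum(2 - t); alt_al <- sum(t)
  tibble(
    n_pairs = n, fp_alleles = fp, fn_alleles = fn,
    ref_alleles = ref_al, alt_alleles = alt_al,
    fpr = if (ref_al > 0) 100 * fp / ref_al else NA_real_,
    fnr = if (alt_al > 0) 100 * fn / alt_al else NA_real_,
    aer = 100 * (fp + fn) / (2 * n)
  )
}

#' Genotype concordance for one variant
#'
#' Percentage of samples whose imputed best-guess genotype equals the true
#' genotype, over complete pairs.
#'
#' @inheritParams allelic_error_rates
#' @return Percentage in \[0, 100\].
#' @export
concordance <- function(truth_vec, gt_vec) {
  ok <- !is.na(truth_vec) & !is.na(gt_vec)
  if (!any(ok)) abort("No complete (truth, imputed) pairs.")
  100 * mean(truth_vec[ok] == gt_vec[ok])
}

# Vectorised per-variant Pearson r over a validity mask.
# Returns list(r, estimable) without allocating per-variant loops.
row_pearson <- function(X, Y, mask) {
  n <- rowSums(mask)
  Xm <- X; Xm[!mask] <- 0
  Ym <- Y; Ym[!mask] <- 0
  sx <- rowSums(Xm); sy <- rowSums(Ym)
  sxx <- rowSums(Xm * Xm); syy <- rowSums(Ym * Ym)
  sxy <- rowSums(Xm * Ym)
  vx <- pmax(sxx - sx^2 / pmax(n, 1), 0)
  vy <- pmax(syy - sy^2 / pmax(n, 1), 0)
  cv <- sxy - sx * sy / pmax(n, 1)
  est <- n >= 2 & vx / pmax(n, 1) > VAR_TOL & vy / pmax(n, 1) > VAR_TOL
  r <- rep(NA_real_, length(n))
  r[est] <- cv[est] / sqrt(vx[est] * vy[est])
  r <- pmin(pmax(r, -1), 1)
  list(r = r, estimable = est, n = n)
}

#' Per-variant empirical accuracy statistics
#'
#' The workhorse of the package: computes, for every aligned variant, the
#' empirical accuracy r in GT and DS mode, squared empirical accuracy
#' (`rsq_emp_*`), genotype concordance, the allele-level error rates
#' FPR/FNR/AER, segregation flags and estimability flags. Cells with a
#' missing value in truth, GT or DS are dropped pairwise for that variant.
#'
#' @param truth An aligned `truth_matrix`, or the list returned by
#'   [match_variants()] (in which case `imputed` is ignored).
#' @param imputed The aligned `imputed_callset`.
#' @return A tibble with one row per variant: variant identity and metadata
#'   (`chrom`, `pos`, `ref`, `alt`, `region`, `vclass`, `maf_ref`,
#'   `rsq_soft`), `n_pairs`, `r_gt`, `r_ds`, `rsq_emp_gt`, `rsq_emp_ds`,
#'   `concordance`, `fpr`, `fnr`, `aer`, estimability flags `est_gt`,
#'   `est_ds`, and segregation flags `seg_truth`, `seg_imp`.
#' @export
per_variant_stats <- function(truth, imputed = NULL) {
  if (is.list(truth) && !inherits(truth, "truth_matrix") &&
      all(c("truth", "imputed") %in% names(truth))) {
    imputed <- truth$imputed; truth <- truth$truth
  }
  stopifnot(inherits(truth, "truth_matrix"), inherits(imputed, "imputed_callset"),
            nrow(truth$g) == nrow(imputed$gt),
            identical(truth$samples, imputed$samples))
  G <- truth$g; GT <- imputed$gt; DS <- imputed$ds
  mask <- !is.na(G) & !is.na(GT) & !is.na(DS)
  n <- rowSums(mask)
  if (any(n == 0)) {
    warn(sprintf("%d variant(s) have no complete pairs; statistics are NA.",
                 sum(n == 0)))
  }
  Gm <- G; Gm[!mask] <- 0L
  GTm <- GT; GTm[!mask] <- 0L

  pg <- row_pearson(G, GT, mask)
  pd <- row_pearson(G, DS, mask)

  fp <- rowSums(pmax(GTm - Gm, 0))
  fn <- rowSums(pmax(Gm - GTm, 0))
  alt_al <- rowSums(Gm)
  ref_al <- 2 * n - alt_al
  fpr <- ifelse(ref_al > 0, 100 * fp / ref_al, NA_real_)
  fnr <- ifelse(alt_al > 0, 100 * fn / alt_al, NA_real_)
  aer <- ifelse(n > 0, 100 * (fp + fn) / (2 * n), NA_real_)
  conc <- ifelse(n > 0, 100 * rowSums((G == GT) & mask) / n, NA_real_)

  alt_imp <- rowSums(GTm)
  seg_truth <- alt_al > 0 & alt_al < 2 * n
  seg_imp <- alt_imp > 0 & alt_imp < 2 * n

  tibble(
    chrom = truth$variants$chrom, pos = truth$variants$pos,
    ref = truth$variants$ref, alt = truth$variants$alt,
    region = truth$variants$region, vclass = truth$variants$vclass,
    maf_ref = truth$variants$maf_ref,
    rsq_soft = imputed$variants$rsq_soft,
    n_pairs = as.integer(n),
    r_gt = pg$r, r_ds = pd$r,
    rsq_emp_gt = pg$r^2, rsq_emp_ds = pd$r^2,
    concordance = conc, fpr = fpr, fnr = fnr, aer = aer,
    est_gt = pg$estimable, est_ds = pd$estimable,
    seg_truth = seg_truth, seg_imp = seg_imp
  )
}

#' Common estimable variant set across software
#'
#' When benchmarking several imputation programs the GT-mode comparison is
#' restricted to the variants with an estimable r in every program, so that
#' a tool imputing rare variants as monomorphic does not drop its hardest
#' variants from its own average.
#'
#' @param stats_list A list of per-variant statistics tibbles (one per
#'   software), each from [per_variant_stats()].
#' @return A tibble of variant keys (`chrom`, `pos`, `ref`, `alt`) estimable
#'   in GT mode in every collection; empty (with a warning) if the
#'   intersection is empty.
#' @export
common_estimable_set <- function(stats_list) {
  stopifnot(is.list(stats_list), length(stats_list) >= 1)
  keys <- purrr::map(stats_list, function(s) {
    variant_key_chr(s[s$est_gt, c("chrom", "pos", "ref", "alt")])
  })
  common <- purrr::reduce(keys, intersect)
  if (length(common) == 0)
    warn("Common estimable variant set is empty.")
  first <- stats_list[[1]]
  out <- first[variant_key_chr(first) %in% common,
               c("chrom", "pos", "ref", "alt")]
  as_tibble(out)
}

#' Segregation error rates
#'
#' The percentage of variants segregating in the truth that were imputed as
#' monomorphic (best-guess), and conversely the percentage of truth-
#' monomorphic variants imputed as segregating. "Segregating" means at least
#' one copy of each allele among the target samples.
#'
#' @param truth Aligned `truth_matrix` or [match_variants()] result.
#' @param imputed Aligned `imputed_callset`.
#' @return One-row tibble with the two percentages and their explicit
#'   numerators and denominators; an undefined rate (zero denominator) is
#'   `NA` with a reason recorded in `note`.
#' @export
segregation_errors <- function(truth, imputed = NULL) {
  stats <- per_variant_stats(truth, imputed)
  n_seg <- sum(stats$seg_truth)
  n_mono <- sum(!stats$seg_truth)
  seg_as_mono <- sum(stats$seg_truth & !stats$seg_imp)
  mono_as_seg <- sum(!stats$seg_truth & stats$seg_imp)
  tibble(
    n_truth_segregating = n_seg, n_seg_imputed_monomorphic = seg_as_mono,
    pct_seg_as_mono = if (n_seg > 0) 100 * seg_as_mono / n_seg else NA_real_,
    n_truth_monomorphic = n_mono, n_mono_imputed_segregating = mono_as_seg,
    pct_mono_as_seg = if (n_mono > 0) 100 * mono_as_seg / n_mono else NA_real_,
    note = dplyr::case_when(
      n_seg == 0 ~ "no truth-segregating variants",
      n_mono == 0 ~ "no truth-monomorphic variants",
      TRUE ~ NA_character_
    )
  )
}
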