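# Independent brute-force Pearson correlation (textbook sum formula),
# kept free of any package internals so it can serve as an oracle.
bf_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Write a handcrafted VCF from header extras + body lines.
write_mini_vcf <- function(body, samples = c("S1", "S2"),
                           format_defs = "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                           info_defs = character()) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    info_defs, format_defs,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body
  ), path)
  path
}

# Truth container straight from a genotype matrix (variants x samples).
make_truth <- function(g, chrom = NULL, pos = NULL, maf_ref = NULL) {
  g <- as.matrix(g)
  v <- nrow(g)
  chrom <- chrom %||% rep("1", v)
  pos <- pos %||% (seq_len(v) * 1000L)
  n_called <- rowSums(!is.na(g))
  p <- rowSums(g, na.rm = TRUE) / (2 * pmax(n_called, 1))
  variants <- tibble::tibble(
    chrom = chrom, pos = as.integer(pos),
    ref = rep("A", v), alt = rep("T", v),
    vclass = "SNP",
    region = classify_region(chrom, pos),
    maf_ref = maf_ref %||% pmin(p, 1 - p),
    mac_ref = as.integer(pmin(rowSums(g, na.rm = TRUE),
                              2 * n_called - rowSums(g, na.rm = TRUE))),
    p_ref = p
  )
  samples <- sprintf("S%02d", seq_len(ncol(g)))
  imputeval:::new_truth_matrix(variants, g, samples)
}

# Matching imputed container; defaults to a perfect copy of the truth.
make_imputed <- function(truth, gt = NULL, ds = NULL, rsq_soft = NULL,
                         dialect = "custom") {
  gt <- gt %||% truth$g
  ds <- ds %||% (gt * 1.0)
  variants <- dplyr::mutate(
    truth$variants[, c("chrom", "pos", "ref", "alt", "vclass")],
    rsq_soft = rsq_soft %||% rep(1, nrow(truth$variants)))
  imputeval:::new_imputed_callset(variants, gt, ds, NULL, truth$samples,
                                  dialect)
}

# Minimal per-variant stats tibble for calibration tests.
make_stats <- function(soft, emp, maf_ref = 0.3, vclass = "SNP",
                       chrom = "1", pos = NULL) {
  n <- length(soft)
  tibble::tibble(
    chrom = rep_len(chrom, n),
    pos = as.integer(pos %||% (seq_len(n) * 1000)),
    ref = "A", alt = "T",
    region = "AUTOSOME", vclass = rep_len(vclass, n),
    maf_ref = rep_len(maf_ref, n), rsq_soft = soft,
    n_pairs = 70L,
    r_gt = sqrt(emp), r_ds = sqrt(emp),
    rsq_emp_gt = emp, rsq_emp_ds = emp,
    concordance = 100, fpr = 0, fnr = 0, aer = 0,
    est_gt = !is.na(emp), est_ds = !is.na(emp),
    seg_truth = TRUE, seg_imp = TRUE
  )
}
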