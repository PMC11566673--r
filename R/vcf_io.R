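#' @section Call-set containers:
#' Truth and imputed call sets are matrix-backed S3 containers: a `variants`
#' tibble (one row per variant, in file order) plus variants x samples
#' matrices. All downstream statistics functions return plain tibbles.
#' @name imputeval-containers
#' @keywords internal
NULL

new_truth_matrix <- function(variants, g, samples, n_skipped_multiallelic = 0L) {
  stopifnot(nrow(variants) == nrow(g), length(samples) == ncol(g))
  bad <- g[!is.na(g)]
  if (length(bad) && (any(bad < 0) || any(bad > 2))) {
    abort("Truth genotypes must be alternate-allele counts in {0, 1, 2} or missing.")
  }
  rownames(g) <- NULL
  colnames(g) <- samples
  structure(
    list(variants = as_tibble(variants), g = g, samples = samples,
         n_skipped_multiallelic = as.integer(n_skipped_multiallelic)),
    class = "truth_matrix"
  )
}

new_imputed_callset <- function(variants, gt, ds, gp = NULL, samples,
                                dialect = "custom",
                                n_skipped_multiallelic = 0L,
                                n_rsq_capped = 0L, n_ds_clipped = 0L) {
  stopifnot(nrow(variants) == nrow(gt), length(samples) == ncol(gt),
            all(dim(ds) == dim(gt)))
  if (!is.null(gp)) {
    stopifnot(is.list(gp), length(gp) == 3L,
              all(vapply(gp, function(m) all(dim(m) == dim(gt)), logical(1))))
    names(gp) <- c("p0", "p1", "p2")
  }
  for (m in c(list(gt, ds), gp)) rownames(m) <- NULL
  colnames(gt) <- samples; colnames(ds) <- samples
  structure(
    list(variants = as_tibble(variants), gt = gt, ds = ds, gp = gp,
         samples = samples, dialect = dialect,
         n_skipped_multiallelic = as.integer(n_skipped_multiallelic),
         n_rsq_capped = as.integer(n_rsq_capped),
         n_ds_clipped = as.integer(n_ds_clipped)),
    class = "imputed_callset"
  )
}

#' @export
print.truth_matrix <- function(x, ...) {
  cat("<truth_matrix> ", nrow(x$variants), " variants x ", length(x$samples),
      " samples\n", sep = "")
  cat("  regions: ", paste(names(table(x$variants$region)),
                           table(x$variants$region), collapse = ", "), "\n")
  if (x$n_skipped_multiallelic > 0)
    cat("  multi-allelic records skipped:", x$n_skipped_multiallelic, "\n")
  invisible(x)
}

#' @export
print.imputed_callset <- function(x, ...) {
  cat("<imputed_callset> ", nrow(x$variants), " variants x ", length(x$samples),
      " samples; dialect ", x$dialect,
      if (is.null(x$gp)) "; no GP" else "; with GP", "\n", sep = "")
  invisible(x)
}

# dialect -> conventional per-variant quality INFO tag
dialect_info_key <- function(dialect, info_key = NULL) {
  switch(dialect,
    beagle_dr2  = info_key %||% "DR2",
    minimac_r2  = info_key %||% "R2",
    impute_info = info_key %||% "INFO",
    custom = {
      if (is.null(info_key)) abort("dialect \"custom\" requires `info_key`.")
      info_key
    },
    abort(sprintf("Unknown dialect \"%s\".", dialect))
  )
}

# "0/1", "0|1", "./." ... -> alt-allele count or NA
decode_gt_strings <- function(m) {
  dm <- dim(m)
  v <- gsub("|", "/", as.character(m), fixed = TRUE)
  out <- rep(NA_integer_, length(v))
  out[v %in% "0/0"] <- 0L
  out[v %in% c("0/1", "1/0")] <- 1L
  out[v %in% "1/1"] <- 2L
  # haploid calls (e.g. "0", "1") count the single allele
  out[v %in% "0"] <- 0L
  out[v %in% "1"] <- 1L
  matrix(out, nrow = dm[1], ncol = dm[2])
}

biallelic_mask <- function(fix) {
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  !is.na(alt) & !grepl(",", alt, fixed = TRUE) & !is.na(ref) &
    grepl("^[ACGTacgt]+$", ref) & grepl("^[ACGTacgt]+$", alt)
}

check_chrom_labels <- function(chrom, config) {
  if (!config$strict) return(invisible())
  known <- chrom %in% config$x_chrom | grepl("^(chr)?[0-9]+$", chrom)
  if (!all(known)) {
    abort(sprintf("Unknown chromosome label(s) in strict mode: %s",
                  paste(unique(chrom[!known]), collapse = ", ")))
  }
}

#' Read a truth (sequenced) call set from VCF
#'
#' Reads a VCF with per-sample GT calls, retains biallelic SNP/INDEL records,
#' decodes genotypes to alternate-allele counts (0/1/2, `NA` for missing) and
#' classifies each variant into `AUTOSOME`/`NONPAR`/`PAR`. Multi-allelic
#' records are skipped and counted.
#'
#' Reference-population allele frequency is taken from the `AF` INFO field
#' and minor allele count from `MAC` when present; otherwise both are
#' computed from the sample genotypes in the file.
#'
#' @param path Path to a VCF (plain or bgzipped).
#' @param config A [region_config()]; `strict = TRUE` errors on chromosome
#'   labels that are neither X labels nor numeric autosome labels.
#' @return A `truth_matrix` object.
#' @export
read_truth_vcf <- function(path, config = region_config()) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (ncol(vcf@gt) < 2 || nrow(vcf@gt) == 0 ||
      !grepl("(^|:)GT(:|$)", vcf@gt[1, "FORMAT"])) {
    abort("Truth VCF must carry a GT FORMAT field.")
  }
  keep <- biallelic_mask(vcf@fix)
  n_skip <- sum(!keep)
  vcf <- vcf[keep, ]
  fix <- vcf@fix
  chrom <- fix[, "CHROM"]
  check_chrom_labels(chrom, config)
  pos <- as.integer(fix[, "POS"])
  ref <- toupper(fix[, "REF"]); alt <- toupper(fix[, "ALT"])
  g <- decode_gt_strings(vcfR::extract.gt(vcf, element = "GT"))
  samples <- colnames(vcf@gt)[-1]

  af <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = "AF")))
  mac <- suppressWarnings(as.integer(vcfR::extract.info(vcf, element = "MAC")))
  n_called <- rowSums(!is.na(g))
  alt_count <- rowSums(g, na.rm = TRUE)
  p_obs <- ifelse(n_called > 0, alt_count / (2 * n_called), NA_real_)
  p <- ifelse(is.na(af), p_obs, af)
  maf_ref <- pmin(p, 1 - p)
  mac_obs <- pmin(alt_count, 2 * n_called - alt_count)
  mac_ref <- ifelse(is.na(mac), mac_obs, mac)

  variants <- tibble(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    vclass = variant_class(ref, alt),
    region = classify_region(chrom, pos, config),
    maf_ref = maf_ref, mac_ref = as.integer(mac_ref)
  )
  if (n_skip > 0)
    inform(sprintf("Skipped %d non-biallelic record(s).", n_skip))
  new_truth_matrix(variants, g, samples, n_skip)
}

#' Read an imputed call set from VCF
#'
#' Reads best-guess genotypes (GT), dosages (DS, the expected alternate
#' allele count in \[0, 2\]) and optional genotype posteriors (GP) plus the
#' per-variant software quality score from the INFO field named by the
#' dialect: `DR2` (Beagle), `R2` (Minimac), `INFO` (IMPUTE), or a custom key.
#'
#' When DS is absent but GP is present, dosage is computed as `p1 + 2*p2`.
#' Dosages outside \[0, 2\] are clipped with a warning; quality scores above
#' 1 (possible for MACH-style estimates) are capped at 1 with a counter.
#'
#' @param path Path to a VCF with GT and DS and/or GP FORMAT fields.
#' @param dialect One of `"beagle_dr2"`, `"minimac_r2"`, `"impute_info"`,
#'   `"custom"`.
#' @param info_key Override for the quality INFO tag (required for
#'   `"custom"`).
#' @return An `imputed_callset` object.
#' @export
read_imputed_vcf <- function(path, dialect = c("beagle_dr2", "minimac_r2",
                                               "impute_info", "custom"),
                             info_key = NULL) {
  dialect <- match.arg(dialect)
  key <- dialect_info_key(dialect, info_key)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fmt <- vcf@gt[1, "FORMAT"]
  if (!grepl("(^|:)GT(:|$)", fmt)) abort("Imputed VCF must carry a GT FORMAT field.")
  has_ds <- grepl("(^|:)DS(:|$)", fmt)
  has_gp <- grepl("(^|:)GP(:|$)", fmt)
  if (!has_ds && !has_gp)
    abort("Imputed VCF must carry DS or GP FORMAT fields; neither found.")

  keep <- biallelic_mask(vcf@fix)
  n_skip <- sum(!keep)
  vcf <- vcf[keep, ]
  fix <- vcf@fix
  ref <- toupper(fix[, "REF"]); alt <- toupper(fix[, "ALT"])
  samples <- colnames(vcf@gt)[-1]
  gt <- decode_gt_strings(vcfR::extract.gt(vcf, element = "GT"))

  gp <- NULL
  if (has_gp) {
    gp_str <- vcfR::extract.gt(vcf, element = "GP")
    parts <- strsplit(as.character(gp_str), ",", fixed = TRUE)
    pm <- vapply(parts, function(x) {
      if (length(x) == 3L) as.numeric(x) else rep(NA_real_, 3)
    }, numeric(3))
    gp <- list(p0 = matrix(pm[1, ], nrow(gt)), p1 = matrix(pm[2, ], nrow(gt)),
               p2 = matrix(pm[3, ], nrow(gt)))
  }
  if (has_ds) {
    ds <- matrix(suppressWarnings(
      as.numeric(vcfR::extract.gt(vcf, element = "DS"))), nrow(gt))
  } else {
    ds <- gp$p1 + 2 * gp$p2
  }
  n_clip <- sum(ds < 0 | ds > 2, na.rm = TRUE)
  if (n_clip > 0) {
    warn(sprintf("%d dosage value(s) outside [0, 2] clipped.", n_clip))
    ds <- pmin(pmax(ds, 0), 2)
  }

  rsq_raw <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = key)))
  if (all(is.na(rsq_raw)))
    abort(sprintf("Quality INFO field \"%s\" absent from VCF.", key))
  n_cap <- sum(rsq_raw > 1, na.rm = TRUE)
  rsq_soft <- pmin(pmax(rsq_raw, 0), 1)

  variants <- tibble(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = ref, alt = alt, vclass = variant_class(ref, alt),
    rsq_soft = rsq_soft
  )
  new_imputed_callset(variants, gt, ds, gp, samples, dialect,
                      n_skip, n_cap, n_clip)
}

variant_key_chr <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}

#' Align a truth and an imputed call set
#'
#' Matches variants on exact (chrom, pos, ref, alt) identity after allele
#' upper-casing (no indel left-alignment is attempted) and intersects and
#' reorders samples identically in both sets. Unmatched truth records whose
#' (chrom, pos) exists in the imputed set with different alleles are counted
#' as allele mismatches.
#'
#' @param truth A `truth_matrix`.
#' @param imputed An `imputed_callset`.
#' @return A list with elements `truth`, `imputed` (aligned, same variant and
#'   sample order) and `report` (one-row tibble of match counts).
#' @export
match_variants <- function(truth, imputed) {
  stopifnot(inherits(truth, "truth_matrix"), inherits(imputed, "imputed_callset"))
  samples <- intersect(truth$samples, imputed$samples)
  if (length(samples) == 0) abort("No overlapping samples between call sets.")

  kt <- variant_key_chr(truth$variants)
  ki <- variant_key_chr(imputed$variants)
  it <- match(kt, ki)
  matched_t <- which(!is.na(it))
  if (length(matched_t) == 0) abort("No overlapping variants between call sets.")
  matched_i <- it[matched_t]

  pt <- paste(truth$variants$chrom, truth$variants$pos, sep = ":")
  pi <- paste(imputed$variants$chrom, imputed$variants$pos, sep = ":")
  unm_t <- setdiff(seq_along(kt), matched_t)
  unm_i <- setdiff(seq_along(ki), matched_i)
  n_mismatch <- sum(pt[unm_t] %in% pi[unm_i])

  report <- tibble(
    n_truth = length(kt), n_imputed = length(ki),
    n_matched = length(matched_t),
    n_truth_only = length(unm_t), n_imputed_only = length(unm_i),
    n_allele_mismatch = n_mismatch, n_samples = length(samples)
  )

  st <- match(samples, truth$samples)
  si <- match(samples, imputed$samples)
  truth_al <- new_truth_matrix(
    truth$variants[matched_t, ],
    truth$g[matched_t, st, drop = FALSE], samples,
    truth$n_skipped_multiallelic)
  gp <- imputed$gp
  if (!is.null(gp))
    gp <- lapply(gp, function(m) m[matched_i, si, drop = FALSE])
  imputed_al <- new_imputed_callset(
    imputed$variants[matched_i, ],
    imputed$gt[matched_i, si, drop = FALSE],
    imputed$ds[matched_i, si, drop = FALSE],
    gp, samples, imputed$dialect,
    imputed$n_skipped_multiallelic, imputed$n_rsq_capped, imputed$n_ds_clipped)
  list(truth = truth_al, imputed = imputed_al, report = report)
}

stats_table_columns <- c(
  "chrom", "pos", "ref", "alt", "region", "vclass", "maf_ref", "rsq_soft",
  "n_pairs", "r_gt", "r_ds", "rsq_emp_gt", "rsq_emp_ds", "concordance",
  "fpr", "fnr", "aer", "est_gt", "est_ds"
)

#' Write / read a per-variant statistics table
#'
#' Tab-separated, one row per variant, fixed column order, `NA` for
#' non-estimable values. `read_stats_table()` restores the column types so a
#' write/read round trip reproduces the values.
#'
#' @param stats A per-variant statistics tibble from [per_variant_stats()].
#' @param path Output file path.
#' @return `write_stats_table()` returns `path` invisibly;
#'   `read_stats_table()` returns a tibble.
#' @export
write_stats_table <- function(stats, path) {
  missing_cols <- setdiff(stats_table_columns, names(stats))
  if (length(missing_cols))
    abort(paste("Stats table lacks columns:", paste(missing_cols, collapse = ", ")))
  readr::write_tsv(stats[, stats_table_columns], path, na = "NA")
  invisible(path)
}

#' @rdname write_stats_table
#' @export
read_stats_table <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      chrom = readr::col_character(), pos = readr::col_integer(),
      ref = readr::col_character(), alt = readr::col_character(),
      region = readr::col_character(), vclass = readr::col_character(),
      n_pairs = readr::col_integer(),
      est_gt = readr::col_logical(), est_ds = readr::col_logical(),
      .default = readr::col_double()
    ),
    na = "NA", progress = FALSE
  )
}
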