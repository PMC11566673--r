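#' Default simulated genome layout
#'
#' One 50 Mb autosome containing a high-error "hotspot" span (emulating a
#' segmental-duplication region with error-prone alignment) and a 0.5 Mb
#' span reserved for excess-heterozygosity injection, plus the distal part
#' of an X chromosome spanning the non-PAR/PAR boundary with elevated error
#' in the PAR.
#'
#' @param par_boundary PAR boundary position (bp) on the X chromosome.
#' @return Tibble with `chrom`, `start`, `end` (half-open span, bp),
#'   `class`, `error_mult`, `label`.
#' @export
default_regions <- function(par_boundary = 133300518) {
  tibble(
    chrom = c("1", "1", "1", "1", "1", "X", "X"),
    start = c(0, 20e6, 24e6, 40e6, 40.5e6, 120e6, par_boundary),
    end   = c(20e6, 24e6, 40e6, 40.5e6, 50e6, par_boundary, 139e6),
    class = c(rep("AUTOSOME", 5), "NONPAR", "PAR"),
    error_mult = c(1, 4, 1, 1, 1, 1, 3),
    label = c("autosome", "hotspot", "autosome", "het_excess", "autosome",
              "nonpar", "par")
  )
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic truth/imputed generator. The
#' defaults emulate the structure the accuracy pipeline assumes: 70 diploid
#' target samples, a skewed minor-allele-frequency spectrum with
#' MAC-filterable rare variants, ~7% INDELs, and an error intensity that
#' rises at low MAF, in the PAR and in a localized hotspot.
#'
#' @param seed Integer seed; fully determines the simulated data.
#' @param n_ref_hap Number of reference-panel haplotypes used to realise
#'   per-variant reference allele frequencies.
#' @param n_target Number of diploid target samples (default 70).
#' @param n_variants Number of variants.
#' @param indel_fraction Fraction of variants simulated as INDELs.
#' @param maf_spectrum Either `list(type = "one_over_p")` (density
#'   proportional to 1/p, truncated so the reference MAC is at least 1) or
#'   `list(type = "beta", shape1 =, shape2 =)` drawing the alternate allele
#'   frequency from a Beta distribution.
#' @param regions Region layout tibble, see [default_regions()].
#' @param error_model `list(type = "posterior", lambda, maf_c0,
#'   maf_exponent, jitter, prior_noise)`: per-variant error intensity
#'   `lambda_v = lambda * ((0.5 + maf_c0)/(maf_ref + maf_c0))^maf_exponent *
#'   region_mult * jitter_v` with `jitter_v ~ U(jitter[1], jitter[2])`;
#'   `prior_noise` is the Dirichlet concentration of the error-cell
#'   posterior around the Hardy-Weinberg prior. Or `list(type =
#'   "allele_flip", epsilon)`: each allele is independently mis-imputed
#'   with probability `epsilon`.
#' @param score_model `list(estimator, gamma)`: which quality score
#'   populates `rsq_soft` (`"dr2"`, `"mach"`, `"info"`, or `"oracle"` which
#'   uses the realised DS-mode empirical Rsq) and the miscalibration
#'   exponent `gamma` applied as `score^gamma` (`gamma > 1` deflates the
#'   score, Minimac-like; `gamma < 1` inflates it, Beagle/IMPUTE-like).
#' @param profile `"default"`, or `"calibration"`: a single uniform-error
#'   autosome with a wide spread of error intensities and a common-variant
#'   spectrum, used to study score calibration over the full \[0, 1\] score
#'   range.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_ref_hap = 400,
                       n_target = 70,
                       n_variants = 5000,
                       indel_fraction = 0.07,
                       maf_spectrum = list(type = "one_over_p"),
                       regions = default_regions(),
                       error_model = list(type = "posterior", lambda = 0.025,
                                          maf_c0 = 0.1, maf_exponent = 1,
                                          jitter = c(0.3, 1.5),
                                          prior_noise = 300),
                       score_model = list(estimator = "dr2", gamma = 1),
                       profile = c("default", "calibration")) {
  profile <- match.arg(profile)
  if (profile == "calibration") {
    if (missing(regions))
      regions <- tibble(chrom = "1", start = 0, end = 100e6,
                        class = "AUTOSOME", error_mult = 1,
                        label = "autosome")
    if (missing(maf_spectrum))
      maf_spectrum <- list(type = "beta", shape1 = 2, shape2 = 2)
    if (missing(error_model))
      error_model <- list(type = "posterior", lambda = 0.5, maf_c0 = 0.1,
                          maf_exponent = 0, jitter = c(0.02, 1.9),
                          prior_noise = 300)
  }
  stopifnot(length(seed) == 1, n_target >= 2, n_variants >= 1,
            indel_fraction >= 0, indel_fraction <= 1, n_ref_hap >= 2)
  if (any(regions$end <= regions$start)) abort("Region spans must be non-empty.")
  by_chr <- split(regions, regions$chrom)
  for (rr in by_chr) {
    rr <- rr[order(rr$start), ]
    if (nrow(rr) > 1 && any(rr$start[-1] < rr$end[-nrow(rr)]))
      abort("Region spans overlap within a chromosome.")
  }
  error_model$type <- error_model$type %||% "posterior"
  score_model$estimator <- match.arg(score_model$estimator,
                                     c("dr2", "mach", "info", "oracle"))
  score_model$gamma <- score_model$gamma %||% 1
  structure(
    list(seed = as.integer(seed), n_ref_hap = n_ref_hap, n_target = n_target,
         n_variants = n_variants, indel_fraction = indel_fraction,
         maf_spectrum = maf_spectrum, regions = regions,
         error_model = error_model, score_model = score_model,
         profile = profile),
    class = "sim_config"
  )
}

draw_alt_freq <- function(n, spectrum, n_ref_hap) {
  if (spectrum$type == "one_over_p") {
    mmin <- 1 / n_ref_hap
    maf <- mmin * (0.5 / mmin)^runif(n)
    flip <- runif(n) < 0.5
    ifelse(flip, 1 - maf, maf)
  } else if (spectrum$type == "beta") {
    stats::rbeta(n, spectrum$shape1, spectrum$shape2)
  } else {
    abort(sprintf("Unknown maf_spectrum type \"%s\".", spectrum$type))
  }
}

BASES <- c("A", "C", "G", "T")

draw_alleles <- function(n, is_indel) {
  ref <- sample(BASES, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1), character(1))
  if (any(is_indel)) {
    k <- sum(is_indel)
    ins <- runif(k) < 0.5
    ext <- vapply(sample.int(3, k, replace = TRUE), function(m)
      paste(sample(BASES, m, replace = TRUE), collapse = ""), character(1))
    ref_i <- ref[is_indel]; alt_i <- ref_i
    alt_i[ins] <- paste0(ref_i[ins], ext[ins])
    ref_i[!ins] <- paste0(ref_i[!ins], ext[!ins])
    ref[is_indel] <- ref_i
    alt[is_indel] <- alt_i
  }
  list(ref = ref, alt = alt)
}

#' Simulate a truth call set
#'
#' Draws a biallelic variant panel over the configured region layout:
#' per-variant alternate allele frequencies from the MAF spectrum, a
#' reference-panel realisation of `n_ref_hap` haplotypes (truncated so at
#' least one copy of each allele is present) giving `maf_ref`/`mac_ref`,
#' and diploid target genotypes drawn at the realised reference frequency.
#' Positions are uniform (without replacement) within each region span and
#' variants are returned sorted by chromosome and position. Deterministic
#' under `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A `truth_matrix` whose `variants` tibble additionally carries
#'   `label` (region label) and `p_ref` (reference alternate allele
#'   frequency).
#' @export
simulate_truth <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  V <- cfg$n_variants; N <- cfg$n_target
  reg <- cfg$regions
  span <- reg$end - reg$start
  ridx <- sample.int(nrow(reg), V, replace = TRUE, prob = span)
  counts <- tabulate(ridx, nbins = nrow(reg))
  pos <- integer(V)
  for (j in seq_len(nrow(reg))) {
    if (counts[j] == 0) next
    if (counts[j] > span[j]) abort("More variants than positions in a span.")
    pos[ridx == j] <- reg$start[j] + sample.int(span[j], counts[j])
  }
  chrom <- reg$chrom[ridx]

  is_indel <- runif(V) < cfg$indel_fraction
  al <- draw_alleles(V, is_indel)

  p <- draw_alt_freq(V, cfg$maf_spectrum, cfg$n_ref_hap)
  k <- rbinom(V, cfg$n_ref_hap, p)
  k <- pmin(pmax(k, 1L), cfg$n_ref_hap - 1L)   # MAC >= 1 in the panel
  p_ref <- k / cfg$n_ref_hap
  g <- matrix(rbinom(V * N, 2, p_ref), nrow = V, ncol = N)

  rcfg <- region_config()
  variants <- tibble(
    chrom = chrom, pos = pos, ref = al$ref, alt = al$alt,
    vclass = variant_class(al$ref, al$alt),
    region = classify_region(chrom, pos, rcfg),
    maf_ref = pmin(p_ref, 1 - p_ref),
    mac_ref = as.integer(pmin(k, cfg$n_ref_hap - k)),
    label = reg$label[ridx], p_ref = p_ref
  )
  ord <- order(variants$chrom, variants$pos)
  samples <- sprintf("S%03d", seq_len(N))
  new_truth_matrix(variants[ord, ], g[ord, , drop = FALSE], samples)
}

lambda_per_variant <- function(truth, cfg) {
  em <- cfg$error_model
  maf <- truth$variants$maf_ref
  term <- ((0.5 + em$maf_c0) / (maf + em$maf_c0))^em$maf_exponent
  mult <- cfg$regions$error_mult[match(truth$variants$label, cfg$regions$label)]
  mult[is.na(mult)] <- 1
  jit <- runif(nrow(truth$variants), em$jitter[1], em$jitter[2])
  lam <- em$lambda * term * mult * jit
  if (any(lam < 0 | lam > 1))
    abort(sprintf(
      "Error intensity outside [0, 1] after multipliers (max %.3f).", max(lam)))
  lam
}

#' Simulate an imputed call set from a truth set
#'
#' Under the posterior error model, each (variant, sample) cell is either
#' "known" (probability `1 - lambda_v`), giving a degenerate posterior at
#' the true genotype, or "uninformed" (probability `lambda_v`), giving the
#' Hardy-Weinberg prior at the reference alternate allele frequency with
#' small Dirichlet sampling noise. Averaged over cells the posterior is the
#' blend `(1 - lambda_v) * delta(truth) + lambda_v * HWE`, and the truth is
#' distributed according to the posterior up to the noise term, i.e. the
#' posteriors are calibrated. Best-guess genotypes are the posterior
#' argmax (ties broken toward the lower genotype), dosage is `p1 + 2*p2`,
#' and `rsq_soft` is computed from the simulated posteriors by the
#' configured estimator, then transformed by `score^gamma`.
#'
#' Under the allele-flip model each of the two alleles of every cell is
#' independently mis-imputed with probability `epsilon`; posteriors are
#' degenerate at the (possibly wrong) called genotype.
#'
#' @param truth A `truth_matrix` from [simulate_truth()].
#' @param cfg The same [sim_config()].
#' @return An `imputed_callset` with GT, DS, GP and per-variant `rsq_soft`;
#'   the per-variant error intensity is attached as attribute `lambda`.
#' @export
simulate_imputation <- function(truth, cfg) {
  stopifnot(inherits(truth, "truth_matrix"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1000003L)
  V <- nrow(truth$g); N <- ncol(truth$g)
  z <- truth$g
  p_ref <- truth$variants$p_ref
  if (is.null(p_ref)) p_ref <- rowSums(z) / (2 * N)
  em <- cfg$error_model

  if (em$type == "posterior") {
    lam <- lambda_per_variant(truth, cfg)
    E <- matrix(runif(V * N) < lam, nrow = V)   # lam recycles down columns
    P0 <- (z == 0) + 0; P1 <- (z == 1) + 0; P2 <- (z == 2) + 0
    err <- which(E)
    if (length(err)) {
      row <- ((err - 1L) %% V) + 1L
      pe <- p_ref[row]
      c0 <- em$prior_noise %||% 300
      g0 <- rgamma(length(err), shape = c0 * (1 - pe)^2)
      g1 <- rgamma(length(err), shape = c0 * 2 * pe * (1 - pe))
      g2 <- rgamma(length(err), shape = c0 * pe^2)
      s <- g0 + g1 + g2 + 1e-300
      P0[err] <- g0 / s; P1[err] <- g1 / s; P2[err] <- g2 / s
    }
  } else if (em$type == "allele_flip") {
    eps <- em$epsilon
    lam <- rep(eps, V)
    down <- matrix(rbinom(V * N, as.vector(z), eps), nrow = V)
    up <- matrix(rbinom(V * N, as.vector(2L - z), eps), nrow = V)
    gt_flip <- z - down + up
    P0 <- (gt_flip == 0) + 0; P1 <- (gt_flip == 1) + 0; P2 <- (gt_flip == 2) + 0
    E <- NULL
  } else {
    abort(sprintf("Unknown error model type \"%s\".", em$type))
  }

  gt <- matrix(ifelse(P0 >= pmax(P1, P2), 0L, ifelse(P1 >= P2, 1L, 2L)),
               nrow = V)
  ds <- P1 + 2 * P2

  est <- cfg$score_model$estimator
  if (est == "dr2") {
    score <- dr2_rows(P1, P2)
  } else if (est == "info") {
    score <- info_rows(P1, P2)
  } else if (est == "mach") {
    if (em$type == "posterior") {
      # haplotype dosages: true alleles where known, p_ref where uninformed
      A1 <- (z >= 1) + 0; A2 <- (z == 2) + 0
      if (!is.null(E)) {
        pe_m <- matrix(p_ref, nrow = V, ncol = N)
        A1[E] <- pe_m[E]; A2[E] <- pe_m[E]
      }
      score <- mach_rows(cbind(A1, A2))$value
    } else {
      score <- mach_rows(cbind(pmin(ds / 2, 1), pmin(ds / 2, 1)))$value
    }
  } else {  # oracle: the realised DS-mode empirical Rsq
    mask <- matrix(TRUE, V, N)
    score <- row_pearson(z, ds, mask)$r^2
  }
  gamma <- cfg$score_model$gamma
  rsq_soft <- score^gamma

  dialect <- switch(est, dr2 = "beagle_dr2", mach = "minimac_r2",
                    info = "impute_info", oracle = "custom")
  variants <- dplyr::mutate(
    truth$variants[, c("chrom", "pos", "ref", "alt", "vclass")],
    rsq_soft = rsq_soft)
  out <- new_imputed_callset(variants, gt, ds,
                             list(p0 = P0, p1 = P1, p2 = P2),
                             truth$samples, dialect)
  attr(out, "lambda") <- lam
  out
}

#' Inject an excess-heterozygosity artefact into a truth set
#'
#' Resamples the genotypes of a fraction of the variants inside a span so
#' their observed heterozygosity exceeds 0.55, emulating the false
#' heterozygous calls produced by collapsed segmental duplications. Used to
#' exercise the excess-heterozygosity window filter.
#'
#' @param truth A `truth_matrix`.
#' @param chrom,start,end Span (half-open, bp) to perturb.
#' @param excess_rate Fraction of the span's variants to perturb (rounded
#'   to a count).
#' @param target_het Heterozygote fraction given to perturbed variants
#'   (must exceed 0.55).
#' @return The modified `truth_matrix`.
#' @export
inject_het_excess <- function(truth, chrom = "1", start = 40e6, end = 40.5e6,
                              excess_rate = 0.03, target_het = 0.8) {
  stopifnot(inherits(truth, "truth_matrix"))
  if (target_het <= 0.55) abort("`target_het` must exceed 0.55.")
  inspan <- which(truth$variants$chrom == chrom & truth$variants$pos >= start &
                    truth$variants$pos < end)
  if (length(inspan) == 0) abort("No variants in the requested span.")
  n_pert <- round(excess_rate * length(inspan))
  if (n_pert == 0) return(truth)
  pick <- sample(inspan, n_pert)
  N <- ncol(truth$g)
  h <- round(target_het * N)
  for (v in pick) {
    gv <- integer(N)
    het_idx <- sample.int(N, h)
    gv[het_idx] <- 1L
    gv[-het_idx] <- 2L * rbinom(N - h, 1, 0.5)
    truth$g[v, ] <- gv
  }
  truth
}

format_num <- function(x, digits = 8) {
  ifelse(is.na(x), ".", formatC(x, digits = digits, format = "f"))
}

gt_string <- function(g) {
  out <- rep("./.", length(g))
  out[!is.na(g) & g == 0] <- "0/0"
  out[!is.na(g) & g == 1] <- "0/1"
  out[!is.na(g) & g == 2] <- "1/1"
  out
}

write_vcf_lines <- function(path, header_extra, variants, samples, body) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    header_extra,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  ), con)
  writeLines(body, con)
  invisible(path)
}

#' Write a simulated truth/imputed pair as VCF plus manifest
#'
#' Writes `truth.vcf` (GT FORMAT; `AF` and `MAC` INFO fields carrying the
#' reference-panel frequency), `imputed.vcf` (GT, DS, GP FORMAT; per-variant
#' quality INFO tag named by the call set's dialect) and a JSON manifest
#' recording the configuration and seed. Both files round-trip through
#' [read_truth_vcf()] / [read_imputed_vcf()].
#'
#' @param truth A `truth_matrix`.
#' @param imputed The matching `imputed_callset`.
#' @param out_dir Output directory (created if needed).
#' @param cfg Optional [sim_config()] recorded in the manifest.
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_simulation <- function(truth, imputed, out_dir, cfg = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(sprintf("Cannot create \"%s\".", out_dir))
  tv <- truth$variants
  truth_path <- file.path(out_dir, "truth.vcf")
  gt_mat <- matrix(gt_string(truth$g), nrow = nrow(truth$g))
  info <- sprintf("AF=%s;MAC=%d", format_num(tv$p_ref %||% (NA_real_)),
                  tv$mac_ref)
  body <- paste(tv$chrom, tv$pos, ".", tv$ref, tv$alt, ".", "PASS", info, "GT",
                apply(gt_mat, 1, paste, collapse = "\t"), sep = "\t")
  write_vcf_lines(truth_path, c(
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Reference panel alternate allele frequency\">",
    "##INFO=<ID=MAC,Number=1,Type=Integer,Description=\"Reference panel minor allele count\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
    tv, truth$samples, body)

  iv <- imputed$variants
  key <- if (imputed$dialect == "custom") "RSQ" else
    dialect_info_key(imputed$dialect)
  imp_path <- file.path(out_dir, "imputed.vcf")
  gt_mat <- matrix(gt_string(imputed$gt), nrow = nrow(imputed$gt))
  ds_mat <- matrix(format_num(imputed$ds), nrow = nrow(imputed$ds))
  cells <- paste0(gt_mat, ":", ds_mat)
  if (!is.null(imputed$gp)) {
    gp_mat <- matrix(paste(format_num(imputed$gp$p0), format_num(imputed$gp$p1),
                           format_num(imputed$gp$p2), sep = ","),
                     nrow = nrow(imputed$gt))
    cells <- paste0(cells, ":", gp_mat)
    fmt <- "GT:DS:GP"
  } else {
    fmt <- "GT:DS"
  }
  cells <- matrix(cells, nrow = nrow(imputed$gt))
  info <- sprintf("%s=%s", key, format_num(iv$rsq_soft, digits = 6))
  body <- paste(iv$chrom, iv$pos, ".", iv$ref, iv$alt, ".", "PASS", info, fmt,
                apply(cells, 1, paste, collapse = "\t"), sep = "\t")
  write_vcf_lines(imp_path, c(
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"Estimated imputation quality\">", key),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Best-guess genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Alternate allele dosage\">",
    "##FORMAT=<ID=GP,Number=G,Type=Float,Description=\"Genotype posterior\">"),
    iv, imputed$samples, body)

  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- list(
    package = "imputeval",
    seed = if (!is.null(cfg)) cfg$seed else NA,
    n_variants = nrow(tv), n_samples = length(truth$samples),
    dialect = imputed$dialect, quality_info_key = key,
    files = list(truth = basename(truth_path), imputed = basename(imp_path)),
    config = if (!is.null(cfg)) unclass(cfg) else NULL
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")
  invisible(c(truth = truth_path, imputed = imp_path,
              manifest = manifest_path))
}
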