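DENOM_TOL <- 1e-12

check_gp <- function(gp) {
  gp <- as.matrix(gp)
  if (ncol(gp) != 3) abort("`gp` must have three columns (p0, p1, p2).")
  if (nrow(gp) < 2) abort("At least 2 samples are required.")
  if (any(abs(rowSums(gp) - 1) > 1e-6))
    abort("Genotype posterior triples must sum to 1 (tolerance 1e-6).")
  if (any(gp < -1e-9)) abort("Genotype posteriors must be non-negative.")
  gp
}

#' Beagle-style dosage R2 (DR2)
#'
#' Estimates the squared correlation between imputed and true genotypes,
#' approximating the (co)variance of the unobserved true genotypes from the
#' imputed posteriors themselves. With per-sample expected dosage
#' `d_i = p1 + 2*p2` and expected squared dosage `e_i = p1 + 4*p2`,
#'
#' `DR2 = (sum(d^2) - (sum d)^2 / N) / (sum(e) - (sum d)^2 / N)`.
#'
#' A denominator at or below tolerance (monomorphic posteriors) returns 0 by
#' convention; the result is capped into \[0, 1\].
#'
#' @param gp N x 3 matrix (or data frame) of genotype posterior triples
#'   (p0, p1, p2), one row per sample.
#' @return DR2 value in \[0, 1\].
#' @examples
#' beagle_dr2(rbind(c(1, 0, 0), c(0, 0, 1)))  # degenerate, polymorphic -> 1
#' @export
beagle_dr2 <- function(gp) {
  gp <- check_gp(gp)
  d <- gp[, 2] + 2 * gp[, 3]
  e <- gp[, 2] + 4 * gp[, 3]
  n <- nrow(gp)
  centre <- sum(d)^2 / n
  den <- sum(e) - centre
  if (den <= DENOM_TOL) return(0)
  min(max((sum(d^2) - centre) / den, 0), 1)
}

#' MACH / Minimac-style imputation Rsq
#'
#' The average squared deviation of the imputed allele dosage at each
#' haplotype from the estimated allele frequency, divided by the binomial
#' variance of the allele frequency:
#'
#' `Rsq = mean((D_h - p)^2) / (p * (1 - p))`, with `p = mean(D_h)`.
#'
#' With haplotype-level allele dosages this is the ratio of observed to
#' expected dosage variance. When only diploid dosages are available
#' (`haploid = FALSE`), each individual contributes `d_i / 2` twice; note
#' that this fallback halves the ratio when the two haplotype errors are
#' independent. The raw value can exceed 1; both raw and capped values are
#' returned.
#'
#' @param dosages Haplotype allele dosages in \[0, 1\] (default), or diploid
#'   dosages in \[0, 2\] with `haploid = FALSE`.
#' @param haploid Whether `dosages` are per-haplotype values.
#' @return List with `raw` and `value` (capped into \[0, 1\]); `value` is 0
#'   when `p * (1 - p)` is at or below tolerance.
#' @examples
#' mach_rsq(c(1, 0.5, 0, 0.5))$value  # 0.5
#' @export
mach_rsq <- function(dosages, haploid = TRUE) {
  if (!haploid) dosages <- rep(dosages / 2, each = 2)
  h <- length(dosages)
  if (h < 2) abort("At least 2 haplotype dosages are required.")
  if (any(dosages < -1e-9 | dosages > 1 + 1e-9))
    abort("Haplotype dosages must lie in [0, 1].")
  p <- mean(dosages)
  den <- p * (1 - p)
  if (den <= DENOM_TOL) return(list(raw = 0, value = 0))
  raw <- mean((dosages - p)^2) / den
  list(raw = raw, value = min(max(raw, 0), 1))
}

#' IMPUTE-style INFO score
#'
#' The ratio of observed to complete statistical information about the
#' population allele frequency. With `d_i`, `e_i` as in [beagle_dr2()] and
#' `p = sum(d_i) / (2N)`,
#'
#' `INFO = 1 - sum(e_i - d_i^2) / (2 * N * p * (1 - p))`.
#'
#' When `p * (1 - p)` is at or below tolerance the score is 1 if all
#' posteriors are degenerate (a confidently monomorphic variant carries all
#' its — trivial — information) and 0 otherwise; the result is capped into
#' \[0, 1\].
#'
#' @inheritParams beagle_dr2
#' @return INFO value in \[0, 1\].
#' @export
impute_info <- function(gp) {
  gp <- check_gp(gp)
  d <- gp[, 2] + 2 * gp[, 3]
  e <- gp[, 2] + 4 * gp[, 3]
  n <- nrow(gp)
  p <- sum(d) / (2 * n)
  den <- 2 * n * p * (1 - p)
  cond_var <- sum(e - d^2)
  if (den <= DENOM_TOL) return(if (cond_var <= 1e-9) 1 else 0)
  min(max(1 - cond_var / den, 0), 1)
}

# ---- vectorised forms used by the simulator (variants x samples matrices) --

dr2_rows <- function(P1, P2) {
  d <- P1 + 2 * P2
  e <- P1 + 4 * P2
  n <- ncol(P1)
  centre <- rowSums(d)^2 / n
  den <- rowSums(e) - centre
  num <- rowSums(d * d) - centre
  out <- ifelse(den > DENOM_TOL, num / den, 0)
  pmin(pmax(out, 0), 1)
}

info_rows <- function(P1, P2) {
  d <- P1 + 2 * P2
  e <- P1 + 4 * P2
  n <- ncol(P1)
  p <- rowSums(d) / (2 * n)
  den <- 2 * n * p * (1 - p)
  cond_var <- rowSums(e - d * d)
  out <- ifelse(den > DENOM_TOL, 1 - cond_var / den,
                ifelse(cond_var <= 1e-9, 1, 0))
  pmin(pmax(out, 0), 1)
}

# Dh: variants x (2 * n_samples) haplotype dosages
mach_rows <- function(Dh) {
  h <- ncol(Dh)
  p <- rowMeans(Dh)
  den <- p * (1 - p)
  msd <- rowMeans((Dh - p)^2)
  raw <- ifelse(den > DENOM_TOL, msd / den, 0)
  list(raw = raw, value = pmin(pmax(raw, 0), 1))
}
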