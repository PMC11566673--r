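#' Region configuration for chromosome classification
#'
#' Builds the configuration used to classify variants into `AUTOSOME`,
#' `NONPAR` (X-specific region) or `PAR` (pseudo-autosomal region). The X
#' chromosome recombines with Y only inside the PAR, which sits at the distal
#' end of the chromosome; imputation accuracy behaves very differently there,
#' so the two parts are tracked separately throughout the package.
#'
#' Positions at or below `par_boundary` on an X-labelled chromosome are
#' classified `NONPAR`; positions above it are `PAR`. The default boundary is
#' the cattle ARS-UCD1.2 coordinate 133,300,518 bp.
#'
#' @param par_boundary 1-based position (bp) of the non-PAR/PAR boundary on
#'   the X chromosome. Positions `<= par_boundary` are non-PAR.
#' @param x_chrom Character vector of chromosome labels treated as the X
#'   chromosome.
#' @param strict If `TRUE`, chromosome labels not matching `x_chrom` and not
#'   plausible autosome labels still classify as `AUTOSOME`; `strict` only
#'   controls whether unknown labels error in [read_truth_vcf()].
#'
#' @return A list of class `region_config`.
#' @examples
#' cfg <- region_config()
#' classify_region(c("1", "X", "X"), c(100, 133300518, 133300519), cfg)
#' @export
region_config <- function(par_boundary = 133300518,
                          x_chrom = c("X", "chrX"),
                          strict = FALSE) {
  if (!is.numeric(par_boundary) || length(par_boundary) != 1 || par_boundary < 1) {
    abort("`par_boundary` must be a single position >= 1.")
  }
  structure(
    list(par_boundary = as.numeric(par_boundary),
         x_chrom = as.character(x_chrom),
         strict = isTRUE(strict)),
    class = "region_config"
  )
}

#' Classify variants by chromosome region
#'
#' Total function assigning exactly one of `AUTOSOME`, `NONPAR`, `PAR` to
#' every variant. On X-labelled chromosomes, positions at or below the PAR
#' boundary are `NONPAR` and positions above it are `PAR`; all other
#' chromosomes are `AUTOSOME`.
#'
#' @param chrom Character vector of chromosome labels.
#' @param pos Integer vector of 1-based positions (bp), same length.
#' @param config A [region_config()].
#' @return Character vector in `{"AUTOSOME","NONPAR","PAR"}`.
#' @export
classify_region <- function(chrom, pos, config = region_config()) {
  stopifnot(inherits(config, "region_config"), length(chrom) == length(pos))
  out <- rep("AUTOSOME", length(chrom))
  on_x <- chrom %in% config$x_chrom
  out[on_x & pos <= config$par_boundary] <- "NONPAR"
  out[on_x & pos > config$par_boundary] <- "PAR"
  out
}

# SNP iff both alleles are single bases; anything else (length difference or
# multi-base on either side) is an INDEL for the purposes of accuracy grouping
variant_class <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNP", "INDEL")
}
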