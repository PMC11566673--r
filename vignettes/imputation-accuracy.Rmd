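---
title: "Evaluating and calibrating genotype imputation quality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating and calibrating genotype imputation quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imputeval)
```

## The statistical model

`imputeval` compares an imputed call set against a sequenced truth set for
the same samples. Truth genotypes are alternate-allele counts
$t_i \in \{0, 1, 2\}$; the imputed side provides best-guess genotypes
$g_i$ (GT), dosages $d_i = p_1 + 2 p_2 \in [0, 2]$ (DS), optionally the
posterior triple $(p_0, p_1, p_2)$ (GP), and a per-variant software quality
score `rsq_soft`.

**Empirical accuracy** is the per-variant Pearson correlation $r$ between
truth and imputed values across samples, squared to give `Rsq_emp`. The
estimability rule follows from the correlation itself: in GT mode the
variant must segregate in *both* truth and best-guess calls, otherwise one
variance is zero and $r$ does not exist; in DS mode truth segregation
suffices in principle, but a numerically constant dosage vector (variance
below $10^{-12}$ per sample) is also flagged non-estimable rather than
returned as 0/0. Cells with a missing value on either side are dropped
pairwise, per variant, and the retained pair count `n_pairs` is reported so
denominators stay explicit.

**Allele-level error rates** decompose the per-sample genotype difference:
$\mathrm{FP} = \sum_i \max(g_i - t_i, 0)$ alleles wrongly gained,
$\mathrm{FN} = \sum_i \max(t_i - g_i, 0)$ alleles wrongly lost. This is the
unique decomposition in which FP + FN equals the total number of wrongly
imputed alleles, so the three rates are consistent by construction:
FPR = FP over total reference alleles, FNR = FN over total alternate
alleles, AER = (FP + FN) over $2 n$. A rate whose truth denominator is zero
(e.g. FNR at a variant with no alternate alleles) is reported `NA`, never
0-filled. All "average percentage" statistics are computed per variant
across samples, matching the per-variant framing of the correlations;
cross-variant aggregation weights variants equally.

**Software scores.** The three scores are implemented in their standard
closed forms from the posterior summaries $d_i$ and
$e_i = p_1 + 4 p_2$ (the expected squared dosage):

* Beagle-style `DR2` $= \frac{\sum d_i^2 - (\sum d_i)^2/N}
  {\sum e_i - (\sum d_i)^2/N}$ — an estimate of the squared correlation
  with the unobserved truth in which the truth (co)variance is approximated
  from the imputed dosages themselves;
* MACH/Minimac-style `Rsq` $= \frac{\tfrac1H \sum_h (D_h - \hat p)^2}
  {\hat p (1 - \hat p)}$ over haplotype dosages, i.e. observed over
  expected dosage variance, with $\hat p$ the mean dosage over the whole
  input (chunk-level estimation is not modelled). The diploid fallback
  ($d_i/2$ contributed twice) is provided but halves the ratio when the two
  haplotype errors are independent, so haplotype-level input is preferred;
* IMPUTE-style `INFO` $= 1 - \frac{\sum_i (e_i - d_i^2)}
  {2 N \hat p (1 - \hat p)}$ — observed over complete information about the
  allele frequency.

Zero-denominator conventions are fixed and documented on each function:
monomorphic posteriors give `DR2 = 0` and MACH `Rsq = 0`; `INFO` is 1 for
confidently monomorphic (fully degenerate) posteriors and 0 otherwise. The
denominator tolerance is $10^{-12}$. Raw MACH values and any score read
from a VCF above 1 are capped into $[0, 1]$ with a counter, keeping the
calibration domain closed.

## Variant identity, regions and reference filters

Truth/imputed matching is exact on upper-cased (chrom, pos, ref, alt); no
indel left-normalisation is attempted, so inputs should be normalised
consistently upstream. Unmatched truth records sharing a position with an
unmatched imputed record are counted as allele mismatches in the match
report.

Every variant is classified into exactly one of `AUTOSOME`, `NONPAR`,
`PAR`. The X chromosome's pseudo-autosomal boundary defaults to
133,300,518 bp (cattle ARS-UCD1.2). The boundary side is a convention the
coordinate alone does not determine: positions at or below the boundary are
non-PAR, above it PAR, with both the coordinate and the X labels
configurable via `region_config()`.

The reference-panel QC chain is biallelic → MAC → heterozygosity excess, in
that order (the window percentages are therefore computed on
MAC-surviving variants). "Heterozygosity" is *observed* heterozygosity —
the fraction of heterozygous calls — rather than expected $2pq$, because
the filter targets collapsed-repeat artefacts that manifest directly in the
calls. Thresholds are read literally: a window is flagged when at least 2%
of its variants exceed 0.55, and only variants strictly above 0.55 are
removed, so a variant at exactly 0.55 always survives. The window step
defaults to the window width (adjacent tiling), which makes the filter
idempotent; with a smaller step the removal is the union over flagged
windows and each variant is removed at most once. The MAC cut is inclusive
(`MAC >= 4` keeps a variant with exactly 4 minor copies).

## Score calibration and equivalent thresholds

`build_curve()` bins variants on `rsq_soft` (default width 0.05, half-open
bins, last bin closed at 1) and summarises `Rsq_emp` per bin with count,
mean, median, quartiles and 1.5 × IQR whisker bounds. Variants with a
non-estimable `Rsq_emp` are excluded and counted.

`equivalent_threshold()` defines the software-equivalent cutoff as the
smallest bin lower edge from which *every* eligible bin upward has mean
`Rsq_emp` at or above the target (default 0.8). Bins with fewer than
`min_bin_n = 50` variants are excluded from the scan because sparsely
populated bins have unstable means. Because the target is not formalised
beyond the bin picture, a "cumulative" alternative — the smallest edge at
which the pooled mean over all retained variants meets the target — is
reported alongside; on heavily right-skewed score distributions the
cumulative variant is much more lenient, which is why the bin scan is the
canonical definition. "Pass" is `rsq_soft >= threshold` and "achieve" is
`rsq_emp >= target`; one inclusive convention is fixed throughout.
`threshold_confusion()` then reports true/false positives as percentages of
passing variants and false negatives as a percentage of non-passing
variants, overall and split by variant class × MAF group (common means
reference MAF strictly above 0.05).

MAF bin edges default to
$(0, .005, .01, .025, .05, .1, .2, .3, .4, .5)$ — a conventional
sequence-data binning including the 0.025 and 0.05 cut points used in the
two-group split — and are fully configurable; bins are half-open
$(\mathrm{lo}, \mathrm{hi}]$ with 0 folded into the first bin. Window
summaries use adjacent half-open windows at 0-based multiples of the window
size (default 1 Mb), reporting empty windows with $n = 0$ so chromosome
tracks show gaps honestly.

## The synthetic data generator

The simulator produces the *statistical* structure the pipeline consumes —
(GT, DS, GP, `rsq_soft`) plus truth — without modelling imputation HMMs:
the evaluation is agnostic to how posteriors arose.

**Truth.** Alternate allele frequencies come from the configured spectrum:
by default density $\propto 1/p$ on the folded frequency (a standard
neutral-like skew producing many rare variants), truncated so the realised
reference panel of `n_ref_hap = 400` haplotypes carries at least one copy
of each allele; a Beta alternative is available. Target genotypes for
`n_target = 70` diploid samples are binomial draws at the realised panel
frequency. About 7% of variants are INDELs (multi-base ref or alt), the
remainder SNPs. The default layout places variants on a 50 Mb autosome —
containing a 4 Mb high-error "hotspot" emulating a segmental-duplication
region, and a 0.5 Mb span reserved for heterozygosity-excess injection —
and on the distal X across the PAR boundary, with elevated error in the
PAR. Positions are uniform within spans; no linkage disequilibrium or
recombination map is modelled (the per-variant statistics do not use LD).

**Imputation error.** Each (variant, sample) cell is independently either
*known* — posterior degenerate at the truth — with probability
$1 - \lambda_v$, or *uninformed* — posterior equal to the Hardy–Weinberg
prior at the reference allele frequency, with small Dirichlet sampling
noise (concentration 300) — with probability $\lambda_v$. Averaged over
cells this is the blend
$(1-\lambda_v)\,\delta(t) + \lambda_v\,\mathrm{HWE}$, and the posteriors
are calibrated up to the $O(1/c)$ noise term: the truth is distributed
according to the stated posterior. Two consequences matter for testing:
mean `Rsq_emp` and the mean software scores both approximate
$1 - \lambda_v$, so score-vs-accuracy calibration is recoverable; and at
$\lambda = 1$ the dosage is independent of the truth, so mean $r$ is
centred on zero. The noise term exists precisely so that fully uninformed
cells still vary across samples — a noiseless prior would make the dosage
vector constant and $r$ non-estimable rather than null. Best-guess
genotypes are the posterior argmax with ties broken toward the lower
genotype (deterministic); a pure allele-flip error model (each allele
independently mis-imputed with probability $\epsilon$) is available for
allele-level error-rate checks.

**Error intensity.** $\lambda_v = \lambda \cdot
\left(\frac{0.5 + c_0}{\mathrm{maf} + c_0}\right)^{\kappa} \cdot
m_{\mathrm{region}} \cdot u_v$ with defaults $\lambda = 0.025$,
$c_0 = 0.1$, $\kappa = 1$ (so rare variants are up to 6× harder),
multipliers 1/3/4 for autosome/PAR/hotspot, and per-variant jitter
$u_v \sim U(0.3, 1.5)$. The jitter gives within-bin heterogeneity so that
score filtering can select good variants *inside* a MAF bin or region; the
defaults were chosen once so that $\lambda_v \le 0.9$ for every variant
(values outside $[0, 1]$ are an error, not clamped) while reproducing the
qualitative picture of low-MAF and hotspot degradation. The `calibration`
profile replaces this with a single uniform region, a common-variant Beta
spectrum and a wide jitter, spreading scores over the whole $[0, 1]$ range
for calibration studies. `rsq_soft` is produced by the configured
estimator (DR2, MACH on the simulator's haplotype-level dosages, INFO, or
an "oracle" score equal to the realised `Rsq_emp`) and then transformed
$s \mapsto s^\gamma$: $\gamma > 1$ deflates scores (Minimac-like
under-prediction at the top of the range), $\gamma < 1$ inflates them
(Beagle/IMPUTE-like over-prediction).

**What passing tests do and do not show.** The generator reproduces
calibrated-posterior structure, MAF- and region-dependent error, rare-MAC
variants and software-style score dialects; it does not reproduce LD,
relatedness, phasing or hemizygosity (X males are diploid here), genotyping
error in the truth, or the allele-frequency mismatch between reference and
target populations. Results on synthetic data therefore validate the
*statistics and their implementation*, not the field performance of any
imputation program.

## Problem sizes and numerical choices

The test suite and the acceptance script run at deliberately desk-friendly
sizes — 70 target samples throughout; 2,000–20,000 variants for error-rate
and filtering checks; 50,000–100,000 variant draws for calibration-curve
fidelity — which keep the full suite under a minute of compute while
leaving per-bin counts in the hundreds to thousands. Variance tolerance
$10^{-12}$ per sample decides estimability; denominator tolerance
$10^{-12}$ decides score conventions; stats tables serialise at full
precision and round-trip losslessly; simulated VCF floats are written at
6–8 decimals (recovered within $10^{-6}$). Determinism: every simulation
is fully determined by `sim_config(seed)`; truth and imputation use
distinct streams derived from it.

## Known limitations

* Matching is exact; un-normalised indel representations will not match.
* The observed-heterozygosity filter assumes a sample size large enough
  that binomial noise rarely crosses 0.55; with few samples and
  intermediate frequencies, sporadic background removals occur (visible in
  the package's own simulations at $N = 70$).
* The diploid MACH fallback systematically halves the variance ratio for
  independent haplotype errors; use haplotype dosages where available.
* Aggregated AER weights variants equally; allele-count weighting would
  emphasise common variants and is not implemented.
* GT-mode comparisons across software are only meaningful on the common
  estimable set, which `evaluate_imputation()` computes; single-software
  GT summaries on the full set are biased by each tool's monomorphic
  imputation behaviour.
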