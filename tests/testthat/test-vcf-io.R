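test_that("region classification follows the PAR boundary convention", {
  cfg <- region_config(par_boundary = 133300518)
  expect_equal(
    classify_region(c("1", "X", "X", "X"),
                    c(100, 133300518, 133300519, 1), cfg),
    c("AUTOSOME", "NONPAR", "PAR", "NONPAR"))
  # total function over arbitrary labels/positions
  set.seed(1)
  chrom <- sample(c("1", "5", "X", "25"), 200, replace = TRUE)
  pos <- sample.int(2e8, 200)
  r <- classify_region(chrom, pos, cfg)
  expect_true(all(r %in% c("AUTOSOME", "NONPAR", "PAR")))
  expect_length(r, 200)
})

test_that("truth VCF reading decodes genotypes and skips multi-allelics", {
  path <- write_mini_vcf(c(
    "1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/1\t1/1",
    "1\t200\t.\tA\tT,C\t.\tPASS\t.\tGT\t0/1\t1/2",
    "1\t300\t.\tAT\tA\t.\tPASS\t.\tGT\t0|0\t./."
  ))
  tr <- suppressMessages(read_truth_vcf(path))
  expect_equal(nrow(tr$variants), 2)
  expect_equal(tr$n_skipped_multiallelic, 1L)
  expect_equal(unname(tr$g[1, ]), c(1L, 2L))
  expect_equal(tr$variants$vclass, c("SNP", "INDEL"))
  expect_equal(tr$variants$region, c("AUTOSOME", "AUTOSOME"))
  expect_equal(unname(tr$g[2, ]), c(0L, NA_integer_))
})

test_that("truth VCF without GT errors", {
  path <- write_mini_vcf(
    "1\t100\t.\tA\tT\t.\tPASS\t.\tDP\t10\t12",
    format_defs = "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">")
  expect_error(read_truth_vcf(path), "GT")
})

test_that("strict mode rejects unknown chromosome labels", {
  path <- write_mini_vcf("weird_contig\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/1\t1/1")
  expect_error(read_truth_vcf(path, region_config(strict = TRUE)),
               "weird_contig")
  expect_silent(tr <- read_truth_vcf(path, region_config(strict = FALSE)))
  expect_equal(tr$variants$region, "AUTOSOME")
})

test_that("imputed VCF reading maps dialect quality fields", {
  fmt <- c("##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
           "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"d\">")
  info <- "##INFO=<ID=DR2,Number=1,Type=Float,Description=\"q\">"
  path <- write_mini_vcf(
    "1\t100\t.\tA\tT\t.\tPASS\tDR2=0.93\tGT:DS\t0/1:0.9\t1/1:1.8",
    format_defs = fmt, info_defs = info)
  im <- read_imputed_vcf(path, "beagle_dr2")
  expect_equal(im$variants$rsq_soft, 0.93)
  expect_equal(unname(im$ds[1, ]), c(0.9, 1.8))
  expect_equal(unname(im$gt[1, ]), c(1L, 2L))
  # wrong dialect key -> error naming the key
  expect_error(read_imputed_vcf(path, "minimac_r2"), "R2")
  expect_error(read_imputed_vcf(path, "custom"), "info_key")
})

test_that("dosage falls back to GP and out-of-range dosages are clipped", {
  fmt <- c("##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
           "##FORMAT=<ID=GP,Number=G,Type=Float,Description=\"p\">")
  info <- "##INFO=<ID=R2,Number=1,Type=Float,Description=\"q\">"
  path <- write_mini_vcf(
    "1\t100\t.\tA\tT\t.\tPASS\tR2=0.5\tGT:GP\t1/1:0.1,0.2,0.7\t0/0:1,0,0",
    format_defs = fmt, info_defs = info)
  im <- read_imputed_vcf(path, "minimac_r2")
  expect_equal(unname(im$ds[1, ]), c(1.6, 0))
  expect_equal(unname(im$gp$p2[1, ]), c(0.7, 0))

  fmt2 <- c("##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
            "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"d\">")
  path2 <- write_mini_vcf(
    "1\t100\t.\tA\tT\t.\tPASS\tR2=1.2\tGT:DS\t1/1:2.0004\t0/0:0",
    format_defs = fmt2, info_defs = info)
  expect_warning(im2 <- read_imputed_vcf(path2, "minimac_r2"), "clipped")
  expect_equal(unname(im2$ds[1, ]), c(2, 0))
  # MACH-style score above 1 capped with a counter
  expect_equal(im2$variants$rsq_soft, 1)
  expect_equal(im2$n_rsq_capped, 1L)
})

test_that("imputed VCF with neither DS nor GP errors", {
  info <- "##INFO=<ID=DR2,Number=1,Type=Float,Description=\"q\">"
  path <- write_mini_vcf(
    "1\t100\t.\tA\tT\t.\tPASS\tDR2=0.9\tGT\t0/1\t1/1", info_defs = info)
  expect_error(read_imputed_vcf(path, "beagle_dr2"), "DS or GP")
})

test_that("variant matching intersects keys and accounts symmetrically", {
  g <- rbind(c(0, 1), c(1, 2), c(2, 0))
  tr <- make_truth(g, pos = c(100, 200, 300))
  im_full <- make_imputed(tr)
  # imputed set: drops pos 100, keeps 200/300, adds pos 400
  iv <- dplyr::bind_rows(im_full$variants[2:3, ],
                         dplyr::mutate(im_full$variants[1, ], pos = 400L))
  im <- imputeval:::new_imputed_callset(
    iv, rbind(tr$g[2:3, ], c(0L, 0L)), rbind(tr$g[2:3, ], c(0, 0)),
    NULL, tr$samples)
  mv <- match_variants(tr, im)
  expect_equal(mv$report$n_matched, 2)
  expect_equal(mv$report$n_truth_only, 1)
  expect_equal(mv$report$n_imputed_only, 1)
  expect_equal(mv$report$n_matched + mv$report$n_truth_only,
               mv$report$n_truth)
  expect_equal(mv$report$n_matched + mv$report$n_imputed_only,
               mv$report$n_imputed)
  expect_equal(mv$truth$variants$pos, mv$imputed$variants$pos)

  # same position, different alt allele -> allele mismatch
  im2 <- im_full
  im2$variants$alt[1] <- "G"
  mv2 <- match_variants(tr, im2)
  expect_equal(mv2$report$n_allele_mismatch, 1)
  expect_equal(mv2$report$n_matched, 2)
})

test_that("matching errors on disjoint samples or variants", {
  tr <- make_truth(rbind(c(0, 1)))
  im <- make_imputed(tr)
  im$samples <- c("X1", "X2"); colnames(im$gt) <- im$samples
  expect_error(match_variants(tr, im), "samples")
  im2 <- make_imputed(tr)
  im2$variants$pos <- 999L
  expect_error(match_variants(tr, im2), "variants")
})

test_that("stats tables round-trip through TSV with NA conventions", {
  tr <- make_truth(rbind(c(0, 1, 2), c(0, 0, 0), c(1, 1, 2)))
  im <- make_imputed(tr, rsq_soft = c(0.9, 0.5, 0.993))
  st <- per_variant_stats(tr, im)
  path <- tempfile(fileext = ".tsv")
  write_stats_table(st, path)
  lines <- readLines(path)
  expect_length(lines, 4)          # header + 3 variants
  # monomorphic truth row writes NA for non-estimable r
  expect_match(lines[3], "\tNA\t")
  back <- read_stats_table(path)
  expect_equal(back$r_gt, st$r_gt, tolerance = 1e-6)
  expect_equal(back$rsq_soft, st$rsq_soft, tolerance = 1e-6)
  expect_equal(back$est_gt, st$est_gt)
})
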