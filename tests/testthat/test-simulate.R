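test_that("simulation is fully determined by the seed", {
  cfg <- sim_config(seed = 4, n_variants = 600)
  t1 <- simulate_truth(cfg); t2 <- simulate_truth(cfg)
  expect_identical(t1$g, t2$g)
  expect_identical(t1$variants, t2$variants)
  i1 <- simulate_imputation(t1, cfg); i2 <- simulate_imputation(t2, cfg)
  expect_identical(i1$ds, i2$ds)
  expect_identical(i1$variants$rsq_soft, i2$variants$rsq_soft)

  cfg2 <- sim_config(seed = 5, n_variants = 600)
  t3 <- simulate_truth(cfg2)
  expect_false(identical(t1$g, t3$g))
})

test_that("INDEL fraction matches its binomial expectation", {
  cfg <- sim_config(seed = 6, n_variants = 20000)
  tr <- simulate_truth(cfg)
  n_indel <- sum(tr$variants$vclass == "INDEL")
  expected <- 0.07 * 20000
  expect_lt(abs(n_indel - expected), 3 * sqrt(20000 * 0.07 * 0.93))
  # INDEL alleles differ in length; SNP alleles are single bases
  iv <- tr$variants[tr$variants$vclass == "INDEL", ]
  expect_true(all(nchar(iv$ref) != nchar(iv$alt) |
                    nchar(iv$ref) > 1 | nchar(iv$alt) > 1))
})

test_that("beta MAF spectrum reproduces the folded distribution", {
  cfg <- sim_config(seed = 8, n_variants = 20000,
                    maf_spectrum = list(type = "beta", shape1 = 0.5,
                                        shape2 = 0.5))
  tr <- simulate_truth(cfg)
  maf <- tr$variants$maf_ref
  folded_cdf <- function(m) pbeta(m, 0.5, 0.5) + 1 - pbeta(1 - m, 0.5, 0.5)
  for (m in c(0.1, 0.25, 0.4)) {
    expect_lt(abs(mean(maf <= m) - folded_cdf(m)), 0.02)
  }
})

test_that("region spans place variants and record classes correctly", {
  cfg <- sim_config(seed = 12, n_variants = 3000)
  tr <- simulate_truth(cfg)
  v <- tr$variants
  expect_true(all(v$region[v$chrom == "1"] == "AUTOSOME"))
  x <- v[v$chrom == "X", ]
  expect_true(all(x$region[x$pos <= 133300518] == "NONPAR"))
  expect_true(all(x$region[x$pos > 133300518] == "PAR"))
  expect_true(all(v$label[v$pos >= 20e6 & v$pos < 24e6 & v$chrom == "1"] ==
                    "hotspot"))
  # reference MAC truncation guarantees segregation in the panel
  expect_true(all(v$mac_ref >= 1))
  expect_true(all(v$maf_ref > 0 & v$maf_ref <= 0.5))
})

test_that("zero error intensity reproduces the truth exactly", {
  cfg <- sim_config(seed = 9, n_variants = 1000,
                    error_model = list(type = "posterior", lambda = 0,
                                       maf_c0 = 0.1, maf_exponent = 1,
                                       jitter = c(1, 1), prior_noise = 300))
  tr <- simulate_truth(cfg)
  im <- simulate_imputation(tr, cfg)
  expect_identical(im$gt, tr$g)
  st <- per_variant_stats(tr, im)
  expect_true(all(st$aer == 0))
  expect_true(all(st$r_gt[st$est_gt] == 1))
})

test_that("full error intensity makes dosage independent of truth", {
  cfg <- sim_config(seed = 10, n_variants = 2500, profile = "calibration",
                    maf_spectrum = list(type = "beta", shape1 = 2, shape2 = 2),
                    error_model = list(type = "posterior", lambda = 1,
                                       maf_exponent = 0, maf_c0 = 0.1,
                                       jitter = c(1, 1), prior_noise = 300))
  tr <- simulate_truth(cfg)
  im <- simulate_imputation(tr, cfg)
  st <- per_variant_stats(tr, im)
  r <- st$r_ds[st$est_ds]
  expect_gt(length(r), 1000)
  se <- sd(r) / sqrt(length(r))
  expect_lt(abs(mean(r)), 3 * se + 1e-3)
})

test_that("mean empirical accuracy decreases monotonically in lambda", {
  means <- vapply(c(0, 0.05, 0.1, 0.2, 0.4), function(lam) {
    cfg <- sim_config(seed = 13, n_variants = 1200, profile = "calibration",
                      error_model = list(type = "posterior", lambda = lam,
                                         maf_exponent = 0, maf_c0 = 0.1,
                                         jitter = c(1, 1), prior_noise = 300))
    tr <- simulate_truth(cfg)
    st <- per_variant_stats(tr, simulate_imputation(tr, cfg))
    mean(st$rsq_emp_ds[st$est_ds])
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("error intensities outside [0, 1] are rejected", {
  cfg <- sim_config(seed = 14, n_variants = 200,
                    error_model = list(type = "posterior", lambda = 0.9,
                                       maf_exponent = 1, maf_c0 = 0.1,
                                       jitter = c(1, 1), prior_noise = 300))
  tr <- simulate_truth(cfg)
  expect_error(simulate_imputation(tr, cfg), "\\[0, 1\\]")
})

test_that("simulated VCFs round-trip exactly and manifests record the seed", {
  cfg <- sim_config(seed = 19, n_variants = 400)
  tr <- simulate_truth(cfg)
  im <- simulate_imputation(tr, cfg)
  dir <- tempfile()
  paths <- write_simulation(tr, im, dir, cfg)
  tr2 <- read_truth_vcf(paths["truth"])
  expect_identical(tr2$g, tr$g)
  expect_equal(tr2$variants$maf_ref, tr$variants$maf_ref, tolerance = 1e-6)
  expect_equal(tr2$variants$mac_ref, tr$variants$mac_ref)
  expect_equal(tr2$variants$region, tr$variants$region)

  im2 <- read_imputed_vcf(paths["imputed"], "beagle_dr2")
  expect_identical(im2$gt, im$gt)
  expect_lt(max(abs(im2$ds - im$ds)), 1e-6)
  expect_lt(max(abs(im2$gp$p1 - im$gp$p1)), 1e-6)
  expect_lt(max(abs(im2$variants$rsq_soft - im$variants$rsq_soft),
                na.rm = TRUE), 1e-6)

  manifest <- jsonlite::read_json(paths["manifest"])
  expect_equal(manifest$seed, 19)
  expect_equal(manifest$n_variants, 400)

  # different seeds give different VCF bodies
  cfg2 <- sim_config(seed = 20, n_variants = 400)
  tr3 <- simulate_truth(cfg2)
  dir2 <- tempfile()
  paths2 <- write_simulation(tr3, simulate_imputation(tr3, cfg2), dir2, cfg2)
  expect_false(identical(readLines(paths["truth"]),
                         readLines(paths2["truth"])))
})

test_that("overlapping region spans are rejected", {
  bad <- dplyr::bind_rows(default_regions(),
                          tibble::tibble(chrom = "1", start = 10e6, end = 30e6,
                                         class = "AUTOSOME", error_mult = 1,
                                         label = "overlap"))
  expect_error(sim_config(regions = bad), "overlap")
})
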