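test_that("empirical r reproduces hand-worked and degenerate cases", {
  res <- empirical_r(c(0, 1, 2, 1), c(0, 1, 1, 1))
  expect_equal(res$r, bf_pearson(c(0, 1, 2, 1), c(0, 1, 1, 1)))
  expect_equal(res$r, 0.8164966, tolerance = 1e-6)
  expect_true(res$estimable)

  expect_equal(empirical_r(c(0, 1, 2, 1), c(0, 1, 2, 1))$r, 1)

  mono <- empirical_r(c(0, 0, 0, 0), c(0, 1, 2, 1))
  expect_false(mono$estimable)
  expect_equal(mono$reason, "zero_truth_variance")
  expect_true(is.na(mono$r))

  flat_imp <- empirical_r(c(0, 1, 2, 1), c(1, 1, 1, 1))
  expect_equal(flat_imp$reason, "zero_imputed_variance")

  few <- empirical_r(c(0, NA, NA, NA), c(0, 1, 1, 1))
  expect_false(few$estimable)
  expect_equal(few$reason, "too_few_pairs")
})

test_that("empirical r matches the brute-force oracle on random vectors", {
  set.seed(42)
  for (i in 1:300) {
    n <- sample(3:40, 1)
    t <- sample(0:2, n, replace = TRUE)
    y <- if (i %% 2 == 0) sample(0:2, n, replace = TRUE) else runif(n, 0, 2)
    res <- empirical_r(t, y, mode = if (i %% 2 == 0) "gt" else "ds")
    if (res$estimable) {
      expect_equal(res$r, bf_pearson(t, y), tolerance = 1e-12)
    } else {
      expect_true(var(t) == 0 || var(y) == 0)
    }
  }
})

test_that("allele-level error rates decompose genotype differences", {
  a <- allelic_error_rates(c(0, 1, 2, 1), c(0, 1, 1, 1))
  expect_equal(a$fn_alleles, 1)
  expect_equal(a$fp_alleles, 0)
  expect_equal(a$fnr, 25)
  expect_equal(a$fpr, 0)
  expect_equal(a$aer, 12.5)

  perfect <- allelic_error_rates(c(0, 1, 2), c(0, 1, 2))
  expect_equal(c(perfect$fpr, perfect$fnr, perfect$aer), c(0, 0, 0))

  b <- allelic_error_rates(c(0, 0), c(2, 1))
  expect_equal(b$fp_alleles, 3)
  expect_equal(b$fpr, 75)
  expect_true(is.na(b$fnr))   # no alternate alleles in truth
  expect_equal(b$aer, 75)

  expect_error(allelic_error_rates(NA_integer_, 1L), "pairs")
})

test_that("concordance counts identical genotype calls", {
  expect_equal(concordance(c(0, 1, 2, 1), c(0, 1, 1, 1)), 75)
  expect_equal(concordance(c(0, 1, 2), c(0, 1, 2)), 100)
  expect_equal(concordance(c(0, 1, 2), c(1, 2, 0)), 0)
  expect_error(concordance(NA_integer_, NA_integer_), "pairs")
})

test_that("per-variant stats agree with the scalar statistics", {
  set.seed(7)
  V <- 60; N <- 25
  g <- matrix(sample(0:2, V * N, replace = TRUE), V)
  g[sample(length(g), 40)] <- NA          # scattered missingness
  gt <- g
  flip <- sample(length(gt), 150)
  gt[flip] <- sample(0:2, 150, replace = TRUE)
  tr <- make_truth(g)
  ds <- ifelse(is.na(gt), NA, pmin(pmax(gt + rnorm(length(gt), 0, 0.1), 0), 2))
  im <- make_imputed(tr, gt = gt, ds = ds)
  st <- per_variant_stats(tr, im)

  for (v in sample(V, 12)) {
    ok <- !is.na(g[v, ]) & !is.na(gt[v, ])
    er <- empirical_r(g[v, ok], gt[v, ok])
    expect_equal(st$r_gt[v], er$r, tolerance = 1e-12)
    expect_equal(st$est_gt[v], er$estimable)
    ed <- empirical_r(g[v, ok], ds[v, ok], mode = "ds")
    expect_equal(st$r_ds[v], ed$r, tolerance = 1e-12)
    ae <- allelic_error_rates(g[v, ok], gt[v, ok])
    expect_equal(st$aer[v], ae$aer)
    expect_equal(st$fpr[v], ae$fpr)
    expect_equal(st$fnr[v], ae$fnr)
    expect_equal(st$concordance[v], concordance(g[v, ok], gt[v, ok]))
    expect_equal(st$n_pairs[v], sum(ok))
  }
})

test_that("allele conservation and rate identities hold for every variant", {
  set.seed(11)
  cfg <- sim_config(seed = 11, n_variants = 800)
  tr <- simulate_truth(cfg)
  im <- simulate_imputation(tr, cfg)
  st <- per_variant_stats(tr, im)
  fp <- rowSums(pmax(im$gt - tr$g, 0))
  fn <- rowSums(pmax(tr$g - im$gt, 0))
  # FP + FN alleles = AER/100 * 2 * n_pairs, exactly
  expect_equal(fp + fn, st$aer / 100 * 2 * st$n_pairs, tolerance = 1e-12)
  # (FPR/100) * ref_alleles + (FNR/100) * alt_alleles = total wrong alleles
  both <- !is.na(st$fpr) & !is.na(st$fnr)
  ref_al <- 2 * st$n_pairs - rowSums(tr$g)
  alt_al <- rowSums(tr$g)
  expect_equal((st$fpr / 100 * ref_al + st$fnr / 100 * alt_al)[both],
               (fp + fn)[both], tolerance = 1e-9)
  # aer == 0 <=> concordance == 100
  expect_equal(st$aer == 0, st$concordance == 100)
})

test_that("statistics are invariant to sample permutation", {
  set.seed(3)
  cfg <- sim_config(seed = 3, n_variants = 300)
  tr <- simulate_truth(cfg)
  im <- simulate_imputation(tr, cfg)
  st <- per_variant_stats(tr, im)
  perm <- sample(length(tr$samples))
  tr2 <- tr; im2 <- im
  tr2$g <- tr$g[, perm]; tr2$samples <- tr$samples[perm]
  im2$gt <- im$gt[, perm]; im2$ds <- im$ds[, perm]
  im2$gp <- lapply(im$gp, function(m) m[, perm])
  im2$samples <- im$samples[perm]
  st2 <- per_variant_stats(tr2, im2)
  expect_equal(st2$r_gt, st$r_gt, tolerance = 1e-12)
  expect_equal(st2$r_ds, st$r_ds, tolerance = 1e-12)
  expect_equal(st2$aer, st$aer)
  expect_equal(st2$concordance, st$concordance)
})

test_that("common estimable set is the intersection of estimable keys", {
  mk <- function(pos, est) {
    s <- make_stats(rep(0.9, length(pos)), rep(0.9, length(pos)), pos = pos)
    s$est_gt <- est
    s
  }
  a <- mk(c(1000, 2000, 3000), c(TRUE, TRUE, TRUE))
  b <- mk(c(2000, 3000), c(TRUE, TRUE))
  c3 <- mk(c(2000, 3000, 4000), c(TRUE, TRUE, TRUE))
  common <- common_estimable_set(list(a, b, c3))
  expect_equal(sort(common$pos), c(2000, 3000))
  one <- common_estimable_set(list(a))
  expect_equal(sort(one$pos), c(1000, 2000, 3000))
  expect_warning(
    disjoint <- common_estimable_set(list(mk(1000, TRUE), mk(2000, TRUE))),
    "empty")
  expect_equal(nrow(disjoint), 0)
})

test_that("segregation error rates count monomorphic imputation", {
  set.seed(5)
  N <- 20
  g <- matrix(rbinom(100 * N, 2, 0.3), 100)
  g[rowSums(g) == 0, 1] <- 1L   # force all variants segregating
  g[rowSums(g) == 2 * N, 1] <- 1L
  gt <- g
  gt[1:3, ] <- 0L               # 3 of 100 imputed monomorphic
  tr <- make_truth(g)
  st <- segregation_errors(tr, make_imputed(tr, gt = gt))
  expect_equal(st$pct_seg_as_mono, 3)
  expect_equal(st$n_truth_segregating, 100)

  perfect <- segregation_errors(tr, make_imputed(tr))
  expect_equal(perfect$pct_seg_as_mono, 0)
  expect_true(is.na(perfect$pct_mono_as_seg))  # no monomorphic truth here
  expect_equal(perfect$note, "no truth-monomorphic variants")

  mono <- make_truth(matrix(0L, 5, N))
  sm <- segregation_errors(mono, make_imputed(mono))
  expect_true(is.na(sm$pct_seg_as_mono))
  expect_equal(sm$note, "no truth-segregating variants")
})
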