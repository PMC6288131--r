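test_that("effective sample size matches the harmonic formula", {
  expect_equal(effective_sample_size(1000, 1000), 2000)
  expect_equal(effective_sample_size(100, 300), 300)
  expect_equal(effective_sample_size(15212, 29677),
               4 / (1 / 15212 + 1 / 29677), tolerance = 1e-12)
  # symmetry and the balanced-design upper bound
  for (pair in list(c(10, 50), c(123, 456), c(5000, 5000))) {
    a <- pair[1]; b <- pair[2]
    expect_equal(effective_sample_size(a, b), effective_sample_size(b, a))
    expect_lte(effective_sample_size(a, b), a + b)
  }
  expect_equal(effective_sample_size(700, 700), 1400) # equality iff balanced
  expect_error(effective_sample_size(0, 10), "positive")
  expect_error(effective_sample_size(10, -1), "positive")
})

test_that("genomic inflation is the median chi-square ratio", {
  expect_equal(genomic_inflation(rep(qchisq(0.5, 1), 5))$lambda_gc, 1.0)
  expect_equal(genomic_inflation(c(0, 0, 0))$lambda_gc, 0)
  expect_equal(genomic_inflation(c(1, 2, 3))$mean_chi2, 2)
  expect_error(genomic_inflation(numeric(0)), "non-empty")
  # null calibration: squared standard normals give lambda near 1
  set.seed(11)
  lam <- genomic_inflation(rnorm(1e5)^2)$lambda_gc
  expect_lt(abs(lam - 1), 0.01)
})

test_that("lambda_1000 rescales to a 1000/1000 study", {
  expect_equal(lambda_1000(1.0, 50000, 80000), 1.0)
  for (lam in c(0.9, 1.0, 1.1, 1.4)) {
    expect_equal(lambda_1000(lam, 1000, 1000), lam)
  }
  expect_equal(lambda_1000(1.05, 5000, 5000), 1.01)
  expect_error(lambda_1000(1.1, -5, 1000), "positive")
  expect_error(lambda_1000(0, 1000, 1000), "positive")
})

test_that("chi-square LD pair filter flags extreme differences", {
  ss <- data.frame(SNP = c("s1", "s2", "s3", "s4"),
                   Z = sqrt(c(400, 16, 64, 36)))
  ld <- data.frame(SNP_A = c("s1", "s3", "s1"),
                   SNP_B = c("s2", "s4", "s3"),
                   R2 = c(0.9, 0.5, 0.3))
  res <- chi2_ld_pair_filter(ss, ld, r2_min = 0.4)
  expect_equal(nrow(res), 2L) # r2 = 0.3 pair not evaluated
  p12 <- res[res$snp_a == "s1" & res$snp_b == "s2", ]
  expect_equal(p12$cutoff, 3 * sqrt((400 + 16) / 2) / 0.9^2)
  expect_true(p12$flagged)
  expect_equal(p12$remove_variant, "s1") # larger chi-square removed
  p34 <- res[res$snp_a == "s3" & res$snp_b == "s4", ]
  expect_equal(p34$cutoff, 3 * sqrt(50) / 0.25, tolerance = 1e-12)
  expect_false(p34$flagged)
})

test_that("equal statistics are never flagged and pair order is irrelevant", {
  ss <- data.frame(SNP = c("a", "b"), Z = c(sqrt(30), sqrt(30)))
  ld1 <- data.frame(SNP_A = "a", SNP_B = "b", R2 = 0.9)
  ld2 <- data.frame(SNP_A = "b", SNP_B = "a", R2 = 0.9)
  expect_false(chi2_ld_pair_filter(ss, ld1)$flagged)
  expect_identical(chi2_ld_pair_filter(ss, ld1),
                   chi2_ld_pair_filter(ss, ld2))
  # row-order invariance on a larger random instance
  set.seed(3)
  ss <- data.frame(SNP = paste0("v", 1:50), Z = rnorm(50, sd = 4))
  ld <- data.frame(SNP_A = paste0("v", sample(50, 30)),
                   SNP_B = paste0("v", sample(50, 30)),
                   R2 = runif(30, 0.3, 1))
  shuf <- ld[sample(nrow(ld)), ]
  swap <- data.frame(SNP_A = shuf$SNP_B, SNP_B = shuf$SNP_A, R2 = shuf$R2)
  expect_identical(chi2_ld_pair_filter(ss, ld),
                   chi2_ld_pair_filter(ss, swap))
})

test_that("Cochran's Q heterogeneity filter", {
  same <- heterogeneity_test(rep(0.3, 13), rep(0.1, 13))
  expect_equal(same$Q, 0)
  expect_equal(same$p, 1)
  expect_false(same$remove)

  far <- heterogeneity_test(c(0, 10), c(1, 1))
  expect_equal(far$Q, 50)
  expect_equal(far$p, pchisq(50, 1, lower.tail = FALSE))
  expect_true(far$remove) # ~1.5e-12 < 1e-8

  near <- heterogeneity_test(c(0, 1), c(1, 1))
  expect_equal(near$Q, 0.5)
  expect_false(near$remove)

  single <- heterogeneity_test(0.2, 0.1)
  expect_true(is.na(single$Q))
  expect_false(single$remove)

  # location invariance: Q unchanged by adding a constant to all effects
  set.seed(5)
  b <- rnorm(6); s <- runif(6, 0.5, 2)
  expect_equal(heterogeneity_test(b, s)$Q,
               heterogeneity_test(b + 17.3, s)$Q, tolerance = 1e-9)
})

test_that("sample-size-weighted meta-analysis of z-scores", {
  expect_equal(meta_analyze(z = 2.5, n_eff = 5000)$z_meta, 2.5)
  two <- meta_analyze(z = c(1.96, 1.96), n_eff = c(4000, 4000))
  expect_equal(two$z_meta, 1.96 * sqrt(2), tolerance = 1e-12)
  cancel <- meta_analyze(z = c(2, -2), n_eff = c(1000, 1000))
  expect_equal(cancel$z_meta, 0)
  expect_equal(cancel$p_meta, 1)
  # k identical equal-weight strata give z * sqrt(k)
  for (k in c(2, 5, 13)) {
    m <- meta_analyze(z = rep(1.2, k), n_eff = rep(777, k))
    expect_equal(m$z_meta, 1.2 * sqrt(k), tolerance = 1e-12)
  }
  expect_error(meta_analyze(z = numeric(0), n_eff = numeric(0)),
               "at least one")
  # inverse-variance alternative agrees with the closed form
  ivw <- meta_analyze(beta = c(0.1, 0.3), se = c(0.1, 0.2),
                      method = "ivw")
  w <- c(100, 25)
  expect_equal(ivw$beta_meta, sum(w * c(0.1, 0.3)) / sum(w))
})

test_that("summary-statistic validation checks p/z consistency and maf", {
  ss <- data.table::data.table(
    SNP = "v1", CHR = "1", BP = 100L, A1 = "A", A2 = "G",
    FREQ = 0.2, Z = 2.0, P = 2 * pnorm(-2))
  expect_silent(validate_sumstats(ss))
  bad <- data.table::copy(ss)[, P := 0.5]
  expect_error(validate_sumstats(bad), "inconsistent")
  badf <- data.table::copy(ss)[, `:=`(FREQ = 0.7, P = 2 * pnorm(-2))]
  expect_error(validate_sumstats(badf), "frequencies")
})

test_that("qc_sumstats removes flagged variants and reports inflation", {
  set.seed(8)
  n <- 200
  z <- rnorm(n)
  z[1] <- 20 # inflated isolated statistic
  z[2] <- 1
  ss <- data.table::data.table(
    SNP = paste0("v", 1:n), CHR = "1", BP = 1:n, A1 = "A", A2 = "G",
    FREQ = runif(n, 0.05, 0.5), Z = z, P = 2 * pnorm(-abs(z)),
    N_CASES = 15212L, N_CONTROLS = 29677L)
  ld <- data.frame(SNP_A = "v1", SNP_B = "v2", R2 = 0.9)
  qc <- qc_sumstats(ss, ld)
  expect_equal(qc$removed_ld_filter, "v1")
  expect_false("v1" %in% qc$sumstats$SNP)
  expect_s3_class(qc$inflation, "inflation_report")
  expect_true(is.finite(qc$lambda_1000))
})
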