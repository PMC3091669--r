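test_that("binomial tail probabilities match exact summation", {
  expect_equal(binomial_tail_p(5, 5, 0.5), 0.03125)
  expect_equal(binomial_tail_p(2, 6, 0.5), 0.34375)
  expect_equal(binomial_tail_p(9, 30, 0.5), 22964087 / 2^30)
  expect_equal(binomial_tail_p(3, 6, 0.5), 0.65625)
  set.seed(41)
  for (i in 1:60) {
    n <- sample(200, 1)
    k <- sample(0:n, 1)
    p0 <- sample(c(0.3, 0.5, 0.55), 1)
    expect_equal(binomial_tail_p(k, n, p0), oracle_tail_p(k, n, p0),
                 tolerance = 1e-12)
  }
  expect_error(binomial_tail_p(0, 0, 0.5), "no informative reads")
})

test_that("tail symmetry and extremity monotonicity hold", {
  for (n in c(7, 30, 101)) {
    k <- 0:n
    expect_equal(binomial_tail_p(k, n, 0.5), binomial_tail_p(n - k, n, 0.5))
    expect_equal(lbp(k, n, 0.5), -lbp(n - k, n, 0.5))
    # symmetric null: globally monotone in the count difference
    p5 <- binomial_tail_p(k, n, 0.5)
    o <- order(abs(2 * k - n))
    expect_true(all(diff(p5[o]) <= 1e-12))
    # asymmetric null: monotone within each tail side of the median
    for (p0 in c(0.3, 0.55)) {
      p <- binomial_tail_p(k, n, p0)
      med <- qbinom(0.5, n, p0)
      expect_true(all(diff(p[k >= med + 1]) <= 1e-12))
      expect_true(all(diff(p[k <= med - 1]) >= -1e-12))
    }
  }
})

test_that("lbp sign encodes the over-expressed allele", {
  expect_equal(lbp(5, 5, 0.5), -(-log10(0.03125)))
  expect_equal(lbp(0, 5, 0.5), -log10(0.03125))
  expect_equal(lbp(3, 6, 0.5), 0)             # exact null ratio
  expect_lt(lbp(80, 100, 0.5), 0)             # reference (B6) excess
  expect_gt(lbp(20, 100, 0.5), 0)             # alternate excess
})

test_that("gene-level statistics use the pool null fraction", {
  gc <- data.frame(gene_id = c("a", "b", "c"),
                   total_ref = c(30L, 60L, 60L),
                   total_alt = c(30L, 40L, 40L),
                   n_snps_informative = 3L, n_snps_agreeing = 3L,
                   accepted = TRUE)
  ga <- gene_ase(gc, p0 = c(a = 0.5, b = 0.5, c = 0.6))
  expect_equal(ga$lbp[1], 0)
  expect_equal(ga$binomial_p[2], oracle_tail_p(60, 100, 0.5))
  expect_equal(ga$lbp[3], 0)                  # 60/100 equals the 0.6 null
  expect_error(gene_ase(gc, p0 = c(a = 0.5, b = 1, c = 0.5)),
               "monomorphic")
})

test_that("confidence envelope matches brute-force enumeration", {
  expect_equal(ci_envelope(10, 0.01), 8L)
  expect_equal(ci_envelope(1, 0.01), 1L)
  for (n in c(2:12, 25, 60, 100)) {
    for (alpha in c(0.01, 0.05)) {
      expect_equal(ci_envelope(n, alpha), oracle_envelope(n, alpha),
                   info = paste("n =", n, "alpha =", alpha))
    }
  }
  expect_error(ci_envelope(10, 1.5), "alpha")
})

test_that("the envelope has at least nominal null coverage", {
  set.seed(42)
  for (alpha in c(0.01, 0.05)) {
    k <- rbinom(2e4, 100, 0.5)
    outside <- mean(abs(2 * k - 100) > ci_envelope(100, alpha))
    expect_lte(outside, alpha)
  }
})

test_that("replicate error is zero for identical replicates and falls with depth", {
  r1 <- data.frame(snp_id = paste0("s", 1:20),
                   ref_count = rep(c(3L, 12L), 10),
                   alt_count = rep(c(2L, 9L), 10))
  out <- replicate_error_analysis(r1, r1, seed = 5)
  expect_true(all(out$table$observed_error == 0))
  expect_error(replicate_error_analysis(r1[1, ], r1[1, ], seed = 5),
               "shared")

  set.seed(43)
  n <- c(rep(15L, 400), rep(150L, 400))
  r <- runif(800, 0.35, 0.65)
  mk <- function() {
    k <- rbinom(800, n, r)
    data.frame(snp_id = paste0("s", 1:800), ref_count = k,
               alt_count = n - k)
  }
  out <- replicate_error_analysis(mk(), mk(), seed = 6)
  deep <- out$table$mean_reads >= 100
  shallow <- out$table$mean_reads < 30
  expect_lt(median(out$table$observed_error[deep]),
            median(out$table$observed_error[shallow]))
})

test_that("the rank-sum comparison is calibrated under the null", {
  set.seed(44)
  pvals <- vapply(1:150, function(i) {
    n1 <- rpois(120, 50) + 1L
    n2 <- rpois(120, 50) + 1L
    r <- runif(120, 0.3, 0.7)
    k1 <- rbinom(120, n1, r); k2 <- rbinom(120, n2, r)
    replicate_error_analysis(
      data.frame(snp_id = paste0("s", 1:120), ref_count = k1,
                 alt_count = n1 - k1),
      data.frame(snp_id = paste0("s", 1:120), ref_count = k2,
                 alt_count = n2 - k2),
      seed = 1000 + i)$rank_sum_p
  }, 0)
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("concordance recovers exact and null correlation structure", {
  expect_equal(concordance(1:10, 1:10)$r_squared, 1)
  four <- concordance(c(0, 1, 2, 3), c(0, 1, 2, 0))
  expect_equal(four$r_squared, 0.25 / 13.75)  # closed form on the 4 points
  expect_equal(four$n, 4L)
  set.seed(45)
  r2 <- vapply(1:11, function(i) concordance(rnorm(1000),
                                             rnorm(1000))$r_squared, 0)
  expect_lte(median(r2), 0.01)
  expect_error(concordance(rep(1, 5), 1:5), "zero variance")
})

test_that("excess-ASE is near zero under the null and zero at the null ratio", {
  set.seed(46)
  ex <- vapply(1:5, function(i) {
    n <- rep(100L, 2000)
    excess_ase_fraction(rbinom(2000, n, 0.5), n, 0.5)$excess
  }, 0)
  expect_lte(median(ex), 0.02)
  # every SNP at its maximal achievable p-value: no excess
  flat <- excess_ase_fraction(rep(5L, 50), rep(10L, 50), 0.5)
  expect_equal(flat$excess, 0)
  expect_error(excess_ase_fraction(integer(), integer(), 0.5), "no SNPs")
})

test_that("exact power matches published coverage claims and the oracle", {
  expect_equal(round(ase_power(100, 1.70, 0.05), 2), 0.82)
  expect_lte(ase_power(100, 1, 0.05), 0.05)   # null alternative
  expect_equal(ase_power(100, 1.70, 0.01),
               oracle_power_one_tailed(100, 1.70, 0.01), tolerance = 1e-12)
  expect_equal(ase_power(37, 2.2, 0.05),
               oracle_power_one_tailed(37, 2.2, 0.05), tolerance = 1e-12)
  # monotone in n and fold
  expect_true(all(diff(vapply(c(20, 50, 100, 400),
                              function(n) ase_power(n, 1.5, 0.05), 0)) > 0))
  expect_true(all(diff(vapply(c(1.2, 1.5, 2, 3),
                              function(f) ase_power(100, f, 0.05), 0)) > 0))
  expect_warning(ase_power(2, 1.5, 0.01), "unattainable")
})

test_that("detectable_fold inverts the power function", {
  f <- detectable_fold(100, 0.01, 0.5)
  expect_equal(ase_power(100, f, 0.01), 0.5, tolerance = 1e-3)
  expect_gt(detectable_fold(100, 0.01, 0.5),
            detectable_fold(1000, 0.01, 0.5))
})
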