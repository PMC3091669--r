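# The ten published allele-specific splicing candidates: included and
# skipped (ref:alt) read counts with the printed minor-isoform bound.
published_events <- data.frame(
  gene = c("Slc8a1", "Baz2b", "Eif4enif1", "Epb4.1l2", "Papd4",
           "Aqr", "Ankrd12", "Nudc", "Rbm17", "Cacna1h"),
  inc_ref = c(2L, 9L, 3L, 5L, 6L, 8L, 9L, 11L, 16L, 378L),
  inc_alt = c(4L, 21L, 21L, 2L, 0L, 0L, 23L, 16L, 16L, 740L),
  skip_ref = c(232L, 58L, 12L, 2L, 0L, 0L, 3L, 75L, 5L, 5L),
  skip_alt = c(197L, 41L, 6L, 4L, 3L, 3L, 0L, 0L, 0L, 0L),
  p_printed = c(0.344, 0.021, 0.119, 0.344, 0.125,
                0.125, 0.125, 0.221, 0.031, 0.031),
  stringsAsFactors = FALSE
)

test_that("all ten published splicing bounds are reproduced", {
  out <- splicing_ase_bound(published_events$inc_ref,
                            published_events$inc_alt,
                            published_events$skip_ref,
                            published_events$skip_alt)
  expect_equal(round(out$p_bound, 3), published_events$p_printed)
  # the isoform with fewer reads carries the statistic
  n_inc <- published_events$inc_ref + published_events$inc_alt
  n_skip <- published_events$skip_ref + published_events$skip_alt
  expect_equal(out$minor_isoform,
               ifelse(n_inc < n_skip, "included", "skipped"))
})

test_that("total-read ties fall back to the more balanced isoform", {
  tie <- splicing_ase_bound(5, 5, 5, 5)
  expect_true(tie$tie)
  expect_equal(tie$p_bound, binomial_tail_p(5, 10, 0.5))
  # balanced (5,5) vs skewed (9,1): the balanced one is used
  tie2 <- splicing_ase_bound(5, 5, 9, 1)
  expect_true(tie2$tie)
  expect_equal(tie2$minor_isoform, "included")
  expect_error(splicing_ase_bound(0, 0, 3, 1), "1 read")
})

test_that("the bound is invariant under strain relabeling", {
  set.seed(81)
  for (i in 1:20) {
    x <- as.integer(rpois(4, 20) + 1)
    a <- splicing_ase_bound(x[1], x[2], x[3], x[4])
    b <- splicing_ase_bound(x[2], x[1], x[4], x[3])
    expect_equal(a$p_bound, b$p_bound)
    expect_equal(a$minor_isoform, b$minor_isoform)
  }
})

test_that("junction tables tally alleles per isoform with orientation", {
  snps <- snp_table("chr1", 500L, "A", "G")
  genes <- gene_models("g1", "chr1", "+", 0L, 1000L)
  obs <- observations(
    read_id = paste0("r", 1:7),
    chrom = "chr1", pos = 500L,
    strand = c(rep("+", 5), "-", "+"),
    base = c("A", "A", "G", "G", "G", "A", "A"),
    qual = 30L, unique = TRUE,
    junction_id = c(rep("j1", 6), NA),
    isoform = c("included", "included", "included",
                "skipped", "skipped", "included", NA))
  tab <- junction_allele_table(obs, snps, genes)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$inc_ref, 2L)   # the antisense included read is dropped
  expect_equal(tab$inc_alt, 1L)
  expect_equal(tab$skip_ref, 0L)
  expect_equal(tab$skip_alt, 2L)

  # only one isoform represented: no event
  one_iso <- obs[obs$isoform %in% "included" & obs$strand == "+", ]
  expect_equal(nrow(junction_allele_table(one_iso, snps, genes)), 0L)

  # junction outside any gene model: skipped with a warning
  stray <- obs[1:6, ]
  stray$pos <- 5000L
  stray_snps <- snp_table("chr1", 5000L, "A", "G")
  expect_warning(out <- junction_allele_table(stray, stray_snps, genes),
                 "outside any gene")
  expect_equal(nrow(out), 0L)
})

test_that("allele-independent splicing keeps the bound at its nominal rate", {
  # p_bound is a single (un-doubled) tail: under the null each side is
  # super-uniform, so Pr(p_bound <= t) <= 2t, and the doubled bound is
  # super-uniform outright.
  cfg <- simulation_config(seed = 82, n_splicing_events = 400,
                           splicing_true_fraction = 0)
  sim <- simulate_splicing_events(cfg)
  tab <- junction_allele_table(sim$obs, sim$snps, sim$genes)
  out <- splicing_events(tab)
  for (t in c(0.05, 0.1, 0.25)) {
    se <- sqrt(2 * t * (1 - 2 * t) / nrow(out))
    expect_lte(mean(out$p_bound <= t), 2 * t + 3 * se)
    se1 <- sqrt(t * (1 - t) / nrow(out))
    expect_lte(mean(2 * out$p_bound <= t), t + 3 * se1)
  }
})

test_that("strong allele-specific inclusion shifts are detected", {
  cfg <- simulation_config(seed = 83, n_splicing_events = 200,
                           splicing_true_fraction = 1)
  sim <- simulate_splicing_events(cfg)
  out <- splicing_events(junction_allele_table(sim$obs, sim$snps,
                                               sim$genes))
  minor_n <- with(out, pmin(inc_ref + inc_alt, skip_ref + skip_alt))
  deep <- minor_n >= 20
  expect_gte(mean(out$p_bound[deep] <= 0.01), 0.9)
})
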