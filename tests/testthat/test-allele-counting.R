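mk_obs <- function(n, chrom, pos, base, strand = "+", qual = 30L,
                   unique = TRUE, prefix = "r") {
  observations(paste0(prefix, seq_len(n)), chrom, pos, strand, base, qual,
               unique)
}

test_that("error-prone SNP classes are dropped when configured", {
  snps <- snp_table("chr1", 100L, "G", "T")
  obs <- rbind(mk_obs(3, "chr1", 100L, "G"), mk_obs(2, "chr1", 100L, "T",
                                                    prefix = "q"))
  expect_equal(nrow(count_alleles(obs, snps)), 0L)
  cfg <- filter_config(exclude_snp_types = FALSE)
  cnt <- count_alleles(obs, snps, cfg)
  expect_equal(cnt$ref_count, 3L)
  expect_equal(cnt$alt_count, 2L)
})

test_that("allele tallies separate matches from mismatches", {
  snps <- snp_table("chr1", 50L, "A", "G")
  obs <- rbind(mk_obs(6, "chr1", 50L, "A"),
               mk_obs(3, "chr1", 50L, "G", prefix = "g"),
               mk_obs(1, "chr1", 50L, "N", prefix = "n"))
  cnt <- count_alleles(obs, snps)
  expect_equal(cnt$ref_count, 6L)
  expect_equal(cnt$alt_count, 3L)
  expect_equal(cnt$mean_quality, 30)
  expect_equal(attr(cnt, "n_mismatch"), 1L)
  expect_equal(nrow(count_alleles(obs[0, ], snps)), 0L)
})

test_that("the mean-quality filter removes whole sites across strands", {
  snps <- snp_table("chr1", c(10L, 20L), c("A", "C"), c("G", "T"))
  obs <- rbind(
    mk_obs(2, "chr1", 10L, "A", strand = "+", qual = 15L),
    mk_obs(2, "chr1", 10L, "G", strand = "-", qual = 15L, prefix = "m"),
    mk_obs(2, "chr1", 20L, "C", strand = "+", qual = 35L, prefix = "h"),
    # low-quality minus-strand reads at site 20 pull the site mean to 25
    mk_obs(2, "chr1", 20L, "T", strand = "-", qual = 15L, prefix = "l"))
  cnt <- count_alleles(obs, snps)
  expect_true(all(cnt$pos == 20L))          # site 10 mean = 15 < 20
  expect_equal(sort(unique(cnt$strand)), c("+", "-"))
  expect_equal(unique(cnt$mean_quality), 25)  # both-strand site mean
  cnt30 <- count_alleles(obs, snps, filter_config(min_mean_quality = 30))
  expect_equal(nrow(cnt30), 0L)             # 25 < 30 drops site 20 too
})

test_that("uniqueness and unknown-position handling", {
  snps <- snp_table("chr1", 10L, "A", "G")
  obs <- rbind(mk_obs(4, "chr1", 10L, "A"),
               mk_obs(2, "chr1", 10L, "G", unique = FALSE, prefix = "d"),
               mk_obs(1, "chr1", 999L, "A", prefix = "x"))
  expect_warning(cnt <- count_alleles(obs, snps), "absent")
  expect_equal(cnt$ref_count, 4L)
  expect_equal(cnt$alt_count, 0L)
  expect_equal(attr(cnt, "n_skipped"), 1L)
  cfg <- filter_config(require_unique = FALSE)
  expect_warning(cnt2 <- count_alleles(obs, snps, cfg), "absent")
  expect_equal(cnt2$alt_count, 2L)
})

test_that("disabling every filter reproduces the raw tallies", {
  set.seed(21)
  snps <- random_snp_table(30, seed = 22)
  i <- sample(30, 400, TRUE)
  base <- ifelse(runif(400) < 0.5, snps$ref_allele[i], snps$alt_allele[i])
  obs <- observations(paste0("r", 1:400), snps$chrom[i], snps$pos[i],
                      sample(c("+", "-"), 400, TRUE), base,
                      sample(2:40, 400, TRUE),
                      unique = sample(c(TRUE, FALSE), 400, TRUE))
  cfg <- filter_config(min_mean_quality = 0, exclude_snp_types = FALSE,
                       require_unique = FALSE)
  cnt <- count_alleles(obs, snps, cfg)
  is_ref <- base == snps$ref_allele[i]
  key <- paste(snps$chrom[i], snps$pos[i], obs$strand)
  expect_equal(sum(cnt$ref_count), sum(is_ref))
  expect_equal(sum(cnt$alt_count), sum(!is_ref))
  raw <- tapply(is_ref, key, sum)
  expect_equal(cnt$ref_count,
               as.integer(raw[paste(cnt$chrom, cnt$pos, cnt$strand)]),
               ignore_attr = TRUE)
})

test_that("gene aggregation enforces SNP, read and majority criteria", {
  genes <- gene_models("g1", "chr1", "+", 0L, 1000L)
  cnt2 <- data.frame(chrom = "chr1", pos = c(10L, 20L), strand = "+",
                     ref_count = c(15L, 10L), alt_count = c(10L, 5L),
                     mean_quality = 30)
  agg <- aggregate_to_gene(cnt2, genes)
  expect_false(agg$accepted)
  expect_equal(agg$reject_reason, "min_snps")

  cnt3 <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L), strand = "+",
                     ref_count = c(4L, 3L, 0L), alt_count = c(1L, 1L, 3L),
                     mean_quality = 30)
  agg3 <- aggregate_to_gene(cnt3, genes)
  expect_true(agg3$accepted)
  expect_equal(agg3$n_snps_agreeing, 2L)      # votes ref, ref, alt
  expect_equal(agg3$total_ref, 7L)
  expect_equal(agg3$total_alt, 5L)

  few <- cnt3
  few$ref_count <- c(2L, 2L, 0L); few$alt_count <- c(1L, 1L, 2L)
  expect_equal(aggregate_to_gene(few, genes)$reject_reason, "min_reads")

  split_votes <- cnt3
  split_votes$ref_count <- c(9L, 1L, 5L)
  split_votes$alt_count <- c(1L, 9L, 5L)   # ref, alt, abstain
  expect_equal(aggregate_to_gene(split_votes, genes)$reject_reason,
               "no_majority_direction")
})

test_that("opposite-strand counts are excluded from a gene's total", {
  genes <- gene_models("g1", "chr1", "+", 0L, 1000L)
  cnt <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L, 10L),
                    strand = c("+", "+", "+", "-"),
                    ref_count = c(5L, 5L, 5L, 100L),
                    alt_count = c(1L, 1L, 1L, 0L), mean_quality = 30)
  agg <- aggregate_to_gene(cnt, genes)
  expect_equal(agg$total_ref, 15L)
  agg_any <- aggregate_to_gene(cnt, genes, orientation_match = FALSE)
  expect_equal(agg_any$total_ref, 115L)
  empty <- aggregate_to_gene(cnt[0, ], genes)
  expect_equal(empty$reject_reason, "no_informative_snps")
})

test_that("gene assignment never manufactures counts", {
  cfg <- simulation_config(seed = 31, n_genes = 40)
  tr <- simulate_truth(cfg)
  fp <- simulate_f2_pool(cfg)
  sim <- simulate_ase_reads(cfg, fp$pool, tr)
  cnt <- count_alleles(sim$obs, sim$snps)
  agg <- aggregate_to_gene(cnt, sim$genes)
  strand_of <- sim$genes$strand[match(agg$gene_id, sim$genes$gene_id)]
  total_counts <- sum(cnt$ref_count + cnt$alt_count)
  expect_lte(sum(agg$total_ref + agg$total_alt), total_counts)
  # overlapping same-strand genes double-assign, flagged:
  expect_true(all(agg$shared_snps == 0))  # disjoint spans here
})
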