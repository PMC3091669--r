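# Programmatic fixtures shared across test files.

random_snp_table <- function(n, seed = 1) {
  set.seed(seed)
  b <- c("A", "C", "G", "T")
  ref <- sample(b, n, TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(b, r), 1), "")
  snp_table(sample(paste0("chr", 1:3), n, TRUE),
            sample(1e6, n), ref, alt)
}

# A small SAM file: a forward read with a soft clip, a reverse spliced
# read, and a read whose alignment gap spans a SNP position.
write_fixture_sam <- function(path) {
  lines <- c(
    "@HD\tVN:1.6",
    "@SQ\tSN:chr1\tLN:100000",
    # 5S10M: aligned 96..105, query bases 6..15; SNP chr1:100 -> qpos 10
    paste("r_fwd", 0, "chr1", 96, 60, "5S10M", "*", 0, 0,
          "AAAAACCCCGTTTTT", "IIIIIIIII?IIIII", sep = "\t"),
    # 5M100N5M reverse: blocks 200..204 and 305..309; SNP chr1:305 -> qpos 6
    paste("r_rev", 16, "chr1", 200, 60, "5M100N5M", "*", 0, 0,
          "GGGGGTCCCC", "IIIII5IIII", sep = "\t"),
    # SNP chr1:210 falls inside this read's N gap: contributes nothing
    paste("r_gap", 0, "chr1", 205, 60, "3M20N3M", "*", 0, 0,
          "ACGACG", "IIIIII", sep = "\t")
  )
  writeLines(lines, path)
  path
}

# Observations equivalent to the SAM fixture at the three probed SNPs.
fixture_sam_obs <- function() {
  observations(
    read_id = c("r_fwd", "r_rev"),
    chrom = "chr1", pos = c(100L, 305L), strand = c("+", "-"),
    base = c("G", "T"), qual = c(30L, 20L), unique = TRUE
  )
}

fixture_sam_snps <- function() {
  snp_table("chr1", c(100L, 210L, 305L), c("G", "A", "T"),
            c("A", "G", "C"))
}
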