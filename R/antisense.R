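#' Strand bleed-through filter for antisense sites
#'
#' Strand-specific library protocols mis-assign up to a small fraction
#' (`bleed_rate`, default 0.7%) of reads to the wrong strand, so weak
#' "antisense" signal at a site dominated by one strand may be artifact. A
#' site is kept only when its minor-strand read count significantly
#' exceeds the bleed-through expectation: `Pr(X >= minor | total,
#' bleed_rate) < alpha / n_tests` (Bonferroni over the tested family).
#'
#' @param total_sense,total_antisense total reads per strand (the lesser
#'   strand is treated as the candidate antisense signal).
#' @param bleed_rate wrong-strand assignment rate (default 0.007).
#' @param alpha family-wise significance level (default 1e-4).
#' @param n_tests Bonferroni family size (number of SNPs with reads on
#'   both strands).
#' @return Logical: keep the site?
#' @export
bleed_filter <- function(total_sense, total_antisense, bleed_rate = 0.007,
                         alpha = 1e-4, n_tests = 1) {
  if (n_tests < 1) stop("bleed_filter: n_tests must be >= 1")
  total <- total_sense + total_antisense
  minor <- pmin(total_sense, total_antisense)
  ifelse(total == 0, FALSE,
         stats::pbinom(minor - 1, total, bleed_rate,
                       lower.tail = FALSE) < alpha / n_tests)
}

#' Mean-center LBP scores within each strand
#'
#' Genomic-alignment bias yields slightly more reference (B6) reads
#' overall, shifting LBP scores on both strands; subtracting each strand's
#' mean recenters the scores so the sign reflects allelic bias relative to
#' the strand-wide baseline.
#'
#' @param lbp numeric LBP scores.
#' @param strand parallel strand labels (`"+"`/`"-"`).
#' @return Centered scores (per-strand mean exactly 0).
#' @export
normalize_lbp_per_strand <- function(lbp, strand) {
  if (length(lbp) != length(strand))
    stop("normalize_lbp_per_strand: length mismatch")
  stats::ave(lbp, strand, FUN = function(x) x - mean(x))
}

#' Classify a bidirectionally transcribed site by allelic origin
#'
#' Same-sign sense/antisense LBP means both strands favor the same allele
#' (`same_allele`); opposite signs mean transcription arises from separate
#' alleles (`antidirectional`); a zero score carries no direction
#' (`unclassified`).
#'
#' @param lbp_sense,lbp_antisense normalized LBP per strand.
#' @return Character vector of classes.
#' @export
classify_site <- function(lbp_sense, lbp_antisense) {
  s1 <- sign(lbp_sense); s2 <- sign(lbp_antisense)
  ifelse(s1 == 0 | s2 == 0, "unclassified",
         ifelse(s1 == s2, "same_allele", "antidirectional"))
}

#' Sign test for same-allele antisense predominance
#'
#' One-sided exact binomial test that bidirectionally transcribed SNPs are
#' biased toward expression of both strands from the same allele:
#' `Pr(X >= n_same | n_total, 0.5)`.
#'
#' @param n_same sites classified same-allele.
#' @param n_total all classified bidirectional sites.
#' @return One-sided p-value.
#' @examples
#' same_allele_sign_test(65, 106)  # 0.0125
#' @export
same_allele_sign_test <- function(n_same, n_total) {
  if (n_total < 1 || n_same < 0 || n_same > n_total)
    stop("same_allele_sign_test: need 0 <= n_same <= n_total, n_total >= 1")
  stats::pbinom(n_same - 1, n_total, 0.5, lower.tail = FALSE)
}

#' Antisense site classification pipeline
#'
#' From strand-resolved per-SNP allele counts: selects SNPs with reads on
#' both strands, removes bleed-through artifacts ([bleed_filter()]; the
#' Bonferroni family is the set of bidirectional SNPs), computes the
#' signed LBP per strand, mean-centers within each genomic strand among
#' the surviving sites, and classifies each site ([classify_site()]).
#' Filtering precedes normalization so artifact sites cannot shift the
#' strand means.
#'
#' @param counts per-SNP, per-strand counts as from [count_alleles()].
#' @param p0 null reference fraction for the LBP (default 0.5, F1 data).
#' @param bleed_rate,alpha passed to [bleed_filter()].
#' @return A `data.frame` with one row per retained site: `chrom`, `pos`,
#'   plus-/minus-strand counts, `lbp_plus`, `lbp_minus` (normalized),
#'   `class`.
#' @export
antisense_sites <- function(counts, p0 = 0.5, bleed_rate = 0.007,
                            alpha = 1e-4) {
  key <- paste(counts$chrom, counts$pos)
  plus <- counts[counts$strand == "+", , drop = FALSE]
  minus <- counts[counts$strand == "-", , drop = FALSE]
  both <- intersect(paste(plus$chrom, plus$pos),
                    paste(minus$chrom, minus$pos))
  if (length(both) == 0)
    return(data.frame(chrom = character(), pos = integer(),
                      plus_ref = integer(), plus_alt = integer(),
                      minus_ref = integer(), minus_alt = integer(),
                      lbp_plus = numeric(), lbp_minus = numeric(),
                      class = character(), stringsAsFactors = FALSE))
  ip <- match(both, paste(plus$chrom, plus$pos))
  im <- match(both, paste(minus$chrom, minus$pos))
  tp <- plus$ref_count[ip] + plus$alt_count[ip]
  tm <- minus$ref_count[im] + minus$alt_count[im]
  keep <- bleed_filter(pmax(tp, tm), pmin(tp, tm), bleed_rate, alpha,
                       n_tests = length(both))
  ip <- ip[keep]; im <- im[keep]
  if (!any(keep))
    return(antisense_sites(counts[0, , drop = FALSE], p0))
  lbp_p <- lbp(plus$ref_count[ip], plus$ref_count[ip] + plus$alt_count[ip],
               p0)
  lbp_m <- lbp(minus$ref_count[im],
               minus$ref_count[im] + minus$alt_count[im], p0)
  lbp_p_n <- lbp_p - mean(lbp_p)
  lbp_m_n <- lbp_m - mean(lbp_m)
  data.frame(
    chrom = plus$chrom[ip], pos = plus$pos[ip],
    plus_ref = plus$ref_count[ip], plus_alt = plus$alt_count[ip],
    minus_ref = minus$ref_count[im], minus_alt = minus$alt_count[im],
    lbp_plus = lbp_p_n, lbp_minus = lbp_m_n,
    class = classify_site(lbp_p_n, lbp_m_n),
    stringsAsFactors = FALSE
  )
}
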