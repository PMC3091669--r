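#' Exact binomial allele-specificity test
#'
#' The probability of observing an allele split at least as extreme as
#' `k` reference reads out of `n`, under a null reference-allele fraction
#' `p0` (0.5 for an F1; the pool genotype frequency for a pooled F2). The
#' statistic is the smaller single tail,
#' `min(P(X <= k), P(X >= k))` for `X ~ Binomial(n, p0)`, never doubled;
#' set `two_sided = TRUE` for the doubled two-sided version (capped at 1),
#' which is the calibrated choice when a nominal type-I rate matters.
#'
#' @param k reference-allele count(s), `0 <= k <= n`.
#' @param n total informative counts, `n >= 1`.
#' @param p0 null reference-allele fraction(s) in `(0, 1)`.
#' @param two_sided double the smaller tail (default `FALSE`).
#' @return Tail probabilities in `(0, 1]`, vectorized over the inputs.
#' @examples
#' binomial_tail_p(5, 5, 0.5)   # 0.03125
#' binomial_tail_p(2, 6, 0.5)   # 0.34375
#' @export
binomial_tail_p <- function(k, n, p0, two_sided = FALSE) {
  if (any(n < 1)) stop("no informative reads (n = 0)")
  if (any(k < 0 | k > n)) stop("binomial_tail_p: k must be in [0, n]")
  if (any(p0 <= 0 | p0 >= 1)) stop("binomial_tail_p: p0 must be in (0, 1)")
  lower <- stats::pbinom(k, n, p0)
  upper <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
  p <- pmin(lower, upper)
  if (two_sided) p <- pmin(1, 2 * p)
  p
}

#' Signed log10 binomial score (LBP)
#'
#' `|lbp| = -log10(binomial_tail_p(k, n, p0))`. The sign encodes the
#' direction of allelic bias: negative when the reference (B6) allele is
#' over-represented (`k/n > p0`), positive when the alternate allele is,
#' and zero at the exact null ratio. Thresholding `|lbp| > 2` therefore
#' corresponds to `p < 0.01` on the companion LOD-like scale.
#'
#' @inheritParams binomial_tail_p
#' @return Signed scores, vectorized.
#' @export
lbp <- function(k, n, p0, two_sided = FALSE) {
  p <- binomial_tail_p(k, n, p0, two_sided = two_sided)
  sign(p0 - k / n) * -log10(p)
}

#' Gene-level ASE statistic
#'
#' Applies the binomial test and signed LBP to the aggregated counts of
#' genes that passed [aggregate_to_gene()] acceptance. `p0` is the
#' pool-derived null reference fraction at each gene's locus (a named
#' vector) or a single value (0.5 for F1 data).
#'
#' @param gene_counts output of [aggregate_to_gene()].
#' @param p0 scalar or named vector keyed by `gene_id`.
#' @param two_sided passed to [binomial_tail_p()].
#' @return A `data.frame` with columns `gene_id`, `total_ref`, `total_alt`,
#'   `n_snps_informative`, `n_snps_agreeing`, `p0`, `binomial_p`, `lbp`
#'   (one row per accepted gene).
#' @export
gene_ase <- function(gene_counts, p0 = 0.5, two_sided = FALSE) {
  acc <- gene_counts[gene_counts$accepted, , drop = FALSE]
  p0v <- if (length(p0) == 1L && is.null(names(p0)))
    rep(p0, nrow(acc)) else unname(p0[acc$gene_id])
  if (anyNA(p0v) || any(p0v <= 0 | p0v >= 1))
    stop("gene_ase: monomorphic pool (p0 outside (0, 1))")
  n <- acc$total_ref + acc$total_alt
  out <- data.frame(
    gene_id = acc$gene_id,
    total_ref = acc$total_ref,
    total_alt = acc$total_alt,
    n_snps_informative = acc$n_snps_informative,
    n_snps_agreeing = acc$n_snps_agreeing,
    p0 = p0v,
    binomial_p = binomial_tail_p(acc$total_ref, n, p0v, two_sided),
    lbp = lbp(acc$total_ref, n, p0v, two_sided),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Null confidence envelope for allele-count differences
#'
#' For a transcript with `n` informative reads and no allelic bias, the
#' difference between allele counts `|ref - alt| = |2k - n|` stays inside
#' an envelope `d(n)` for at least `1 - alpha` of null data. `d(n)` is the
#' largest difference inside the smallest symmetric retention set of
#' `Binomial(n, 1/2)` with probability at least `1 - alpha`; plotted
#' against `n` it gives the confidence funnel for read-difference plots.
#'
#' @param n vector of total read counts (`n >= 1`).
#' @param alpha envelope tail mass (default 0.01).
#' @return Integer vector `d(n)`: the maximal `|ref - alt|` still inside
#'   the envelope.
#' @examples
#' ci_envelope(10, 0.01)  # 8: only 0:10 and 10:0 splits are outside
#' @export
ci_envelope <- function(n, alpha = 0.01) {
  if (alpha <= 0 || alpha >= 1) stop("ci_envelope: alpha must be in (0, 1)")
  if (any(n < 1)) stop("ci_envelope: n must be >= 1")
  vapply(as.integer(n), function(ni) {
    m <- stats::qbinom(alpha / 2, ni, 0.5)  # candidate lower cut
    while (m > 0 && 2 * stats::pbinom(m - 1, ni, 0.5) > alpha) m <- m - 1L
    while (m < floor(ni / 2) && 2 * stats::pbinom(m, ni, 0.5) <= alpha)
      m <- m + 1L
    as.integer(ni - 2 * m)
  }, 0L)
}

#' Replicate error analysis
#'
#' Compares the observed disagreement between two replicate libraries with
#' the disagreement expected from binomial counting noise alone. For each
#' SNP shared by the replicates the observed error is
#' `|log2(ref1/alt1) - log2(ref2/alt2)|` (Haldane-Anscombe 0.5 pseudocount
#' on ratios with an empty cell); a simulated twin redraws both replicates
#' from `Binomial(n_i, r_i)` at the pooled ratio `r_i`, and the two error
#' distributions are compared by the two-sample Wilcoxon rank-sum test. A
#' non-significant rank-sum p indicates binomial noise fully accounts for
#' replicate disagreement.
#'
#' @param rep1,rep2 `data.frame`s with columns `snp_id`, `ref_count`,
#'   `alt_count`.
#' @param seed RNG seed for the simulated twin.
#' @return A list with `table` (per-SNP `snp_id`, `mean_reads`,
#'   `observed_error`, `simulated_error`) and `rank_sum_p`.
#' @export
replicate_error_analysis <- function(rep1, rep2, seed) {
  shared <- intersect(rep1$snp_id, rep2$snp_id)
  if (length(shared) < 2)
    stop("replicate_error_analysis: need at least 2 shared SNPs")
  a <- rep1[match(shared, rep1$snp_id), ]
  b <- rep2[match(shared, rep2$snp_id), ]
  log2r <- function(ref, alt) {
    z <- ref == 0 | alt == 0
    log2((ref + 0.5 * z) / (alt + 0.5 * z))
  }
  obs_err <- abs(log2r(a$ref_count, a$alt_count) -
                 log2r(b$ref_count, b$alt_count))
  n1 <- a$ref_count + a$alt_count
  n2 <- b$ref_count + b$alt_count
  r <- (a$ref_count + b$ref_count) / (n1 + n2)
  set.seed(seed)
  s1 <- stats::rbinom(length(shared), n1, r)
  s2 <- stats::rbinom(length(shared), n2, r)
  sim_err <- abs(log2r(s1, n1 - s1) - log2r(s2, n2 - s2))
  p <- stats::wilcox.test(obs_err, sim_err, exact = FALSE)$p.value
  list(table = data.frame(snp_id = shared, mean_reads = (n1 + n2) / 2,
                          observed_error = obs_err,
                          simulated_error = sim_err,
                          stringsAsFactors = FALSE),
       rank_sum_p = p)
}

#' Squared Pearson concordance
#'
#' Squared Pearson correlation between paired measurements (replicate
#' allelic ratios, or cross-tissue signed LBP) with the correlation-test
#' p-value.
#'
#' @param x,y paired finite numeric vectors, `length >= 3`.
#' @return A list with `r_squared`, `n`, `p_value`.
#' @export
concordance <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("concordance: need at least 3 finite pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("concordance: zero variance")
  ct <- stats::cor.test(x, y)
  list(r_squared = unname(ct$estimate)^2, n = length(x),
       p_value = ct$p.value)
}

#' Excess allele-specificity beyond the binomial null
#'
#' Compares the observed distribution of per-SNP binomial tail p-values
#' with the distribution expected when every SNP follows its null
#' `Binomial(n_i, p0_i)`. The expected CDF at a threshold `t` is the mean
#' over SNPs of `Pr(p_i <= t)` under the null, obtained by exact
#' enumeration of each SNP's achievable p-values; the excess fraction is
#' the largest gap `observed CDF(t) - expected CDF(t)` over the achievable
#' p-value grid. It estimates the fraction of SNPs with more
#' allele-specificity than counting noise explains.
#'
#' @param k,n,p0 per-SNP reference counts, totals and null fractions.
#' @param min_coverage only SNPs with `n >= min_coverage` enter
#'   (default 10).
#' @return A list with `excess` (the maximal CDF gap, >= 0), `threshold`
#'   (the argmax p-value threshold) and `n_snps`.
#' @export
excess_ase_fraction <- function(k, n, p0, min_coverage = 10) {
  if (length(p0) == 1L) p0 <- rep(p0, length(n))
  keep <- n >= min_coverage
  k <- k[keep]; n <- n[keep]; p0 <- p0[keep]
  if (length(n) == 0) stop("excess_ase_fraction: no SNPs at coverage")
  obs_p <- binomial_tail_p(k, n, p0)
  # pool the full null p-value distribution over unique (n, p0) designs
  key <- paste(n, signif(p0, 12))
  tab <- table(key)
  grid_p <- vector("list", length(tab))
  grid_w <- vector("list", length(tab))
  uk <- names(tab)
  un <- n[match(uk, key)]; up <- p0[match(uk, key)]
  for (i in seq_along(uk)) {
    kk <- 0:un[i]
    grid_p[[i]] <- binomial_tail_p(kk, un[i], up[i])
    grid_w[[i]] <- stats::dbinom(kk, un[i], up[i]) *
      (as.integer(tab[i]) / length(n))
  }
  pv <- unlist(grid_p); wv <- unlist(grid_w)
  o <- order(pv)
  pv <- pv[o]; wv <- cumsum(wv[o])
  # collapse ties so each achievable threshold appears once
  last <- !duplicated(pv, fromLast = TRUE)
  thr <- pv[last]; expected <- wv[last]
  observed <- findInterval(thr, sort(obs_p)) / length(obs_p)
  gap <- observed - expected
  i <- which.max(gap)
  list(excess = max(0, gap[i]), threshold = thr[i], n_snps = length(n))
}

#' Exact binomial power for detecting allelic fold differences
#'
#' Power of the exact binomial ASE test at coverage `n` against an allelic
#' fold difference `fold`, i.e. an alternative reference-allele probability
#' `p1 = fold / (fold + 1)`. One-tailed: the critical value is the
#' smallest `c` with `Pr(X >= c | n, 0.5) <= alpha`; power is
#' `Pr(X >= c | n, p1)`. Two-tailed spends `alpha/2` per side and adds the
#' lower-tail rejection mass.
#'
#' @param n coverage (number of informative reads).
#' @param fold allelic fold difference, `> 1`.
#' @param alpha significance level in `(0, 1)`.
#' @param tails `"one"` or `"two"`.
#' @return Power in `[0, 1]`.
#' @examples
#' ase_power(100, 1.70, 0.05)  # ~0.82
#' @export
ase_power <- function(n, fold, alpha = 0.05, tails = c("one", "two")) {
  tails <- match.arg(tails)
  if (fold < 1) stop("ase_power: fold must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("ase_power: alpha must be in (0, 1)")
  if (n < 1) stop("ase_power: n must be >= 1")
  p1 <- fold / (fold + 1)
  a_side <- if (tails == "one") alpha else alpha / 2
  c_hi <- stats::qbinom(a_side, n, 0.5, lower.tail = FALSE) + 1L
  if (stats::pbinom(c_hi - 2, n, 0.5, lower.tail = FALSE) <= a_side)
    c_hi <- c_hi - 1L
  if (c_hi > n) {
    warning("ase_power: alpha unattainable at n = ", n)
    upper <- 0
  } else {
    upper <- stats::pbinom(c_hi - 1, n, p1, lower.tail = FALSE)
  }
  if (tails == "one") return(upper)
  c_lo <- n - c_hi  # symmetric lower critical value
  lower <- if (c_lo < 0) 0 else stats::pbinom(c_lo, n, p1)
  upper + lower
}

#' @rdname ase_power
#' @param target_power power to reach (default 0.5).
#' @param fold_max upper bracket for the search.
#' @return `detectable_fold`: the smallest fold reaching `target_power`,
#'   found by bisection (power is non-decreasing in fold at fixed `n` and
#'   `alpha`).
#' @export
detectable_fold <- function(n, alpha = 0.01, target_power = 0.5,
                            tails = c("one", "two"), fold_max = 1000) {
  tails <- match.arg(tails)
  lo <- 1; hi <- fold_max
  if (ase_power(n, hi, alpha, tails) < target_power)
    stop("detectable_fold: target power unattainable below fold_max")
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (ase_power(n, mid, alpha, tails) >= target_power) hi <- mid
    else lo <- mid
  }
  hi
}
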