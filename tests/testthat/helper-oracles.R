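# Independent oracles, kept deliberately free of the package's code paths.

# Brute-force binomial pmf summation via log-choose, no pbinom.
oracle_pmf <- function(k, n, p) {
  exp(lchoose(n, k) + k * log(p) + (n - k) * log1p(-p))
}
oracle_tail_p <- function(k, n, p0) {
  lower <- sum(oracle_pmf(0:k, n, p0))
  upper <- sum(oracle_pmf(k:n, n, p0))
  min(lower, upper)
}

# Exact one-tailed power by scanning the cumulative pmf for the critical
# value, then summing the alternative pmf.
oracle_power_one_tailed <- function(n, fold, alpha) {
  p1 <- fold / (fold + 1)
  upper_tail <- rev(cumsum(rev(oracle_pmf(0:n, n, 0.5))))
  c_crit <- which(upper_tail <= alpha)[1] - 1L  # 0-based k
  sum(oracle_pmf(c_crit:n, n, p1))
}

# Smallest symmetric retention set of Binomial(n, 1/2) by enumeration.
oracle_envelope <- function(n, alpha) {
  pmf <- oracle_pmf(0:n, n, 0.5)
  m <- 0L
  while (m + 1L <= floor(n / 2) &&
         sum(pmf[1:(m + 1L)]) + sum(pmf[(n - m + 1L):(n + 1L)]) <= alpha)
    m <- m + 1L
  # m is now the count of excluded values per side
  retained <- m:(n - m)
  max(abs(2 * retained - n))
}

# One-sided hypergeometric enrichment p by direct enumeration over all
# tables with the observed margins, using choose() only.
oracle_fisher_greater <- function(n_both, n_array_only, n_seq_only,
                                  n_neither) {
  N <- n_both + n_array_only + n_seq_only + n_neither
  K <- n_both + n_array_only   # array calls
  M <- n_both + n_seq_only     # seq calls
  xs <- max(0, K + M - N):min(K, M)
  probs <- choose(K, xs) * choose(N - K, M - xs) / choose(N, M)
  sum(probs[xs >= n_both])
}

# Monte-Carlo null same-direction overlap with fixed margins and random
# independent signs.
oracle_permutation_overlap <- function(n_all, n_array, n_seq, reps, seed) {
  set.seed(seed)
  vapply(seq_len(reps), function(i) {
    a <- sample(n_all, n_array)
    s <- sample(n_all, n_seq)
    both <- intersect(a, s)
    sum(sample(c(-1, 1), length(both), TRUE) ==
          sample(c(-1, 1), length(both), TRUE))
  }, 0)
}
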