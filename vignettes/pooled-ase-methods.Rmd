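---
title: "Methods: allele-specific expression from a pooled F2 cross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-specific expression from a pooled F2 cross}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asepool)
```

## The measurement model

A heterozygous cis-acting regulatory variant expresses the two alleles of
a gene unequally, even though both sit in the same nucleus. Strand-specific
cDNA sequencing of RNA pooled across animals of an F2 intercross
(reference strain B6 crossed to an alternate strain such as BTBR or CAST)
measures this directly: every read that overlaps a strain-distinguishing
SNP reports which allele it came from. Under the no-ASE null, each
informative read is an independent Bernoulli trial whose reference-allele
probability `p0` is the reference-allele frequency in the pool — exactly
0.5 for an F1, and a locus-specific genotype frequency for a pooled F2,

```
p0 = (2 n_BB + n_Bb) / (2 N)
```

computed by `pool_null_fraction()` from the pooled animals' genotype
codes. The count of reference reads `k` among `n` informative reads is
then Binomial(`n`, `p0`), and the evidence for ASE is the exact binomial
tail.

## The test statistic and its conventions

`binomial_tail_p(k, n, p0)` returns the *smaller single tail*,
`min(P(X <= k), P(X >= k))`, never doubled. This convention is what the
per-event splicing bounds and the power statements in this package's
acceptance suite require, and it is the quantity behind the signed score

```
lbp = -log10(p) * sign(p0 - k/n)
```

(`lbp()`): negative when the reference (B6) allele is over-expressed,
positive for the alternate allele, zero at the exact null ratio. On this
scale `|lbp| > 2` corresponds to `p < 0.01`; base 10 is chosen so the
score is directly comparable with LOD.

One consequence deserves emphasis: the un-doubled min-tail is not a
calibrated two-sided p-value. Under the null, `Pr(p <= t)` approaches
`2t`, because each side contributes `t`. Wherever a nominal type-I rate
matters — the null-calibration checks in the test suite — the package
uses `two_sided = TRUE`, which doubles the tail (capped at 1) and is
conservative under discreteness. Both conventions are exposed; the
default matches the reporting convention of the per-event statistics.

A related discreteness fact: the min-tail p is *not* globally monotone in
the distance `|k - n p0|` when `p0 != 0.5`, because the two tails of an
asymmetric binomial decay at different rates. It is monotone within each
tail side of the median, and globally monotone at `p0 = 0.5`; the
property tests assert exactly that.

## Filters on the raw counts

`count_alleles()` applies the filters a pooled-cross analysis needs
(`filter_config()` holds the knobs):

* **SNP classes C/A, A/C, G/T** (ordered reference/alternate pairs) are
  excluded by default; these substitution classes show disproportionate
  reference-mismatch error in Illumina data. The flag is a pure function
  of the ordered pair, so T/G is *not* excluded.
* **Mean base quality >= 20 per site**, computed over all contributing
  (allele-matching) reads on both strands before the strand split — the
  unreliable artifact is the site, not one strand of it.
* **Uniqueness**: only uniquely aligned reads (or redundant alignments
  anchored by unique ones, encoded upstream in the `unique` flag) count.
* Bases matching neither allele are never counted as evidence; they are
  tallied in a mismatch counter so error-rate regressions stay visible.

Every filter is a pure subtraction: disabling them all reproduces the raw
tallies exactly (a property test holds this).

## Gene-level aggregation

`aggregate_to_gene()` sums per-SNP counts over the transcript span,
introns included (intronic reads are mostly unprocessed pre-mRNA and add
sensitivity), keeping only counts on the gene's annotated strand. A gene
is accepted when it has at least 10 allele-specific count units over at
least 3 SNPs and a strict majority of non-abstaining SNPs agree on the
direction of bias; the per-SNP vote is the sign of
`ref (1 - p0) - alt p0`, so votes are pool-aware, and a SNP at the exact
null ratio abstains. The three-SNP/majority requirement protects against
a single false-positive SNP or differential priming site dominating a
gene. Rejected genes are reported with a reason rather than dropped. A
SNP inside two overlapping same-strand genes contributes to both — a
deterministic, symmetric choice, flagged in the `shared_snps` column. The
10-unit minimum counts per-SNP count units (a read spanning two SNPs
contributes twice), which is the natural unit once per-SNP sums are
added.

## cis-eQTL stage

`marker_regression()` fits expression on the additive genotype coding
(-1, 0, +1) at the gene's own locus. The slope is the additive effect
(half the homozygote mean difference under balance; positive when
alternate-strain homozygotes express more) and
`LOD = (n/2) log10(RSS_null / RSS_fit)`. Dominance is omitted because
cis-acting loci act on the copy they reside on and behave additively;
genome-wide scans and trans-eQTL are out of scope — each gene is tested
only at its own locus, since the purpose is the ASE comparison.
Noise-free fits are guarded by flooring `RSS_fit` at
`RSS_null * .Machine$double.eps`. Genes whose microarray probes overlap a
SNP are excluded from calling (`flag_probe_snp_overlap()`, half-open
interval test) because a SNP under a probe perturbs hybridization and
fakes cis signal.

## ASE/eQTL agreement

Under independence, two gene lists of sizes `n_array` and `n_seq` drawn
from `n_all` genes overlap *with the same directional bias* in
`n_array * n_seq / (2 n_all)` genes in expectation — the product of the
marginal rates, halved because independent signs agree half the time
(`expected_overlap()`; multiply by 2 for direction-free overlap — both are
derivable from the grid output). `enrichment_grid()` sweeps thresholds on
`|additive effect|` and `|lbp|` and reports, per cell, the margins, the
observed overlap, the same-direction overlap, the observed/expected
ratio, and the direction agreement among overlapping genes (genes with
`lbp == 0` carry no direction and leave the denominator).
`fisher_overlap()` gives the one-sided hypergeometric p for a single 2x2
membership table.

## Antisense classification

Sites with reads on both strands are candidates for allele-specific
antisense transcription. Because strand-specific protocols mis-assign up
to 0.7% of reads, a site is kept only when its minor-strand count
significantly exceeds the bleed-through expectation
(`Pr(X >= minor | total, 0.007) < 1e-4 / n_tests`, Bonferroni over the
bidirectional sites) — the only reading of the exclusion rule that
actually removes bleed-through artifacts. Filtering happens *before*
normalization so artifact sites cannot shift the strand means; LBP scores
are then mean-centered within each genomic strand (a small genome-wide
excess of reference reads, presumably alignment bias, would otherwise
masquerade as agreement) and classified by sign pattern: same signs =
both strands from the same allele; opposite signs = antidirectional;
a zero score = unclassified. `same_allele_sign_test()` is the one-sided
exact binomial test that same-allele sites predominate.

## Allele-specific splicing

`junction_allele_table()` tallies reads that span an alternative splice
junction *and* cover a SNP, split by isoform (included/skipped) and
allele, keeping only reads oriented like the transcript and only events
where both isoforms are represented. `splicing_ase_bound()` then computes
the one-sided exact binomial tail of the *minor* isoform (fewer total
reads) at `p0 = 0.5`, in the direction of its observed bias. Taking the
minor isoform makes the value a conservative upper bound on the evidence
("p(ASE) is less than"), which is how the per-event table reports it; on
a total-read tie the more balanced isoform is used and the event flagged.
Because the bound is an un-doubled tail, its null distribution satisfies
`Pr(p <= t) <= 2t` (the doubled bound is super-uniform outright); the
conservativeness test asserts exactly this. No multiple-testing
correction is applied — events are presented as candidates. Conditioning
on transcription-level ASE beyond requiring both isoforms present is not
implemented; with junction-spanning coverage the included/skipped
contrast already shares the transcription-level allele ratio.

## Confidence envelopes, replicate error, excess ASE

* `ci_envelope(n, alpha)` returns the largest `|ref - alt|` difference
  inside the smallest symmetric retention set of Binomial(`n`, 1/2) with
  probability at least `1 - alpha` — the funnel drawn on read-difference
  plots. By construction it excludes at most `alpha` of null data
  (Monte-Carlo checked at 0.01 and 0.05).
* `replicate_error_analysis()` asks whether two replicate libraries
  disagree more than binomial counting noise allows: per shared SNP the
  observed error `|log2(ref1/alt1) - log2(ref2/alt2)|` (Haldane-Anscombe
  0.5 pseudocount only when a cell is empty, and only here — never in
  test statistics) is compared, via the two-sample Wilcoxon rank-sum
  test, with a simulated twin redrawn from `Binomial(n_i, r_i)` at the
  pooled ratio.
* `excess_ase_fraction()` estimates how many SNPs are more
  allele-specific than chance: it compares the observed CDF of per-SNP
  min-tail p-values with the expected null CDF — the mean over SNPs of
  `Pr(p_i <= t)` under `Binomial(n_i, p0_i)`, obtained by exact
  enumeration — and reports the largest gap over the achievable p-value
  grid. This max-gap estimator is this package's concrete instantiation
  of an observed-versus-expected distribution comparison; it is validated
  by parameter recovery on synthetic data (recovering a simulated 40%
  cis fraction within +-0.07 at 100x coverage), not by any external
  real-data figure. It is conservative: detection power below 1 means
  the gap under-states the true mixing fraction at moderate folds.

## Power

`ase_power(n, fold, alpha, tails)` is exact binomial power: the smallest
critical value `c` with `Pr(X >= c | n, 0.5) <= alpha` (one-tailed;
`alpha/2` per side plus the mirrored lower region for two-tailed), then
`Pr(X >= c | n, p1)` with `p1 = fold / (fold + 1)`. At `n = 100`,
`alpha = 0.05`, `fold = 1.70` this gives 0.8226 — 82% — and
`detectable_fold()` inverts the curve by bisection. The one-tailed,
un-doubled convention is pinned down by the per-event statistics this
package reproduces; claims at much higher coverage depend on
convention details the exact test alone does not determine, so only the
100x figure is treated as a fixed reference point.

## The synthetic-data generator

`simulation_config()` freezes the study conditions the generator
emulates; defaults were chosen once, as follows, and are not tuned to
test outcomes:

* **Pool of 100 animals**, one marker locus per gene, genotypes
  Binomial(2, 1/2) per locus — Mendelian 1:2:1 with no linkage. None of
  the implemented statistics uses inter-locus LD, so independence costs
  nothing and keeps the generator transparent.
* **cis fraction 0.25** of genes, a plausible rate for a dense cross;
  recovery tests override it explicitly (e.g. 0.40) when the scenario
  calls for it.
* **Fold 2.0** for cis genes, applied multiplicatively to one allele
  with a random direction per gene: a comfortably detectable effect at
  the default coverage, above the 1.7-fold the 100x power analysis
  references. The reference-allele read probability at a cis SNP is
  `p0 f / (p0 f + 1 - p0)` (bias toward reference) or its mirror.
* **Coverage Poisson(30) per SNP, 3-8 SNPs per gene**, so gene totals
  span roughly 90-240 — deep enough for gene-level tests, small enough
  that the full suite runs in well under a minute.
* **Additive expression effect 0.6, residual sd 1**: single-marker LOD
  comfortably above 3 for most cis genes at n = 100 animals, with
  realistic misses. The expression effect sign agrees with the ASE
  direction with probability 1 by default (`agreement_prob`), making
  direction-agreement results interpretable against truth.
* **Base-call error 0.005** flat (no quality-score model), **strand
  bleed-through 0.007**, antisense allele bias 0.85, same-allele
  proportion 0.6 among true bidirectional sites — near the observed
  predominance of same-allele antisense in real crosses.
* **Splicing**: inclusion probability 0.9 vs 0.1 between alleles for
  shifted events, 0.5/0.5 for null events, ~30 reads per allele.

What the generator does *not* emulate: realistic read positioning along
transcripts, quality-score error structure, linkage between loci,
reference-alignment bias, RNA-pooling mass variation between animals, and
overdispersion beyond binomial (no beta-binomial component). Passing
recovery tests therefore demonstrates the statistical machinery is
correct and calibrated under its own assumptions — not that real
libraries meet those assumptions.

## Numerical and edge-case choices

* Tail probabilities come from `pbinom` (regularized incomplete beta),
  asserted equal to brute-force pmf summation up to `n = 200` in the
  acceptance suite.
* `p0` from a pool is clamped to `[0.01, 0.99]` with a warning;
  monomorphic loci cannot support ASE testing and error out of
  `gene_ase()`.
* Duplicate SNP positions are a hard parse error — per-SNP statistics
  assume unique sites; silent merging would corrupt counts.
* Coordinates: 1-based positions in VCF/GTF/TSV records; 0-based
  half-open for every interval-containment test (`pos_to_interval()` is
  the single conversion point). BED input is converted at the boundary.
* Problem sizes in the test suite (2-3k genes for calibration and
  recovery, 10^4 permutation replicates, 10^5 envelope draws) were chosen
  as the smallest sizes at which binomial Monte-Carlo error is well below
  the asserted tolerances.

## Known limitations

Binomial nulls ignore extra-binomial variation between animals in the
pool; a beta-binomial extension would absorb it but is out of scope. The
eQTL stage is a deliberately minimal single-marker additive fit, not an
interval-mapping pipeline, and its LOD is not claimed to match one. The
excess-ASE estimator is a lower-bound-flavored summary, not a mixture
fit. SAM input is read linearly (no index-dependent semantics) and
junction/isoform labels travel only through the TSV observation dialect.
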