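#' Simulation configuration for the pooled-cross study design
#'
#' Defines the generative model the test-data simulator uses: an F2
#' intercross pool (per-locus genotypes Binomial(2, 1/2), so ~1:2:1), one
#' marker locus per gene, allele-specific reads over SNPs inside each
#' gene, an additive-genetic expression matrix over the same animals,
#' strand-resolved antisense sites and junction-labeled splicing reads.
#' Defaults represent the study conditions: a pool of 100 animals, genes
#' carrying a true cis effect with probability `cis_fraction`, a constant
#' allelic fold of 2 applied to a randomly chosen allele per cis gene, a
#' matching additive expression effect of 0.6 (sd-1 noise) whose sign
#' agrees with the ASE direction with probability `agreement_prob`,
#' per-SNP coverage Poisson(30), a flat 0.5% base-call error and 0.7%
#' strand bleed-through.
#'
#' @param seed RNG seed (mandatory; all generators derive their streams
#'   from it).
#' @param n_animals pooled F2 animals (default 100).
#' @param n_genes number of genes/loci (default 200).
#' @param snps_per_gene_min,snps_per_gene_max uniform range of SNPs per
#'   gene (default 3..8).
#' @param coverage_mean mean per-SNP read coverage, Poisson (default 30).
#' @param cis_fraction fraction of genes with a true cis effect
#'   (default 0.25).
#' @param fold allelic fold change for cis genes (> 1, default 2).
#' @param base_error_rate per-base miscall rate (default 0.005).
#' @param additive_effect expression effect size for cis genes
#'   (default 0.6).
#' @param expression_sd residual expression noise sd (default 1).
#' @param agreement_prob probability that the expression effect sign
#'   agrees with the ASE direction (default 1).
#' @param n_antisense_sites sites for the antisense generator
#'   (default 150).
#' @param antisense_same_allele_prop proportion of true bidirectional
#'   sites in same-allele mode (default 0.6).
#' @param antisense_bleed_rate wrong-strand read rate (default 0.007).
#' @param antisense_allele_bias allele probability at biased antisense
#'   sites (default 0.85).
#' @param n_splicing_events events for the splicing generator
#'   (default 60).
#' @param splicing_true_fraction fraction of events with a real
#'   allele-specific inclusion shift (default 0.5).
#' @param psi_shift included-isoform probability pair
#'   (reference allele, alternate allele) for true events
#'   (default c(0.9, 0.1)).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed,
                              n_animals = 100L,
                              n_genes = 200L,
                              snps_per_gene_min = 3L,
                              snps_per_gene_max = 8L,
                              coverage_mean = 30,
                              cis_fraction = 0.25,
                              fold = 2,
                              base_error_rate = 0.005,
                              additive_effect = 0.6,
                              expression_sd = 1,
                              agreement_prob = 1,
                              n_antisense_sites = 150L,
                              antisense_same_allele_prop = 0.6,
                              antisense_bleed_rate = 0.007,
                              antisense_allele_bias = 0.85,
                              n_splicing_events = 60L,
                              splicing_true_fraction = 0.5,
                              psi_shift = c(0.9, 0.1)) {
  if (missing(seed)) stop("simulation_config: seed is mandatory")
  stopifnot(fold > 1 || cis_fraction == 0,
            cis_fraction >= 0, cis_fraction <= 1,
            base_error_rate >= 0, base_error_rate <= 1,
            agreement_prob >= 0, agreement_prob <= 1,
            snps_per_gene_min >= 1,
            snps_per_gene_max >= snps_per_gene_min)
  cfg <- as.list(environment())
  structure(cfg, class = "simulation_config")
}

#' Per-gene/site ground truth
#'
#' Draws which genes carry a true cis effect, the direction of their
#' allelic bias (`+1` = alternate/BTBR allele over-expressed, `-1` =
#' reference/B6), and the matching signed additive expression effect.
#'
#' @param config a [simulation_config()].
#' @return A `data.frame`: `gene_id`, `cis`, `fold`, `ase_direction`,
#'   `additive_effect`.
#' @export
simulate_truth <- function(config) {
  set.seed(config$seed + 1L)
  n <- config$n_genes
  cis <- stats::runif(n) < config$cis_fraction
  dir <- sample(c(-1L, 1L), n, replace = TRUE)
  agree <- stats::runif(n) < config$agreement_prob
  eff_sign <- ifelse(agree, dir, -dir)
  data.frame(
    gene_id = sprintf("gene%04d", seq_len(n)),
    cis = cis,
    fold = ifelse(cis, config$fold, 1),
    ase_direction = ifelse(cis, dir, 0L),
    additive_effect = ifelse(cis, eff_sign * config$additive_effect, 0),
    stringsAsFactors = FALSE
  )
}

#' Simulate the F2 pool genotypes
#'
#' One marker locus per gene; each pooled animal's genotype code (count
#' of alternate alleles) is an independent Binomial(2, 1/2) draw, giving
#' per-locus genotype frequencies near 1:2:1. No linkage is modeled.
#'
#' @param config a [simulation_config()].
#' @return A list with `genotypes` (animals x loci integer matrix, locus
#'   ids as colnames) and `pool` (per-locus `data.frame`: `locus`,
#'   `n_BB`, `n_Bb`, `n_bb`, `p0`).
#' @export
simulate_f2_pool <- function(config) {
  set.seed(config$seed + 2L)
  loci <- sprintf("gene%04d", seq_len(config$n_genes))
  g <- matrix(stats::rbinom(config$n_animals * config$n_genes, 2L, 0.5),
              nrow = config$n_animals,
              dimnames = list(NULL, loci))
  pool <- data.frame(
    locus = loci,
    n_BB = colSums(g == 0L),
    n_Bb = colSums(g == 1L),
    n_bb = colSums(g == 2L),
    stringsAsFactors = FALSE
  )
  pool$p0 <- 1 - colSums(g) / (2 * config$n_animals)
  rownames(pool) <- NULL
  list(genotypes = g, pool = pool)
}

# non-excluded (ref, alt) allele pairs, so default counting filters keep
# every simulated site
allowed_pairs <- function() {
  b <- c("A", "C", "G", "T")
  p <- expand.grid(ref = b, alt = b, stringsAsFactors = FALSE)
  p <- p[p$ref != p$alt, ]
  p[!is_excluded_snp_type(p$ref, p$alt), ]
}

#' Simulate allele-specific reads over SNPs
#'
#' Lays each gene on its own 10 kb span of a synthetic chromosome with a
#' random strand, places SNPs inside it, and draws per-SNP reads. At a
#' SNP of gene `g` with locus null fraction `p0` and true fold `f`, the
#' probability that a read carries the reference allele is
#' `p0 * f / (p0 * f + (1 - p0))` when the bias is toward the reference
#' allele, and `p0 / (p0 + (1 - p0) * f)` when toward the alternate.
#' Per-SNP coverage is Poisson (`coverage_mean`, floored at 1). Each read
#' base is miscalled to a uniformly random different base with
#' probability `base_error_rate`.
#'
#' @param config a [simulation_config()].
#' @param pool output of [simulate_f2_pool()].
#' @param truth output of [simulate_truth()].
#' @return A list with `obs` (observations), `snps` (SNP table), `genes`
#'   (gene models), and `snp_truth` (`chrom`, `pos`, `gene_id`,
#'   `ref_prob`).
#' @export
simulate_ase_reads <- function(config, pool, truth) {
  set.seed(config$seed + 3L)
  n <- config$n_genes
  strand <- sample(c("+", "-"), n, replace = TRUE)
  gstart <- (seq_len(n) - 1L) * 10000L  # 0-based half-open spans
  genes <- gene_models(truth$gene_id, "chrS", strand, gstart,
                       gstart + 8000L)
  n_snps <- sample(config$snps_per_gene_min:config$snps_per_gene_max,
                   n, replace = TRUE)
  gidx <- rep(seq_len(n), n_snps)
  off <- unlist(lapply(n_snps, function(k)
    sort(sample(10L:7990L, k))))  # unique within gene
  pos <- gstart[gidx] + off + 1L  # 1-based
  ap <- allowed_pairs()
  pair <- ap[sample(nrow(ap), length(pos), replace = TRUE), ]
  snps <- snp_table("chrS", pos, pair$ref, pair$alt)
  # per-SNP reference-allele probability from fold, direction, locus p0
  p0 <- pool$p0[match(truth$gene_id[gidx], pool$locus)]
  f <- truth$fold[gidx]
  dir <- truth$ase_direction[gidx]
  ref_prob <- ifelse(dir < 0, p0 * f / (p0 * f + (1 - p0)),
              ifelse(dir > 0, p0 / (p0 + (1 - p0) * f), p0))
  cov <- pmax(1L, stats::rpois(length(pos), config$coverage_mean))
  snp_row <- rep(seq_along(pos), cov)
  n_reads <- length(snp_row)
  true_ref <- stats::runif(n_reads) < ref_prob[snp_row]
  base <- ifelse(true_ref, pair$ref[snp_row], pair$alt[snp_row])
  err <- which(stats::runif(n_reads) < config$base_error_rate)
  if (length(err)) {
    base[err] <- vapply(base[err], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
  }
  obs <- observations(
    read_id = sprintf("r%07d", seq_len(n_reads)),
    chrom = "chrS", pos = pos[snp_row],
    strand = strand[gidx][snp_row],
    base = base,
    qual = sample(30:40, n_reads, replace = TRUE),
    unique = TRUE
  )
  list(obs = obs, snps = snps, genes = genes,
       snp_truth = data.frame(chrom = "chrS", pos = pos,
                              gene_id = truth$gene_id[gidx],
                              ref_prob = ref_prob,
                              stringsAsFactors = FALSE))
}

#' Simulate the additive-genetic expression matrix
#'
#' `expression[g, i] = a_g * (genotype[i, g] - 1) + Normal(0, sd)`, with
#' `a_g` the gene's true signed additive effect.
#'
#' @param config a [simulation_config()].
#' @param genotypes animals x loci matrix from [simulate_f2_pool()].
#' @param truth output of [simulate_truth()].
#' @return A genes x animals numeric matrix (gene ids as rownames).
#' @export
simulate_expression <- function(config, genotypes, truth) {
  set.seed(config$seed + 4L)
  n_an <- nrow(genotypes)
  expr <- t(vapply(seq_len(nrow(truth)), function(i) {
    g <- genotypes[, truth$gene_id[i]]
    truth$additive_effect[i] * (g - 1) +
      stats::rnorm(n_an, 0, config$expression_sd)
  }, numeric(n_an)))
  rownames(expr) <- truth$gene_id
  expr
}

#' Simulate strand-resolved antisense sites
#'
#' Three site modes: `same_allele` (both strands transcribed from one
#' allele: the same biased allele ratio on each strand),
#' `antidirectional` (each strand from the opposite allele: mirrored
#' ratios), and `bleed_only` (no true antisense; minor-strand reads are
#' pure bleed-through at `antisense_bleed_rate`). True bidirectional
#' sites split modes by `antisense_same_allele_prop` and make up 2/3 of
#' sites; the rest are bleed-only.
#'
#' @param config a [simulation_config()].
#' @return A list with `counts` (per-site, per-strand `chrom`, `pos`,
#'   `strand`, `ref_count`, `alt_count`, `mean_quality`) and `truth`
#'   (`chrom`, `pos`, `mode`).
#' @export
simulate_antisense_sites <- function(config) {
  set.seed(config$seed + 5L)
  n <- config$n_antisense_sites
  n_true <- round(2 / 3 * n)
  mode <- c(
    ifelse(stats::runif(n_true) < config$antisense_same_allele_prop,
           "same_allele", "antidirectional"),
    rep("bleed_only", n - n_true)
  )
  pos <- seq_len(n) * 1000L
  q <- config$antisense_allele_bias
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sense_total <- max(1L, stats::rpois(1L, 300))
    ref_sense <- if (stats::runif(1) < 0.5) q else 1 - q  # biased allele
    if (mode[i] == "bleed_only") {
      anti_total <- stats::rbinom(1L, sense_total,
                                  config$antisense_bleed_rate)
      ref_anti <- ref_sense
    } else {
      anti_total <- max(1L, stats::rpois(1L, 100))
      ref_anti <- if (mode[i] == "same_allele") ref_sense else 1 - ref_sense
    }
    sr <- stats::rbinom(1L, sense_total, ref_sense)
    ar <- stats::rbinom(1L, anti_total, ref_anti)
    rows[[i]] <- data.frame(
      chrom = "chrA", pos = rep(pos[i], 2L), strand = c("+", "-"),
      ref_count = c(sr, ar),
      alt_count = c(sense_total - sr, anti_total - ar),
      mean_quality = 35, stringsAsFactors = FALSE)
  }
  counts <- do.call(rbind, rows)
  counts <- counts[counts$ref_count + counts$alt_count > 0, , drop = FALSE]
  rownames(counts) <- NULL
  list(counts = counts,
       truth = data.frame(chrom = "chrA", pos = pos, mode = mode,
                          stringsAsFactors = FALSE))
}

#' Simulate junction-labeled splicing reads
#'
#' Each event is a SNP covered by reads supporting an alternative
#' junction. For true events the included-isoform probability differs by
#' allele (`psi_shift`); null events use 0.5 for both alleles. Reads are
#' emitted as observations with `junction_id`/`isoform` labels, oriented
#' with the gene strand.
#'
#' @param config a [simulation_config()].
#' @return A list with `obs`, `snps`, `genes` and `truth` (`gene_id`,
#'   `junction_id`, `true_shift`).
#' @export
simulate_splicing_events <- function(config) {
  set.seed(config$seed + 6L)
  n <- config$n_splicing_events
  strand <- sample(c("+", "-"), n, replace = TRUE)
  gstart <- (seq_len(n) - 1L) * 10000L
  gid <- sprintf("spl%04d", seq_len(n))
  genes <- gene_models(gid, "chrJ", strand, gstart, gstart + 8000L)
  pos <- gstart + 4000L
  ap <- allowed_pairs()
  pair <- ap[sample(nrow(ap), n, replace = TRUE), ]
  snps <- snp_table("chrJ", pos, pair$ref, pair$alt)
  true_shift <- stats::runif(n) < config$splicing_true_fraction
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    n_ref <- max(1L, stats::rpois(1L, 30))
    n_alt <- max(1L, stats::rpois(1L, 30))
    psi_ref <- if (true_shift[i]) config$psi_shift[1] else 0.5
    psi_alt <- if (true_shift[i]) config$psi_shift[2] else 0.5
    inc_ref <- stats::rbinom(1L, n_ref, psi_ref)
    inc_alt <- stats::rbinom(1L, n_alt, psi_alt)
    k <- n_ref + n_alt
    rows[[i]] <- observations(
      read_id = sprintf("j%04d_%03d", i, seq_len(k)),
      chrom = "chrJ", pos = pos[i], strand = strand[i],
      base = c(rep(pair$ref[i], n_ref), rep(pair$alt[i], n_alt)),
      qual = 35L, unique = TRUE,
      junction_id = sprintf("jx%04d", i),
      isoform = c(rep(c("included", "skipped"),
                      c(inc_ref, n_ref - inc_ref)),
                  rep(c("included", "skipped"),
                      c(inc_alt, n_alt - inc_alt)))
    )
  }
  list(obs = do.call(rbind, rows), snps = snps, genes = genes,
       truth = data.frame(gene_id = gid, junction_id = sprintf("jx%04d",
                                                               seq_len(n)),
                          true_shift = true_shift,
                          stringsAsFactors = FALSE))
}
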