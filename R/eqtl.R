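#' Single-marker additive regression at a gene's own locus
#'
#' Minimal cis-eQTL fit: expression is regressed on the additive genotype
#' coding (-1, 0, +1 for 0, 1, 2 copies of the alternate/BTBR allele). The
#' additive effect is the fitted slope - under a balanced design, half the
#' difference between homozygote class means, positive when BTBR
#' homozygotes express more. The LOD score is
#' `(n/2) * log10(RSS_null / RSS_fit)`. Dominance is omitted: cis-acting
#' loci are expected to behave additively.
#'
#' @param expression per-animal expression values.
#' @param genotype per-animal genotype codes in `{0, 1, 2}` (count of
#'   alternate-strain alleles), same animal ordering.
#' @return A one-row `data.frame`: `lod`, `additive_effect`.
#' @export
marker_regression <- function(expression, genotype) {
  if (length(expression) != length(genotype))
    stop("marker_regression: length mismatch")
  if (anyNA(expression) || anyNA(genotype))
    stop("marker_regression: missing values are not supported")
  if (any(!genotype %in% 0:2))
    stop("marker_regression: genotype codes must be 0, 1, 2")
  n <- length(expression)
  y <- expression
  g <- genotype - 1
  rss0 <- sum((y - mean(y))^2)
  if (rss0 == 0 || stats::var(g) == 0)
    return(data.frame(lod = 0, additive_effect = 0))
  slope <- stats::cov(y, g) / stats::var(g)
  resid <- y - mean(y) - slope * (g - mean(g))
  rss1 <- sum(resid^2)
  rss1 <- max(rss1, rss0 * .Machine$double.eps)  # guard noise-free fits
  data.frame(lod = (n / 2) * log10(rss0 / rss1), additive_effect = slope)
}

#' Map cis-eQTL for every gene at its own locus
#'
#' Runs [marker_regression()] for each gene against the genotype of the
#' marker at the gene's locus.
#'
#' @param expr numeric matrix, genes x animals (rownames = gene ids).
#' @param geno integer matrix, animals x loci (colnames = locus ids).
#' @param gene_locus named character vector mapping gene id -> locus id;
#'   defaults to identity (gene ids are locus ids).
#' @param excluded_genes gene ids excluded for probe-SNP overlap.
#' @return A `data.frame` with `gene_id`, `lod`, `additive_effect`,
#'   `excluded_probe_snp`.
#' @export
map_cis_eqtl <- function(expr, geno, gene_locus = NULL,
                         excluded_genes = character()) {
  gids <- rownames(expr)
  if (is.null(gids)) stop("map_cis_eqtl: expr needs gene ids as rownames")
  if (is.null(gene_locus))
    gene_locus <- stats::setNames(gids, gids)
  fits <- lapply(gids, function(g) {
    marker_regression(expr[g, ], geno[, gene_locus[[g]]])
  })
  out <- do.call(rbind, fits)
  out <- cbind(data.frame(gene_id = gids, stringsAsFactors = FALSE), out)
  out$excluded_probe_snp <- out$gene_id %in% excluded_genes
  rownames(out) <- NULL
  out
}

#' Call cis-eQTL genes
#'
#' @param results output of [map_cis_eqtl()] (or any `data.frame` with
#'   `gene_id`, `lod`, `additive_effect`, `excluded_probe_snp`).
#' @param lod_threshold keep genes with `lod > lod_threshold` (default 3).
#' @param effect_threshold keep genes with `|additive_effect|` above this
#'   (default 0).
#' @return The called subset (probe-SNP-excluded genes removed).
#' @export
call_cis <- function(results, lod_threshold = 3.0, effect_threshold = 0.0) {
  keep <- results$lod > lod_threshold &
    abs(results$additive_effect) > effect_threshold &
    !results$excluded_probe_snp
  out <- results[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag genes whose microarray probes overlap a SNP
#'
#' A SNP under a probe perturbs hybridization and can fake a cis-eQTL, so
#' such genes are excluded from array-based calling. Probe intervals are
#' half-open `[start, end)` in the same 0-based coordinate system as
#' `pos_to_interval(snp$pos)`; a probe contains a SNP when
#' `start <= pos0 < end`.
#'
#' @param probes `data.frame` with `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param snps a SNP table.
#' @return Character vector of excluded gene ids.
#' @export
flag_probe_snp_overlap <- function(probes, snps) {
  if (nrow(probes) == 0 || nrow(snps) == 0) return(character())
  pos0 <- pos_to_interval(snps$pos)[, "start"]
  hit <- vapply(seq_len(nrow(probes)), function(i) {
    any(snps$chrom == probes$chrom[i] &
          pos0 >= probes$start[i] & pos0 < probes$end[i])
  }, TRUE)
  unique(probes$gene_id[hit])
}

#' Pool null reference-allele fraction
#'
#' The expected reference (B6) allele proportion among pooled transcripts
#' at a locus, from the pooled animals' genotype codes (count of alternate
#' alleles): `p0 = 1 - sum(codes) / (2 * pool size)`. Values outside
#' `[0.01, 0.99]` are clamped with a warning - a (nearly) monomorphic pool
#' cannot support ASE testing.
#'
#' @param codes genotype codes in `{0, 1, 2}` of the pooled animals.
#' @return `p0` in `[0.01, 0.99]`.
#' @export
pool_null_fraction <- function(codes) {
  if (length(codes) == 0) stop("pool_null_fraction: empty pool")
  if (any(!codes %in% 0:2))
    stop("pool_null_fraction: genotype codes must be 0, 1, 2")
  p0 <- 1 - sum(codes) / (2 * length(codes))
  if (p0 < 0.01 || p0 > 0.99) {
    warning("pool_null_fraction: p0 = ", signif(p0, 3),
            " clamped to [0.01, 0.99] (monomorphic pool)")
    p0 <- min(max(p0, 0.01), 0.99)
  }
  p0
}
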