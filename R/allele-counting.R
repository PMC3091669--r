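#' Counting filters
#'
#' Filter settings applied when turning read observations into per-SNP allele
#' counts. Defaults follow the pooled-cross analysis: sites whose mean phred
#' quality falls below 20 are unreliable; the ordered SNP classes C/A, A/C
#' and G/T carry excess reference-mismatch error and are dropped; only
#' unique (or unique-anchored) alignments are counted.
#'
#' @param min_mean_quality drop SNPs whose mean phred over contributing reads
#'   is below this (default 20).
#' @param exclude_snp_types drop error-prone SNP classes (default `TRUE`).
#' @param require_unique drop non-unique alignments (default `TRUE`).
#' @param orientation_match at gene aggregation, keep only counts on the
#'   gene's annotated strand (default `TRUE`).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_mean_quality = 20, exclude_snp_types = TRUE,
                          require_unique = TRUE, orientation_match = TRUE) {
  if (min_mean_quality < 0) stop("min_mean_quality must be >= 0")
  structure(list(min_mean_quality = min_mean_quality,
                 exclude_snp_types = exclude_snp_types,
                 require_unique = require_unique,
                 orientation_match = orientation_match),
            class = "filter_config")
}

#' Count alleles per SNP and strand
#'
#' Joins observations to the SNP table by `(chrom, pos)` and tallies, per
#' SNP and genomic strand, the reads whose base matches the reference (B6)
#' or alternate allele. Bases matching neither allele (including `N`) are
#' discarded and reported in the `n_mismatch` attribute. The mean-quality
#' filter is evaluated per site over all contributing (allele-matching)
#' reads on both strands, before the strand split. Observations at positions
#' absent from the SNP table are skipped with a warning and counted in the
#' `n_skipped` attribute. With every filter disabled the result is the raw
#' allele tally.
#'
#' @param obs an observations `data.frame` ([observations()]).
#' @param snps a SNP table ([snp_table()]).
#' @param config a [filter_config()].
#' @return A `data.frame` with columns `chrom`, `pos`, `strand`,
#'   `ref_count`, `alt_count`, `mean_quality` and attributes `n_mismatch`,
#'   `n_skipped`.
#' @export
count_alleles <- function(obs, snps, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  empty <- data.frame(chrom = character(), pos = integer(),
                      strand = character(), ref_count = integer(),
                      alt_count = integer(), mean_quality = numeric(),
                      stringsAsFactors = FALSE)
  skey <- paste(snps$chrom, snps$pos)
  okey <- paste(obs$chrom, obs$pos)
  idx <- match(okey, skey)
  n_skipped <- sum(is.na(idx))
  if (n_skipped > 0)
    warning("count_alleles: ", n_skipped,
            " observation(s) at positions absent from the SNP table; skipped")
  keep <- !is.na(idx)
  obs <- obs[keep, , drop = FALSE]; idx <- idx[keep]
  if (config$require_unique) obs <- obs[obs$unique, , drop = FALSE]
  idx <- match(paste(obs$chrom, obs$pos), skey)
  if (config$exclude_snp_types) {
    keep <- !snps$excluded_type[idx]
    obs <- obs[keep, , drop = FALSE]; idx <- idx[keep]
  }
  if (nrow(obs) == 0) {
    attr(empty, "n_mismatch") <- 0L
    attr(empty, "n_skipped") <- n_skipped
    return(empty)
  }
  is_ref <- obs$base == snps$ref_allele[idx]
  is_alt <- obs$base == snps$alt_allele[idx]
  n_mismatch <- sum(!is_ref & !is_alt)
  contrib <- is_ref | is_alt
  obs <- obs[contrib, , drop = FALSE]
  idx <- idx[contrib]; is_ref <- is_ref[contrib]
  if (nrow(obs) == 0) {
    attr(empty, "n_mismatch") <- n_mismatch
    attr(empty, "n_skipped") <- n_skipped
    return(empty)
  }
  site <- paste(obs$chrom, obs$pos)
  meanq <- tapply(obs$qual, site, mean)
  if (config$min_mean_quality > 0) {
    keep_site <- names(meanq)[meanq >= config$min_mean_quality]
    keep <- site %in% keep_site
    obs <- obs[keep, , drop = FALSE]
    idx <- idx[keep]; is_ref <- is_ref[keep]; site <- site[keep]
  }
  if (nrow(obs) == 0) {
    attr(empty, "n_mismatch") <- n_mismatch
    attr(empty, "n_skipped") <- n_skipped
    return(empty)
  }
  key <- paste(site, obs$strand)
  agg <- data.frame(
    chrom = tapply(obs$chrom, key, `[`, 1),
    pos = as.integer(tapply(obs$pos, key, `[`, 1)),
    strand = tapply(obs$strand, key, `[`, 1),
    ref_count = as.integer(tapply(is_ref, key, sum)),
    alt_count = as.integer(tapply(!is_ref, key, sum)),
    stringsAsFactors = FALSE
  )
  agg$mean_quality <- as.numeric(meanq[paste(agg$chrom, agg$pos)])
  agg <- agg[order(agg$chrom, agg$pos, agg$strand), , drop = FALSE]
  rownames(agg) <- NULL
  attr(agg, "n_mismatch") <- n_mismatch
  attr(agg, "n_skipped") <- n_skipped
  agg
}

#' Aggregate per-SNP counts to genes
#'
#' Sums strand-resolved per-SNP counts over each gene's transcript span
#' (introns included), keeping only counts on the gene's annotated strand
#' when `orientation_match` is set. A read overlapping several SNPs
#' contributes one count unit per SNP (per-SNP sums are added). Genes are
#' accepted only when they reach `min_reads` total allele-specific count
#' units over at least `min_snps` informative SNPs, and when a strict
#' majority of the non-abstaining SNPs agree on the direction of strain
#' bias. The per-SNP direction vote is the sign of
#' `ref_count * (1 - p0) - alt_count * p0`; SNPs at the exact null ratio
#' abstain. Rejected genes are reported with a rejection reason rather than
#' silently dropped. A SNP inside two overlapping same-strand genes
#' contributes to both (flagged via the `shared_snps` column).
#'
#' @param counts per-SNP counts from [count_alleles()].
#' @param genes gene models ([gene_models()]).
#' @param p0 null reference-allele fraction: a single value (0.5 for an F1)
#'   or a named vector keyed by `gene_id` (pool-derived, per locus).
#' @param min_reads minimum total count units per gene (default 10).
#' @param min_snps minimum informative SNPs per gene (default 3).
#' @param orientation_match keep only counts on the gene strand
#'   (default `TRUE`).
#' @return A `data.frame` with one row per gene: `gene_id`, `total_ref`,
#'   `total_alt`, `n_snps_informative`, `n_snps_agreeing`, `shared_snps`,
#'   `accepted`, `reject_reason`.
#' @export
aggregate_to_gene <- function(counts, genes, p0 = 0.5, min_reads = 10,
                              min_snps = 3, orientation_match = TRUE) {
  p0_for <- function(gid) {
    v <- if (length(p0) == 1L && is.null(names(p0))) p0
         else unname(p0[gid])
    if (is.na(v) || v <= 0 || v >= 1)
      stop("aggregate_to_gene: p0 for gene ", gid, " must be in (0, 1)")
    v
  }
  snp_key <- paste(counts$chrom, counts$pos)
  snp_gene_hits <- integer(length(snp_key))  # per unique site, genes hit
  rows <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    inside <- gene_contains(genes, i, counts$chrom, counts$pos)
    if (orientation_match) inside <- inside & counts$strand == genes$strand[i]
    sub <- counts[inside, , drop = FALSE]
    snp_gene_hits[inside] <- snp_gene_hits[inside] + 1L
    if (nrow(sub) == 0) {
      rows[[i]] <- data.frame(gene_id = gid, total_ref = 0L, total_alt = 0L,
                              n_snps_informative = 0L, n_snps_agreeing = 0L,
                              accepted = FALSE,
                              reject_reason = "no_informative_snps",
                              stringsAsFactors = FALSE)
      next
    }
    # collapse strands within a site (relevant when orientation_match = FALSE)
    site <- paste(sub$chrom, sub$pos)
    ref_by <- tapply(sub$ref_count, site, sum)
    alt_by <- tapply(sub$alt_count, site, sum)
    p <- p0_for(gid)
    vote <- sign(ref_by * (1 - p) - alt_by * p)
    n_snps <- length(ref_by)
    total <- sum(ref_by) + sum(alt_by)
    voting <- vote[vote != 0]
    n_agree <- if (length(voting)) max(sum(voting > 0), sum(voting < 0)) else 0L
    reason <- NA_character_
    if (n_snps < min_snps) reason <- "min_snps"
    else if (total < min_reads) reason <- "min_reads"
    else if (!(length(voting) > 0 && n_agree > length(voting) / 2))
      reason <- "no_majority_direction"
    rows[[i]] <- data.frame(gene_id = gid,
                            total_ref = as.integer(sum(ref_by)),
                            total_alt = as.integer(sum(alt_by)),
                            n_snps_informative = as.integer(n_snps),
                            n_snps_agreeing = as.integer(n_agree),
                            accepted = is.na(reason),
                            reject_reason = reason,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  shared <- unique(snp_key[snp_gene_hits > 1L])
  out$shared_snps <- vapply(seq_len(nrow(genes)), function(i) {
    inside <- gene_contains(genes, i, counts$chrom, counts$pos)
    sum(unique(snp_key[inside]) %in% shared)
  }, 0L)
  out <- out[, c("gene_id", "total_ref", "total_alt", "n_snps_informative",
                 "n_snps_agreeing", "shared_snps", "accepted",
                 "reject_reason")]
  rownames(out) <- NULL
  out
}
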