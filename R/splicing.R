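#' Tabulate allele counts per alternative splice junction
#'
#' Collects junction-spanning reads that also cover a SNP, keeps only
#' reads oriented like the spliced transcript, and tallies reference /
#' alternate allele counts separately for the exon-included and
#' exon-skipped isoforms. An event is emitted only when both isoforms are
#' represented by at least one allele-informative read. Junction reads
#' falling in no gene model are skipped with a warning.
#'
#' @param obs observations carrying `junction_id` / `isoform` labels.
#' @param snps a SNP table.
#' @param genes gene models.
#' @return A `data.frame` with `gene_id`, `junction_id`, `inc_ref`,
#'   `inc_alt`, `skip_ref`, `skip_alt`.
#' @export
junction_allele_table <- function(obs, snps, genes) {
  jx <- obs[!is.na(obs$junction_id), , drop = FALSE]
  empty <- data.frame(gene_id = character(), junction_id = character(),
                      inc_ref = integer(), inc_alt = integer(),
                      skip_ref = integer(), skip_alt = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(jx) == 0) return(empty)
  idx <- match(paste(jx$chrom, jx$pos), paste(snps$chrom, snps$pos))
  jx <- jx[!is.na(idx), , drop = FALSE]
  idx <- idx[!is.na(idx)]
  if (nrow(jx) == 0) return(empty)
  # assign each read to the gene containing its SNP, matching orientation
  gene_of <- rep(NA_character_, nrow(jx))
  for (i in seq_len(nrow(genes))) {
    hit <- gene_contains(genes, i, jx$chrom, jx$pos) & is.na(gene_of)
    gene_of[hit] <- genes$gene_id[i]
  }
  orphan <- is.na(gene_of)
  if (any(orphan)) {
    warning("junction_allele_table: ", sum(orphan),
            " junction read(s) outside any gene model; skipped")
    jx <- jx[!orphan, , drop = FALSE]; idx <- idx[!orphan]
    gene_of <- gene_of[!orphan]
  }
  if (nrow(jx) == 0) return(empty)
  sense <- jx$strand == genes$strand[match(gene_of, genes$gene_id)]
  jx <- jx[sense, , drop = FALSE]; idx <- idx[sense]
  gene_of <- gene_of[sense]
  if (nrow(jx) == 0) return(empty)
  is_ref <- jx$base == snps$ref_allele[idx]
  is_alt <- jx$base == snps$alt_allele[idx]
  keep <- is_ref | is_alt
  jx <- jx[keep, , drop = FALSE]; is_ref <- is_ref[keep]
  gene_of <- gene_of[keep]
  if (nrow(jx) == 0) return(empty)
  key <- paste(gene_of, jx$junction_id, sep = "\r")
  tall <- function(sel) as.integer(tapply(sel, key, sum))
  inc <- jx$isoform == "included"
  out <- data.frame(
    gene_id = sub("\r.*$", "", sort(unique(key))),
    junction_id = sub("^.*\r", "", sort(unique(key))),
    inc_ref = tall(is_ref & inc), inc_alt = tall(!is_ref & inc),
    skip_ref = tall(is_ref & !inc), skip_alt = tall(!is_ref & !inc),
    stringsAsFactors = FALSE
  )
  out <- out[(out$inc_ref + out$inc_alt) >= 1 &
               (out$skip_ref + out$skip_alt) >= 1, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Allele-specific splicing bound
#'
#' Upper bound on the probability that the allelic split of the minor
#' isoform (the one with fewer reads overall) arose without allele-
#' specific splicing: the one-sided exact binomial tail of the minor
#' isoform's (reference, total) counts at `p0 = 0.5`, taken in the
#' direction of its observed bias (the smaller single tail). Restricting
#' to the minor isoform makes the statistic a conservative "p(ASE) is
#' less than" bound. On a total-read tie the more balanced isoform is
#' used and the event flagged.
#'
#' @param inc_ref,inc_alt included-isoform allele counts (total >= 1).
#' @param skip_ref,skip_alt skipped-isoform allele counts (total >= 1).
#' @return A `data.frame` with `p_bound`, `minor_isoform`
#'   (`"included"`/`"skipped"`) and `tie` (logical), vectorized over the
#'   inputs.
#' @examples
#' splicing_ase_bound(2, 4, 232, 197)$p_bound  # 0.344 (Slc8a1-like)
#' @export
splicing_ase_bound <- function(inc_ref, inc_alt, skip_ref, skip_alt) {
  n_inc <- inc_ref + inc_alt
  n_skip <- skip_ref + skip_alt
  if (any(n_inc < 1) || any(n_skip < 1))
    stop("splicing_ase_bound: both isoforms must have >= 1 read")
  tie <- n_inc == n_skip
  balance_inc <- abs(inc_ref / n_inc - 0.5)
  balance_skip <- abs(skip_ref / n_skip - 0.5)
  use_inc <- ifelse(tie, balance_inc <= balance_skip, n_inc < n_skip)
  k <- ifelse(use_inc, inc_ref, skip_ref)
  n <- ifelse(use_inc, n_inc, n_skip)
  data.frame(
    p_bound = binomial_tail_p(k, n, 0.5),
    minor_isoform = ifelse(use_inc, "included", "skipped"),
    tie = tie,
    stringsAsFactors = FALSE
  )
}

#' Score splicing events
#'
#' Applies [splicing_ase_bound()] to a junction allele table.
#'
#' @param events output of [junction_allele_table()].
#' @return The table with `p_bound`, `minor_isoform`, `tie` appended.
#' @export
splicing_events <- function(events) {
  if (nrow(events) == 0) {
    events$p_bound <- numeric(0)
    events$minor_isoform <- character(0)
    events$tie <- logical(0)
    return(events)
  }
  cbind(events, splicing_ase_bound(events$inc_ref, events$inc_alt,
                                   events$skip_ref, events$skip_alt))
}
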