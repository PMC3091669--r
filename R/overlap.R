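#' Expected null overlap between ASE and cis-eQTL gene lists
#'
#' Under independence, the expected number of genes called by both the
#' array (cis-eQTL) and sequencing (ASE) stages *with the same directional
#' bias* is `(n_array / n_all) * (n_seq / n_all) * n_all * 1/2`: the
#' product of the two marginal rates times the total, halved because two
#' independent signs agree half the time. Multiply by 2 for the expected
#' overlap regardless of direction.
#'
#' @param n_array genes exceeding the array (additive-effect) threshold.
#' @param n_seq genes exceeding the sequencing (LBP) threshold.
#' @param n_all total testable genes.
#' @return Expected same-direction overlap count.
#' @examples
#' expected_overlap(100, 80, 1000)  # 4
#' @export
expected_overlap <- function(n_array, n_seq, n_all) {
  if (n_all <= 0) stop("expected_overlap: n_all must be positive")
  if (n_array < 0 || n_seq < 0 || n_array > n_all || n_seq > n_all)
    stop("expected_overlap: margins must be within [0, n_all]")
  n_array * n_seq / (2 * n_all)
}

#' Observed/expected overlap enrichment across threshold grids
#'
#' For every pair of thresholds (one on the cis-eQTL additive effect, one
#' on the ASE `|lbp|`), counts the genes called by each stage, the genes
#' called by both, how many of those agree on the direction of allelic
#' bias (sign of `lbp` vs sign of `additive_effect`), and the ratio of the
#' same-direction overlap to its independence expectation. Genes with
#' `lbp` exactly 0 carry no direction and are excluded from the agreement
#' denominator.
#'
#' @param eqtl `data.frame` with `gene_id`, `additive_effect` (and
#'   optionally pre-filtered by LOD / probe exclusion).
#' @param ase `data.frame` with `gene_id`, `lbp`.
#' @param effect_thresholds,lbp_thresholds numeric threshold axes
#'   (non-empty).
#' @param n_all total testable genes.
#' @return A long-format `data.frame`, one row per grid cell:
#'   `effect_threshold`, `lbp_threshold`, `n_array`, `n_seq`, `n_overlap`,
#'   `n_overlap_same_direction`, `expected_same_direction`, `ratio`,
#'   `direction_agreement`.
#' @export
enrichment_grid <- function(eqtl, ase, effect_thresholds, lbp_thresholds,
                            n_all) {
  if (length(effect_thresholds) == 0 || length(lbp_thresholds) == 0)
    stop("enrichment_grid: empty threshold axis")
  cells <- expand.grid(effect_threshold = sort(effect_thresholds),
                       lbp_threshold = sort(lbp_thresholds))
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    et <- cells$effect_threshold[i]; lt <- cells$lbp_threshold[i]
    arr <- eqtl[abs(eqtl$additive_effect) > et, , drop = FALSE]
    seq_ <- ase[abs(ase$lbp) > lt, , drop = FALSE]
    both <- intersect(arr$gene_id, seq_$gene_id)
    s_arr <- sign(arr$additive_effect[match(both, arr$gene_id)])
    s_seq <- sign(seq_$lbp[match(both, seq_$gene_id)])
    directed <- s_seq != 0
    n_same <- sum(directed & s_arr == s_seq)
    expct <- expected_overlap(nrow(arr), nrow(seq_), n_all)
    data.frame(
      effect_threshold = et, lbp_threshold = lt,
      n_array = nrow(arr), n_seq = nrow(seq_),
      n_overlap = length(both),
      n_overlap_same_direction = n_same,
      expected_same_direction = expct,
      ratio = if (expct > 0) n_same / expct else NA_real_,
      direction_agreement = if (sum(directed) > 0)
        n_same / sum(directed) else NA_real_
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fisher exact test for gene-list overlap
#'
#' One-sided (enrichment) hypergeometric p-value for the 2x2 membership
#' table of two gene lists.
#'
#' @param n_both,n_array_only,n_seq_only,n_neither non-negative cell
#'   counts.
#' @return The one-sided p-value.
#' @export
fisher_overlap <- function(n_both, n_array_only, n_seq_only, n_neither) {
  tab <- matrix(c(n_both, n_array_only, n_seq_only, n_neither), 2, 2)
  if (any(tab < 0)) stop("fisher_overlap: negative cell")
  stats::fisher.test(tab, alternative = "greater")$p.value
}
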