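#' Per-read allele observations over SNPs
#'
#' A read observation records what one aligned read reports at one SNP: the
#' observed base, its phred quality, the genomic strand the read aligned to,
#' whether the alignment is usable ("unique": uniquely aligned, or
#' redundantly mapped but anchored by unique reads), and - for reads spanning
#' a splice junction - the junction identifier and which isoform the read
#' supports (`included` or `skipped`).
#'
#' @param read_id read identifiers.
#' @param chrom,pos SNP coordinates (1-based).
#' @param strand `"+"` or `"-"`.
#' @param base observed base, one of `A`, `C`, `G`, `T`, `N`.
#' @param qual phred base quality (integer >= 0).
#' @param unique logical; alignment uniqueness flag.
#' @param junction_id junction identifier or `NA`.
#' @param isoform `"included"`, `"skipped"`, or `NA`; must be `NA` exactly
#'   when `junction_id` is `NA`.
#' @return A `data.frame` with the nine observation columns.
#' @export
observations <- function(read_id, chrom, pos, strand, base, qual,
                         unique = TRUE, junction_id = NA_character_,
                         isoform = NA_character_) {
  n <- length(read_id)
  df <- data.frame(
    read_id = as.character(read_id),
    chrom = as.character(chrom),
    pos = as.integer(pos),
    strand = as.character(strand),
    base = toupper(as.character(base)),
    qual = as.integer(qual),
    unique = as.logical(unique),
    junction_id = rep_len(as.character(junction_id), n),
    isoform = rep_len(as.character(isoform), n),
    stringsAsFactors = FALSE
  )
  if (n > 0) {
    if (any(!df$strand %in% c("+", "-")))
      stop("observations: strand must be '+' or '-'")
    if (any(!df$base %in% c("A", "C", "G", "T", "N")))
      stop("observations: base must be one of A, C, G, T, N")
    if (anyNA(df$qual) || any(df$qual < 0L))
      stop("observations: qual must be a non-negative integer")
    if (anyNA(df$unique)) stop("observations: unique must be TRUE/FALSE")
    has_j <- !is.na(df$junction_id)
    if (any(has_j & !df$isoform %in% c("included", "skipped")) ||
        any(!has_j & !is.na(df$isoform)))
      stop("observations: isoform must be included/skipped iff junction_id set")
  }
  df
}

obs_cols <- c("read_id", "chrom", "pos", "strand", "base", "qual",
              "unique", "junction_id", "isoform")

#' Read observations from the TSV dialect or a SAM file
#'
#' The TSV dialect (the package's interchange format for per-read allele
#' evidence) has the columns `read_id`, `chrom`, `pos`, `strand`, `base`,
#' `qual`, `unique`, `junction_id`, `isoform`, with `NA` for absent junction
#' fields. For SAM input, reads are intersected with the supplied SNP table
#' and the aligned base and quality at each overlapped SNP are extracted from
#' the alignment (CIGAR-aware); uniqueness is taken as MAPQ >= 1 and junction
#' fields are left `NA` (junction/isoform labels are carried by the TSV
#' dialect only).
#'
#' @param path input file.
#' @param format `"tsv"` or `"sam"`.
#' @param snps SNP table; required for `format = "sam"`.
#' @return An observations `data.frame` (see [observations()]).
#' @export
read_observations <- function(path, format = c("tsv", "sam"), snps = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_observations: no such file: ", path)
  if (format == "tsv") {
    df <- read_tsv_checked(path, required = obs_cols)
    if (nrow(df) == 0)
      return(observations(character(), character(), integer(), character(),
                          character(), integer()))
    qual <- suppressWarnings(as.integer(df$qual))
    if (anyNA(qual))
      stop("read_observations: missing or malformed qual at line ",
           which(is.na(qual))[1] + 1L)
    jid <- df$junction_id
    jid[jid %in% c("", "NA", ".")] <- NA_character_
    iso <- df$isoform
    iso[iso %in% c("", "NA", ".")] <- NA_character_
    observations(df$read_id, df$chrom, as.integer(df$pos), df$strand,
                 df$base, qual, toupper(df$unique) %in% c("TRUE", "T", "1"),
                 jid, iso)
  } else {
    if (is.null(snps))
      stop("read_observations: SAM input requires a SNP table")
    read_observations_sam(path, snps)
  }
}

# Extract per-read base/quality at SNP positions from a SAM file.
# Relies on Rsamtools for parsing and on CIGAR reference/query-space ranges
# for the coordinate mapping; insertions/deletions/clips are handled, reads
# whose alignment gaps (N/D) span the SNP contribute nothing.
read_observations_sam <- function(path, snps) {
  bam <- Rsamtools::asBam(path,
    destination = tempfile(fileext = ""), overwrite = TRUE,
    indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  param <- Rsamtools::ScanBamParam(what = c("qname", "seq", "qual", "mapq"))
  aln <- GenomicAlignments::readGAlignments(bam, param = param)
  if (length(aln) == 0)
    return(observations(character(), character(), integer(), character(),
                        character(), integer()))
  snp_gr <- GenomicRanges::GRanges(snps$chrom,
                                   IRanges::IRanges(snps$pos, snps$pos))
  hits <- GenomicRanges::findOverlaps(snp_gr, GenomicRanges::granges(aln),
                                      ignore.strand = TRUE)
  if (length(hits) == 0)
    return(observations(character(), character(), integer(), character(),
                        character(), integer()))
  si <- S4Vectors::queryHits(hits)
  ai <- S4Vectors::subjectHits(hits)
  cig <- GenomicAlignments::cigar(aln)[ai]
  astart <- GenomicRanges::start(GenomicRanges::granges(aln))[ai]
  ops <- c("M", "=", "X")
  rblocks <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cig, pos = astart, ops = ops)
  qblocks <- GenomicAlignments::cigarRangesAlongQuerySpace(
    cig, ops = ops, after.soft.clipping = FALSE)
  seqs <- as.character(S4Vectors::mcols(aln)$seq)[ai]
  quals <- as.character(S4Vectors::mcols(aln)$qual)[ai]
  keep <- logical(length(si))
  base <- character(length(si))
  qual <- integer(length(si))
  for (i in seq_along(si)) {
    p <- snps$pos[si[i]]
    rb <- rblocks[[i]]
    j <- which(IRanges::start(rb) <= p & IRanges::end(rb) >= p)
    if (length(j) != 1L) next  # SNP falls in a deletion or skip
    qpos <- IRanges::start(qblocks[[i]])[j] + (p - IRanges::start(rb)[j])
    keep[i] <- TRUE
    base[i] <- substr(seqs[i], qpos, qpos)
    qual[i] <- utf8ToInt(substr(quals[i], qpos, qpos)) - 33L
  }
  si <- si[keep]; ai <- ai[keep]
  observations(
    read_id = S4Vectors::mcols(aln)$qname[ai],
    chrom = snps$chrom[si], pos = snps$pos[si],
    strand = as.character(GenomicRanges::strand(aln))[ai],
    base = base[keep], qual = qual[keep],
    unique = S4Vectors::mcols(aln)$mapq[ai] >= 1L
  )
}

#' Write observations in the TSV dialect
#'
#' @param obs an observations `data.frame`.
#' @param path output path.
#' @export
write_observations <- function(obs, path) {
  utils::write.table(obs[, obs_cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
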