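#' Strain-distinguishing SNP tables
#'
#' A SNP table holds the variant sites that distinguish the reference strain
#' (B6) from the alternate strain (BTBR or CAST). Each row is one biallelic
#' site; the `ref_allele` is the base carried by the reference strain and
#' `alt_allele` the base carried by the alternate strain. The ordered allele
#' pairs C/A, A/C and G/T are flagged as `excluded_type`: these substitution
#' classes show disproportionate reference-mismatch error in Illumina data
#' and are dropped by the default counting filters.
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 1-based positions.
#' @param ref_allele,alt_allele single-base alleles in `A`, `C`, `G`, `T`.
#' @return A `data.frame` with columns `chrom`, `pos`, `ref_allele`,
#'   `alt_allele`, `excluded_type`, sorted by `(chrom, pos)`.
#' @examples
#' snp_table("chr1", 100L, "G", "T")$excluded_type  # TRUE: error-prone class
#' @export
snp_table <- function(chrom, pos, ref_allele, alt_allele) {
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  ref_allele <- toupper(as.character(ref_allele))
  alt_allele <- toupper(as.character(alt_allele))
  n <- max(length(chrom), length(pos), length(ref_allele),
           length(alt_allele))
  recyc <- function(x) if (length(x) == 1L) rep(x, n) else x
  chrom <- recyc(chrom); pos <- recyc(pos)
  ref_allele <- recyc(ref_allele); alt_allele <- recyc(alt_allele)
  if (length(chrom) != n || length(pos) != n || length(ref_allele) != n ||
      length(alt_allele) != n)
    stop("snp_table: all columns must have equal length")
  if (n > 0) {
    bad <- !(ref_allele %in% c("A", "C", "G", "T")) |
      !(alt_allele %in% c("A", "C", "G", "T"))
    if (any(bad))
      stop("snp_table: non-ACGT allele at record(s) ",
           paste(which(bad), collapse = ", "))
    if (any(ref_allele == alt_allele))
      stop("snp_table: ref_allele must differ from alt_allele")
    if (any(pos < 1L)) stop("snp_table: pos must be >= 1")
    key <- paste(chrom, pos)
    if (anyDuplicated(key))
      stop("snp_table: duplicate (chrom, pos): ",
           paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  out <- data.frame(
    chrom = chrom, pos = pos,
    ref_allele = ref_allele, alt_allele = alt_allele,
    excluded_type = is_excluded_snp_type(ref_allele, alt_allele),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname snp_table
#' @details `is_excluded_snp_type()` is a pure function of the ordered
#'   (ref, alt) pair: only C/A, A/C and G/T are excluded (not T/G).
#' @export
is_excluded_snp_type <- function(ref_allele, alt_allele) {
  (ref_allele == "C" & alt_allele == "A") |
    (ref_allele == "A" & alt_allele == "C") |
    (ref_allele == "G" & alt_allele == "T")
}

#' Read a SNP table from VCF or TSV
#'
#' The TSV dialect has columns `chrom`, `pos`, `ref_allele`, `alt_allele`
#' (header required). VCF input is a sites-only VCF 4.x; multi-allelic or
#' non-SNP records are rejected.
#'
#' @param path file path.
#' @param format `"tsv"` or `"vcf"`.
#' @return A SNP table as from [snp_table()].
#' @export
read_snp_table <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_snp_table: no such file: ", path)
  if (format == "tsv") {
    df <- read_tsv_checked(path,
      required = c("chrom", "pos", "ref_allele", "alt_allele"))
    if (nrow(df) == 0)
      return(snp_table(character(), integer(), character(), character()))
    pos <- suppressWarnings(as.integer(df$pos))
    if (anyNA(pos))
      stop("read_snp_table: malformed pos at line ",
           which(is.na(pos))[1] + 1L, " of ", path)
    snp_table(df$chrom, pos, df$ref_allele, df$alt_allele)
  } else {
    v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
    fix <- vcfR::getFIX(v)
    if (is.null(fix) || nrow(fix) == 0)
      return(snp_table(character(), integer(), character(), character()))
    fix <- as.data.frame(fix, stringsAsFactors = FALSE)
    if (any(nchar(fix$REF) != 1L | nchar(fix$ALT) != 1L | grepl(",", fix$ALT)))
      stop("read_snp_table: VCF contains non-SNP or multi-allelic records")
    snp_table(fix$CHROM, as.integer(fix$POS), fix$REF, fix$ALT)
  }
}

#' Write a SNP table in the TSV dialect
#'
#' @param snps a SNP table.
#' @param path output path.
#' @export
write_snp_table <- function(snps, path) {
  utils::write.table(
    snps[, c("chrom", "pos", "ref_allele", "alt_allele")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Coordinate conversion between 1-based positions and half-open intervals
#'
#' A SNP at 1-based position `p` (VCF/GTF convention) occupies the 0-based
#' half-open interval `[p - 1, p)` (BED convention). These converters are the
#' single place the package changes coordinate systems; all interval
#' containment tests use the half-open convention.
#'
#' @param pos 1-based positions.
#' @return `pos_to_interval`: a two-column matrix (`start`, `end`), 0-based
#'   half-open. `interval_to_pos`: the 1-based position of a width-1 interval.
#' @export
pos_to_interval <- function(pos) {
  cbind(start = as.integer(pos) - 1L, end = as.integer(pos))
}

#' @rdname pos_to_interval
#' @param start,end 0-based half-open bounds with `end == start + 1`.
#' @export
interval_to_pos <- function(start, end) {
  if (any(end != start + 1L)) stop("interval_to_pos: not width-1 intervals")
  as.integer(start) + 1L
}

# Shared strict TSV reader: header must contain `required`; all-blank files
# yield a zero-row frame with the required columns.
read_tsv_checked <- function(path, required) {
  if (file.size(path) == 0)
    return(stats::setNames(
      as.data.frame(replicate(length(required), character(0),
                              simplify = FALSE)), required))
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t",
                      colClasses = "character", comment.char = "",
                      quote = "", check.names = FALSE),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  df
}
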