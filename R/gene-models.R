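#' Gene models
#'
#' A gene model is the transcript span and exon structure used to assign SNP
#' counts to genes. Spans and exons are stored 0-based half-open (BED
#' convention); [read_gene_models()] converts from each format's native
#' convention at the boundary. Allele counts are aggregated over the whole
#' span (introns included), so the exon structure matters only for
#' junction-level analyses.
#'
#' @param gene_id gene identifiers (unique).
#' @param chrom chromosome names.
#' @param strand `"+"` or `"-"`.
#' @param start,end 0-based half-open transcript span.
#' @param exons optional list of two-column matrices (`start`, `end`),
#'   0-based half-open, sorted, non-overlapping, within the span. Defaults
#'   to the single-exon span.
#' @return A `data.frame` with an `exons` list-column.
#' @export
gene_models <- function(gene_id, chrom, strand, start, end, exons = NULL) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id)) stop("gene_models: duplicate gene_id")
  start <- as.integer(start); end <- as.integer(end)
  if (any(end <= start)) stop("gene_models: end must exceed start")
  if (any(!strand %in% c("+", "-"))) stop("gene_models: bad strand")
  if (is.null(exons))
    exons <- Map(function(s, e) cbind(start = s, end = e), start, end)
  stopifnot(length(exons) == length(gene_id))
  for (i in seq_along(exons)) {
    ex <- exons[[i]]
    if (nrow(ex) == 0) stop("gene_models: gene with no exons: ", gene_id[i])
    if (any(ex[, 1] < start[i]) || any(ex[, 2] > end[i]))
      stop("gene_models: exon outside span for ", gene_id[i])
    if (is.unsorted(ex[, 1], strictly = TRUE) && nrow(ex) > 1)
      stop("gene_models: exons must be sorted for ", gene_id[i])
    if (nrow(ex) > 1 && any(ex[-nrow(ex), 2] > ex[-1, 1]))
      stop("gene_models: overlapping exons for ", gene_id[i])
  }
  out <- data.frame(gene_id = gene_id, chrom = as.character(chrom),
                    strand = as.character(strand),
                    start = start, end = end, stringsAsFactors = FALSE)
  out$exons <- exons
  out
}

#' Read gene models from BED12 or GTF
#'
#' Parsing is delegated to `rtracklayer`; coordinates are converted to the
#' internal 0-based half-open convention. For GTF, exon features are grouped
#' by `gene_id`.
#'
#' @param path input file.
#' @param format `"bed"` (BED12) or `"gtf"`.
#' @return A gene model `data.frame` (see [gene_models()]).
#' @export
read_gene_models <- function(path, format = c("bed", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_gene_models: no such file: ", path)
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    blocks <- if ("blocks" %in% names(S4Vectors::mcols(gr)))
      S4Vectors::mcols(gr)$blocks else NULL
    exons <- lapply(seq_along(gr), function(i) {
      if (is.null(blocks) || length(blocks[[i]]) == 0) {
        cbind(start = GenomicRanges::start(gr)[i] - 1L,
              end = GenomicRanges::end(gr)[i])
      } else {
        b <- blocks[[i]]  # block coords are relative to chromStart, 1-based
        off <- GenomicRanges::start(gr)[i] - 1L
        cbind(start = off + IRanges::start(b) - 1L,
              end = off + IRanges::end(b))
      }
    })
    gene_models(S4Vectors::mcols(gr)$name, as.character(GenomicRanges::seqnames(gr)),
                as.character(GenomicRanges::strand(gr)),
                GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr), exons)
  } else {
    gr <- rtracklayer::import(path, format = "GTF")
    gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
    if (length(gr) == 0) stop("read_gene_models: GTF has no exon features")
    ids <- as.character(S4Vectors::mcols(gr)$gene_id)
    sp <- split(seq_along(gr), ids)
    build <- lapply(sp, function(idx) {
      s <- GenomicRanges::start(gr)[idx] - 1L
      e <- GenomicRanges::end(gr)[idx]
      o <- order(s)
      list(chrom = as.character(GenomicRanges::seqnames(gr))[idx][1],
           strand = as.character(GenomicRanges::strand(gr))[idx][1],
           start = min(s), end = max(e),
           exons = cbind(start = s[o], end = e[o]))
    })
    gene_models(names(sp),
                vapply(build, `[[`, "", "chrom"),
                vapply(build, `[[`, "", "strand"),
                vapply(build, function(x) x$start, 0L),
                vapply(build, function(x) x$end, 0L),
                lapply(build, `[[`, "exons"))
  }
}

# TRUE where the 1-based position pos on chrom falls inside gene i's span
# (half-open test on the 0-based coordinate).
gene_contains <- function(genes, i, chrom, pos) {
  z <- as.integer(pos) - 1L
  chrom == genes$chrom[i] & z >= genes$start[i] & z < genes$end[i]
}

#' Write and re-read stage result tables
#'
#' All tabular stage outputs are written as tab-separated text with a header
#' row; numeric columns keep at least six significant digits.
#'
#' @param records a `data.frame` of homogeneous records (list-columns such as
#'   `exons` are not writable).
#' @param path output path.
#' @export
write_results_table <- function(records, path) {
  if (!is.data.frame(records)) stop("write_results_table: need a data.frame")
  if (any(vapply(records, is.list, TRUE)))
    stop("write_results_table: list-columns are not writable")
  out <- records
  num <- vapply(out, is.double, TRUE)
  out[num] <- lapply(out[num], function(x) signif(x, 15))
  status <- try(utils::write.table(out, path, sep = "\t", quote = FALSE,
                                   row.names = FALSE), silent = TRUE)
  if (inherits(status, "try-error"))
    stop("write_results_table: cannot write ", path)
  invisible(path)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  if (!file.exists(path)) stop("read_results_table: no such file: ", path)
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE)
}
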