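## Genomic intervals: plain data.frames with columns chrom/start/end[/strand],
## 0-based half-open throughout the package. Conversion to 1-based GRanges
## happens only inside overlap helpers; all file readers convert at the
## boundary.

#' Construct a validated genomic interval table
#'
#' Intervals are 0-based half-open (`start < end`). This is the internal
#' coordinate convention of the whole package; readers convert 1-based
#' formats on input.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open.
#' @param strand optional strand (`"+"`, `"-"` or `"."`).
#' @param ... further equal-length columns carried along.
#' @return A `data.frame` with class `genomic_intervals`, sorted by
#'   `(chrom, start, end)`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = NULL, ...) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end)))
    stop("non-integer interval coordinates")
  if (any(start < 0L)) stop("negative start coordinate")
  bad <- which(start >= end)
  if (length(bad))
    stop("start >= end at row ", bad[1L])
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   stringsAsFactors = FALSE)
  if (!is.null(strand)) {
    strand <- as.character(strand)
    if (!all(strand %in% c("+", "-", "."))) stop("invalid strand")
    df$strand <- strand
  }
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

#' Convert an interval table to GRanges (internal)
#'
#' @param x data.frame with chrom/start/end in 0-based half-open coordinates.
#' @return A [GenomicRanges::GRanges] (1-based closed).
#' @keywords internal
as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end))
}

#' Overlap two interval tables
#'
#' Returns the index pairs of intervals sharing at least one base.
#'
#' @param query,subject interval data.frames (0-based half-open).
#' @return data.frame with columns `query`, `subject` (row indices).
#' @export
interval_overlaps <- function(query, subject) {
  if (nrow(query) == 0L || nrow(subject) == 0L)
    return(data.frame(query = integer(), subject = integer()))
  ov <- GenomicRanges::findOverlaps(as_granges(query), as_granges(subject))
  data.frame(query = S4Vectors::queryHits(ov),
             subject = S4Vectors::subjectHits(ov))
}

#' Does each query interval overlap any subject interval?
#' @inheritParams interval_overlaps
#' @return logical vector along `query` rows.
#' @export
overlaps_any <- function(query, subject) {
  if (nrow(query) == 0L) return(logical(0))
  if (nrow(subject) == 0L) return(rep(FALSE, nrow(query)))
  IRanges::overlapsAny(as_granges(query), as_granges(subject))
}

#' Read a BED file (BED3/BED6)
#'
#' BED is already 0-based half-open, so coordinates pass through unchanged.
#' Output is sorted.
#'
#' @param path file path.
#' @return `genomic_intervals` data.frame (with `name`, `score`, `strand`
#'   when present).
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(x) < 3L) stop("BED file needs >= 3 columns: ", path)
  bad <- which(x[[2]] >= x[[3]])
  if (length(bad))
    stop("start >= end in ", path, " at line ", bad[1L])
  args <- list(chrom = x[[1]], start = x[[2]], end = x[[3]])
  if (ncol(x) >= 4L) args$name <- as.character(x[[4]])
  if (ncol(x) >= 5L) args$score <- x[[5]]
  if (ncol(x) >= 6L) args$strand <- x[[6]]
  do.call(genomic_intervals, args[c("chrom", "start", "end",
                                    setdiff(names(args),
                                            c("chrom", "start", "end")))])
}

#' Write intervals as BED
#'
#' @param x interval data.frame; extra columns after chrom/start/end are
#'   written as BED columns 4+ in their current order.
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  cols <- c("chrom", "start", "end",
            setdiff(names(x), c("chrom", "start", "end")))
  utils::write.table(as.data.frame(x)[, cols, drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read region-to-gene interaction pairs (BEDPE-derived table)
#'
#' Expected columns: chrom, start, end, gene_id (tab separated, 0-based
#' half-open), emulating anchors of ChIA-PET / promoter-DHS links collapsed
#' to region-gene pairs.
#'
#' @param path file path.
#' @return data.frame with `chrom`, `start`, `end`, `gene_id`, sorted.
#' @export
read_interactions <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "gene_id")
  if (!all(need %in% names(x)))
    stop("interaction table needs columns ", paste(need, collapse = ", "))
  bad <- which(x$start >= x$end)
  if (length(bad)) stop("start >= end in ", path, " at line ", bad[1L] + 1L)
  x <- x[order(x$chrom, x$start, x$end, x$gene_id), , drop = FALSE]
  rownames(x) <- NULL
  x
}

#' Read a TSS / gene model table
#'
#' Minimal GTF-like table with columns `gene_id`, `chrom`, `start`, `end`,
#' `tss` (all 0-based; `tss` a single position) and optional `strand`.
#'
#' @param path file path.
#' @return sorted data.frame.
#' @export
read_genes <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end", "tss")
  if (!all(need %in% names(x)))
    stop("gene table needs columns ", paste(need, collapse = ", "))
  if (anyDuplicated(x$gene_id)) stop("duplicate gene ids")
  bad <- which(x$start >= x$end)
  if (length(bad)) stop("start >= end in ", path, " at line ", bad[1L] + 1L)
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  rownames(x) <- NULL
  x
}

#' Read a genome table (chromosome sizes)
#'
#' Two tab-separated columns: chromosome name and length in bp.
#'
#' @param path file path.
#' @return named integer vector of chromosome lengths.
#' @export
read_genome <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  stats::setNames(as.integer(x[[2]]), x[[1]])
}
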