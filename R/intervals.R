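## Genomic intervals are represented throughout as 0-based half-open
## [start, end) data.frame rows (BED convention); CpG positions coming from
## coverage files are 1-based. GRanges (1-based closed) is used internally
## for overlap machinery via the converters below.

#' Construct a table of genomic intervals
#'
#' @param chrom character vector of chromosome names.
#' @param start 0-based inclusive start positions.
#' @param end 0-based exclusive end positions.
#' @param strand one of `"+"`, `"-"`, `"."` (recycled).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`.
#' @export
genomic_interval <- function(chrom, start, end, strand = ".") {
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  if (any(!nzchar(chrom))) stop("chrom must be non-empty")
  if (any(start < 0)) stop("start must be >= 0")
  if (any(start >= end)) stop("start must be < end")
  strand <- rep_len(strand, length(chrom))
  if (!all(strand %in% c("+", "-", "."))) stop("strand must be +, - or .")
  data.frame(chrom = as.character(chrom), start = as.numeric(start),
             end = as.numeric(end), strand = strand,
             stringsAsFactors = FALSE)
}

## 0-based half-open -> GRanges (1-based closed)
.as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = ifelse(df$strand == ".", "*", df$strand)
  )
}

## 1-based position contained in 0-based half-open [start, end)?
.pos_in_interval <- function(pos, start, end) pos > start & pos <= end

## total length of the union of 0-based half-open intervals on one chrom
.union_length <- function(start, end) {
  if (length(start) == 0L) return(0)
  o <- order(start)
  start <- start[o]; end <- end[o]
  tot <- 0; cs <- start[1]; ce <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] > ce) { tot <- tot + (ce - cs); cs <- start[i]; ce <- end[i] }
    else ce <- max(ce, end[i])
  }
  tot + (ce - cs)
}

#' Jaccard index between an interval and a set of intervals
#'
#' Length of intersection over length of union between one reference
#' interval and the union of a set of intervals, all 0-based half-open on
#' the same chromosome. Used to score recovery of planted regions.
#'
#' @param a_start,a_end the reference interval.
#' @param b_start,b_end vectors: the compared interval set.
#' @return Jaccard index in `[0, 1]` (0 when the set is empty).
#' @export
interval_jaccard <- function(a_start, a_end, b_start, b_end) {
  if (length(b_start) == 0L) return(0)
  inter <- sum(pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start)))
  uni <- .union_length(c(a_start, b_start), c(a_end, b_end))
  inter / uni
}
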