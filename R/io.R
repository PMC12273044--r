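## Writers: GTF annotation, BED6/TSV reports for regions, NAT pairs, CURs.

#' Write gene models as GTF
#'
#' Exon features with `gene_id`, `gene_name` and `gene_biotype` attributes;
#' round-trips through [parse_annotation()].
#'
#' @param models a [gene_models] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotation_gtf <- function(models, path) {
  ex <- models$exons
  g <- models$genes
  i <- match(ex$gene_id, g$gene_id)
  gr <- GenomicRanges::GRanges(
    ex$chrom, IRanges::IRanges(ex$start + 1L, ex$end), strand = ex$strand)
  gr$source <- "hoxmeth"
  gr$type <- "exon"
  gr$gene_id <- ex$gene_id
  gr$gene_name <- g$symbol[i]
  gr$gene_biotype <- ifelse(g$biotype[i] == "lncRNA", "lncRNA",
                            "protein_coding")
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

.write_bed6 <- function(chrom, start, end, name, score, strand, path) {
  df <- data.frame(chrom, format(start, scientific = FALSE, trim = TRUE),
                   format(end, scientific = FALSE, trim = TRUE),
                   name, score, strand)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write derived regions as BED6 plus a TSV sidecar with ordinals
#'
#' @param regions table from [derive_regions()].
#' @param bed_path,tsv_path output files (either may be `NULL` to skip).
#' @return invisibly, the paths written.
#' @export
write_regions <- function(regions, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    .write_bed6(regions$chrom, regions$start, regions$end,
                paste(regions$gene_id, regions$region_type, regions$ordinal,
                      sep = "."),
                0L, regions$strand, bed_path)
  }
  if (!is.null(tsv_path)) {
    write.table(regions, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(c(bed_path, tsv_path))
}

#' Write NAT pairs as BED6 (lncRNA spans) plus TSV
#'
#' @param nat_pairs table from [find_nat_pairs()].
#' @param models the [gene_models] the pairs came from.
#' @param bed_path,tsv_path output files (either may be `NULL` to skip).
#' @return invisibly, the paths written.
#' @export
write_nat_pairs <- function(nat_pairs, models, bed_path = NULL,
                            tsv_path = NULL) {
  if (!is.null(bed_path)) {
    g <- models$genes
    i <- match(nat_pairs$lncrna_id, g$gene_id)
    .write_bed6(g$chrom[i], g$start[i], g$end[i],
                paste(nat_pairs$lncrna_id, nat_pairs$gene_id, sep = "|"),
                nat_pairs$overlap_bp, g$strand[i], bed_path)
  }
  if (!is.null(tsv_path)) {
    write.table(nat_pairs, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(c(bed_path, tsv_path))
}

#' Report CUR calls as BED6 and TSV
#'
#' BED intervals are named `<gene_id>.CUR_<k>` with 0-based starts; the TSV
#' carries every CUR call field.
#'
#' @param calls table from [cur_scan()].
#' @param models the [gene_models] scanned.
#' @param bed_path,tsv_path output files (either may be `NULL` to skip).
#' @return invisibly, the paths written.
#' @export
cur_report <- function(calls, models, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    strand <- models$genes$strand[match(calls$gene_id, models$genes$gene_id)]
    if (nrow(calls) == 0L) strand <- character(0)
    .write_bed6(calls$chrom, calls$start, calls$end, calls$cur_id,
                round(calls$mean_pct, 2), strand, bed_path)
  }
  if (!is.null(tsv_path)) {
    write.table(calls, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(c(bed_path, tsv_path))
}
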