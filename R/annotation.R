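## Gene models, analysis regions and natural-antisense pairing.

#' Assemble a gene model set
#'
#' Builds the container used by all annotation-aware operations. Exons are
#' validated (non-overlapping within a gene) and given ordinals in transcript
#' orientation (5' to 3'); the TSS and gene span are derived.
#'
#' @param genes `data.frame` with columns `gene_id`, `symbol`, `biotype`
#'   (`"coding"` or `"lncRNA"`), `chrom`, `strand` (`"+"`/`"-"`).
#' @param exons `data.frame` with columns `gene_id`, `start`, `end`
#'   (0-based half-open genomic coordinates).
#' @param cds optional `data.frame` like `exons` giving coding intervals;
#'   when present, 5'/3' UTR regions can be derived.
#' @return An object of class `gene_models`: a list with elements `genes`
#'   (one row per gene, with `tss` 1-based, `start`, `end`, `cluster`) and
#'   `exons` (with `ordinal`), plus `cds` if supplied.
#' @export
gene_models <- function(genes, exons, cds = NULL) {
  need <- c("gene_id", "symbol", "biotype", "chrom", "strand")
  if (!all(need %in% names(genes))) {
    stop("genes must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("strandless gene model rejected: ",
         paste(genes$gene_id[!genes$strand %in% c("+", "-")], collapse = ", "))
  }
  exons <- exons[order(match(exons$gene_id, genes$gene_id), exons$start), ,
                 drop = FALSE]
  out_ex <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    ex <- exons[exons$gene_id == g$gene_id, , drop = FALSE]
    if (nrow(ex) == 0L) stop("gene without exons: ", g$gene_id)
    if (any(ex$start >= ex$end)) stop("invalid exon in gene ", g$gene_id)
    if (nrow(ex) > 1L && any(ex$start[-1] < ex$end[-nrow(ex)])) {
      stop("overlapping exons in gene ", g$gene_id)
    }
    ord <- if (g$strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
    data.frame(gene_id = g$gene_id, ordinal = ord, chrom = g$chrom,
               start = ex$start, end = ex$end, strand = g$strand,
               stringsAsFactors = FALSE)
  }))
  span <- do.call(rbind, lapply(split(out_ex, out_ex$gene_id), function(e) {
    data.frame(gene_id = e$gene_id[1], start = min(e$start), end = max(e$end))
  }))
  genes <- merge(genes, span, by = "gene_id", sort = FALSE)
  genes$tss <- ifelse(genes$strand == "+", genes$start + 1, genes$end)
  genes$cluster <- hox_cluster(genes$symbol)
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  out <- list(genes = genes, exons = out_ex)
  if (!is.null(cds) && nrow(cds) > 0L) out$cds <- cds
  structure(out, class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes (",
      sum(x$genes$biotype == "coding"), "coding,",
      sum(x$genes$biotype == "lncRNA"), "lncRNA ),",
      nrow(x$exons), "exons\n")
  invisible(x)
}

#' Infer HOX cluster membership from gene symbols
#'
#' Case-insensitive prefix match on `HOXA`/`HOXB`/`HOXC`/`HOXD`; anything
#' else (including embedded lncRNAs and decoy fixtures) maps to `"none"`.
#'
#' @param symbol character vector of gene symbols.
#' @return Character vector over `{"A","B","C","D","none"}`.
#' @export
hox_cluster <- function(symbol) {
  out <- rep("none", length(symbol))
  hit <- grepl("^HOX[ABCD][0-9]", toupper(symbol))
  out[hit] <- substr(toupper(symbol)[hit], 4, 4)
  out
}

.infer_biotype <- function(symbol) {
  lnc <- grepl("(-|_)AS[0-9]*$|HOTAIR|HOTTIP|HAGLR|^LINC", toupper(symbol))
  ifelse(lnc, "lncRNA", "coding")
}

#' Parse a gene annotation file into gene models
#'
#' Reads GTF (exon and, when present, CDS features) or BED12 and collapses to
#' one canonical model per gene. Cluster labels are inferred from the symbol
#' prefix; biotype comes from the GTF `gene_biotype` attribute when present
#' and is otherwise inferred from the symbol (antisense/lncRNA naming).
#'
#' @param path annotation file.
#' @param dialect `"gtf"` or `"bed12"`.
#' @return A [gene_models] object.
#' @export
parse_annotation <- function(path, dialect = c("gtf", "bed12")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (dialect == "gtf") {
    lines <- readLines(path)
    body <- !grepl("^#", lines) & nzchar(lines)
    nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
    if (any(nf < 9L)) {
      bad <- which(body)[which(nf < 9L)[1]]
      stop("malformed GTF record at line ", bad, " of ", path)
    }
    gr <- rtracklayer::import(path, format = "gtf")
    ex <- gr[gr$type == "exon"]
    if (length(ex) == 0L) stop("no exon features in ", path)
    if (any(as.character(GenomicRanges::strand(ex)) == "*")) {
      stop("strandless gene rejected in ", path)
    }
    sym <- if (!is.null(ex$gene_name)) ex$gene_name else ex$gene_id
    bty <- if (!is.null(ex$gene_biotype)) {
      ifelse(grepl("lncRNA|lincRNA|antisense", ex$gene_biotype),
             "lncRNA", "coding")
    } else .infer_biotype(sym)
    ex_df <- data.frame(
      gene_id = ex$gene_id, symbol = sym, biotype = bty,
      chrom = as.character(GenomicRanges::seqnames(ex)),
      strand = as.character(GenomicRanges::strand(ex)),
      start = GenomicRanges::start(ex) - 1L, end = GenomicRanges::end(ex),
      stringsAsFactors = FALSE)
    genes <- unique(ex_df[c("gene_id", "symbol", "biotype", "chrom", "strand")])
    if (anyDuplicated(genes$gene_id)) {
      stop("inconsistent gene attributes for: ",
           genes$gene_id[duplicated(genes$gene_id)][1])
    }
    cds <- NULL
    cd <- gr[gr$type == "CDS"]
    if (length(cd) > 0L) {
      cds <- data.frame(gene_id = cd$gene_id,
                        start = GenomicRanges::start(cd) - 1L,
                        end = GenomicRanges::end(cd),
                        stringsAsFactors = FALSE)
    }
    gene_models(genes, ex_df[c("gene_id", "start", "end")], cds = cds)
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    if (length(gr) == 0L) stop("empty BED12 file: ", path)
    if (any(as.character(GenomicRanges::strand(gr)) == "*")) {
      stop("strandless gene rejected in ", path)
    }
    blocks <- gr$blocks
    if (is.null(blocks)) stop("BED file lacks block structure (need BED12): ", path)
    rows <- lapply(seq_along(gr), function(i) {
      b <- blocks[[i]]
      data.frame(gene_id = gr$name[i],
                 start = GenomicRanges::start(gr)[i] - 1L +
                   IRanges::start(b) - 1L,
                 end = GenomicRanges::start(gr)[i] - 1L + IRanges::end(b),
                 stringsAsFactors = FALSE)
    })
    ex_df <- do.call(rbind, rows)
    genes <- data.frame(gene_id = gr$name, symbol = gr$name,
                        biotype = .infer_biotype(gr$name),
                        chrom = as.character(GenomicRanges::seqnames(gr)),
                        strand = as.character(GenomicRanges::strand(gr)),
                        stringsAsFactors = FALSE)
    gene_models(genes, ex_df)
  }
}

#' Putative promoter interval of each gene
#'
#' The promoter is taken as 1 kb upstream through 100 bp downstream of the
#' TSS, in transcript orientation, clamped at position 0.
#'
#' @param models a [gene_models] object.
#' @param upstream,downstream extent in bp on either side of the TSS.
#' @return `data.frame` with `gene_id`, `chrom`, `start`, `end`, `strand`
#'   (0-based half-open).
#' @export
promoter_interval <- function(models, upstream = 1000, downstream = 100) {
  g <- models$genes
  tss0 <- g$tss - 1  # 0-based coordinate of the TSS base
  start <- ifelse(g$strand == "+", tss0 - upstream, g$tss - downstream)
  end <- ifelse(g$strand == "+", tss0 + downstream, g$tss + upstream)
  start <- pmax(0, start)
  data.frame(gene_id = g$gene_id, chrom = g$chrom, start = start, end = end,
             strand = g$strand, stringsAsFactors = FALSE)
}

## introns = complement of exons within the gene span, ordinals 5'->3'
.introns_of <- function(ex) {
  n <- nrow(ex)
  if (n < 2L) return(NULL)
  ex <- ex[order(ex$start), , drop = FALSE]
  intr <- data.frame(start = ex$end[-n], end = ex$start[-1])
  intr <- intr[intr$start < intr$end, , drop = FALSE]
  if (nrow(intr) == 0L) return(NULL)
  ord <- if (ex$strand[1] == "+") seq_len(nrow(intr)) else rev(seq_len(nrow(intr)))
  data.frame(gene_id = ex$gene_id[1], region_type = "intron", ordinal = ord,
             chrom = ex$chrom[1], start = intr$start, end = intr$end,
             strand = ex$strand[1], stringsAsFactors = FALSE)
}

.utrs_of <- function(ex, cds) {
  if (is.null(cds) || nrow(cds) == 0L) return(NULL)
  cmin <- min(cds$start); cmax <- max(cds$end)
  strand <- ex$strand[1]
  left <- data.frame(start = pmax(ex$start, 0), end = pmin(ex$end, cmin))
  left <- left[left$start < left$end, , drop = FALSE]
  right <- data.frame(start = pmax(ex$start, cmax), end = ex$end)
  right <- right[right$start < right$end, , drop = FALSE]
  mk <- function(df, type) {
    if (nrow(df) == 0L) return(NULL)
    ord <- if (strand == "+") seq_len(nrow(df)) else rev(seq_len(nrow(df)))
    data.frame(gene_id = ex$gene_id[1], region_type = type, ordinal = ord,
               chrom = ex$chrom[1], start = df$start, end = df$end,
               strand = strand, stringsAsFactors = FALSE)
  }
  if (strand == "+") rbind(mk(left, "utr5"), mk(right, "utr3"))
  else rbind(mk(right, "utr5"), mk(left, "utr3"))
}

#' Derive analysis regions for every gene
#'
#' Emits the promoter (ordinal 0), each exon and each intron, numbered 5' to
#' 3' in transcript orientation; when the annotation carried CDS features,
#' 5'/3' UTR intervals are emitted as well. Exons and introns exactly tile
#' the gene span; the promoter may overlap the head of exon 1 (a CpG falling
#' there is assigned to both regions).
#'
#' @param models a [gene_models] object.
#' @param upstream,downstream promoter extent, see [promoter_interval()].
#' @return `data.frame` with columns `gene_id`, `region_type`, `ordinal`,
#'   `chrom`, `start`, `end`, `strand` (0-based half-open).
#' @export
derive_regions <- function(models, upstream = 1000, downstream = 100) {
  prom <- promoter_interval(models, upstream, downstream)
  prom <- data.frame(gene_id = prom$gene_id, region_type = "promoter",
                     ordinal = 0L, chrom = prom$chrom, start = prom$start,
                     end = prom$end, strand = prom$strand,
                     stringsAsFactors = FALSE)
  ex <- models$exons
  ex_reg <- data.frame(gene_id = ex$gene_id, region_type = "exon",
                       ordinal = ex$ordinal, chrom = ex$chrom,
                       start = ex$start, end = ex$end, strand = ex$strand,
                       stringsAsFactors = FALSE)
  intr <- do.call(rbind, lapply(split(ex, ex$gene_id), .introns_of))
  utr <- NULL
  if (!is.null(models$cds)) {
    utr <- do.call(rbind, lapply(split(ex, ex$gene_id), function(e) {
      .utrs_of(e, models$cds[models$cds$gene_id == e$gene_id[1], , drop = FALSE])
    }))
  }
  out <- rbind(prom, ex_reg, intr, utr)
  out <- out[order(out$gene_id, out$region_type, out$ordinal), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign CpG sites to gene regions
#'
#' Every region whose interval contains a site is reported (multi-assignment:
#' a CpG in the promoter/exon-1 overlap, or under two overlapping genes, gets
#' all matching keys). Sites hitting no region are absent from the result.
#'
#' @param chrom,pos equal-length vectors: chromosome and 1-based position of
#'   each CpG site.
#' @param regions region table from [derive_regions()].
#' @return `data.frame` with `site` (index into the input), `chrom`, `pos`,
#'   `gene_id`, `region_type`, `ordinal`.
#' @export
assign_cpg <- function(chrom, pos, regions) {
  stopifnot(length(chrom) == length(pos))
  sites <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
  reg <- .as_granges(regions)
  hits <- GenomicRanges::findOverlaps(sites, reg, ignore.strand = TRUE)
  i <- S4Vectors::queryHits(hits); j <- S4Vectors::subjectHits(hits)
  out <- data.frame(site = i, chrom = chrom[i], pos = pos[i],
                    gene_id = regions$gene_id[j],
                    region_type = regions$region_type[j],
                    ordinal = regions$ordinal[j],
                    stringsAsFactors = FALSE)
  out[order(out$site, out$gene_id, out$region_type, out$ordinal), ,
      drop = FALSE]
}

#' Detect natural-antisense (NAT) lncRNA-gene pairs
#'
#' A pair is emitted iff an exon of a lncRNA overlaps an exon of a coding
#' gene by at least one base on the opposite strand of the same chromosome.
#' The overlapped coding-gene exon ordinals and the total exonic overlap in
#' bp are recorded.
#'
#' @param models a [gene_models] object containing both coding and lncRNA
#'   gene models.
#' @return `data.frame` with `lncrna_id`, `gene_id`, `overlapped_exons`
#'   (comma-separated ordinals), `overlap_bp`.
#' @export
find_nat_pairs <- function(models) {
  g <- models$genes
  ex <- models$exons
  lnc <- g[g$biotype == "lncRNA", , drop = FALSE]
  cod <- g[g$biotype == "coding", , drop = FALSE]
  out <- list()
  for (li in seq_len(nrow(lnc))) {
    lex <- ex[ex$gene_id == lnc$gene_id[li], , drop = FALSE]
    cand <- cod[cod$chrom == lnc$chrom[li] & cod$strand != lnc$strand[li], ,
                drop = FALSE]
    for (ci in seq_len(nrow(cand))) {
      cex <- ex[ex$gene_id == cand$gene_id[ci], , drop = FALSE]
      ov_per_exon <- vapply(seq_len(nrow(cex)), function(k) {
        sum(pmax(0, pmin(cex$end[k], lex$end) - pmax(cex$start[k], lex$start)))
      }, numeric(1))
      if (sum(ov_per_exon) >= 1) {
        ords <- sort(cex$ordinal[ov_per_exon > 0])
        out[[length(out) + 1L]] <- data.frame(
          lncrna_id = lnc$gene_id[li], gene_id = cand$gene_id[ci],
          overlapped_exons = paste(ords, collapse = ","),
          overlap_bp = sum(ov_per_exon), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(lncrna_id = character(), gene_id = character(),
                      overlapped_exons = character(), overlap_bp = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$lncrna_id, res$gene_id), , drop = FALSE]
}
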