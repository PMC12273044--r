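# Small in-code fixtures: compact gene-model builders, random gene
# structures and random call tables used across the module tests.

mk_models <- function(spec, cds = NULL) {
  genes <- do.call(rbind, lapply(spec, function(s) {
    data.frame(gene_id = s$id, symbol = if (is.null(s$symbol)) s$id else s$symbol,
               biotype = if (is.null(s$biotype)) "coding" else s$biotype,
               chrom = s$chrom, strand = s$strand, stringsAsFactors = FALSE)
  }))
  exons <- do.call(rbind, lapply(spec, function(s) {
    data.frame(gene_id = s$id, start = s$exons[, 1], end = s$exons[, 2],
               stringsAsFactors = FALSE)
  }))
  gene_models(genes, exons, cds = cds)
}

# a random non-overlapping exon structure on one strand
rand_gene_spec <- function(id, chrom = "chrS", strand = NULL,
                           n_exons = NULL) {
  if (is.null(strand)) strand <- sample(c("+", "-"), 1)
  if (is.null(n_exons)) n_exons <- sample(1:6, 1)
  widths <- sample(50:400, n_exons, replace = TRUE)
  gaps <- sample(30:500, n_exons, replace = TRUE)
  start0 <- sample(2000:50000, 1)
  starts <- start0 + cumsum(gaps) + c(0, cumsum(widths))[seq_len(n_exons)]
  list(id = id, chrom = chrom, strand = strand,
       exons = cbind(starts, starts + widths))
}

# random per-sample calls at given positions
rand_calls <- function(chrom, positions, sample_ids, pct = NULL) {
  grid <- expand.grid(pos = positions, sample_id = sample_ids,
                      stringsAsFactors = FALSE)
  if (is.null(pct)) pct <- runif(nrow(grid), 0, 100)
  n <- 20L
  nm <- round(n * pct / 100)
  data.frame(chrom = chrom, pos = grid$pos, sample_id = grid$sample_id,
             n_meth = nm, n_unmeth = n - nm, pct = pct,
             stringsAsFactors = FALSE)
}

# reflect all coordinates through M and flip strands
mirror_models <- function(models, M = 1e8) {
  g <- models$genes
  g$strand <- ifelse(g$strand == "+", "-", "+")
  ex <- models$exons
  ex2 <- data.frame(gene_id = ex$gene_id, start = M - ex$end,
                    end = M - ex$start, stringsAsFactors = FALSE)
  gene_models(g[c("gene_id", "symbol", "biotype", "chrom", "strand")], ex2)
}

# metadata for n matched pairs in one group
mk_pairs_meta <- function(n, group = "PMOL") {
  pid <- sprintf("%s%02d", group, seq_len(n))
  data.frame(sample_id = c(paste0(pid, ".N"), paste0(pid, ".T")),
             patient_id = c(pid, pid),
             tissue = rep(c("normal", "tumor"), each = n),
             group = group,
             histology = rep(c(NA, "WDSCC"), each = n),
             stringsAsFactors = FALSE)
}
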