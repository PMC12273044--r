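## Expression integration: upper-quartile normalization, log2 fold change,
## tiered Pearson correlation, methylation-expression and NAT concordance.

#' Between-sample upper-quartile normalization
#'
#' Scales each sample (column) so that its 75th percentile of nonzero counts
#' equals the geometric mean of the per-sample 75th percentiles; zeros stay
#' zero. Idempotent and invariant to per-sample scaling.
#'
#' @param counts genes x samples matrix of non-negative counts.
#' @return normalized matrix of the same shape.
#' @export
upper_quartile_normalize <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  uq <- apply(counts, 2, function(x) {
    nz <- x[x > 0]
    if (length(nz) == 0L) NA_real_ else quantile(nz, 0.75, names = FALSE)
  })
  if (any(is.na(uq))) {
    stop("all-zero sample(s): ",
         paste(colnames(counts)[is.na(uq)], collapse = ", "))
  }
  ref <- exp(mean(log(uq)))
  sweep(counts, 2, uq / ref, "/")
}

#' Log2 fold change with pseudocount
#'
#' @param tumor_mean,normal_mean normalized mean abundances (>= 0).
#' @param pseudocount added to both sides before the ratio.
#' @return `log2((tumor_mean + pc) / (normal_mean + pc))`.
#' @export
log2_fold_change <- function(tumor_mean, normal_mean, pseudocount = 1) {
  stopifnot(all(tumor_mean >= 0), all(normal_mean >= 0))
  log2((tumor_mean + pseudocount) / (normal_mean + pseudocount))
}

#' Per-gene fold-change records with threshold flag
#'
#' Flags genes passing `|log2FC| >= fc_threshold`; when an externally
#' computed per-gene p-value is supplied, `p < alpha` is also required
#' (differential-expression p-values are not computed here).
#'
#' @param tumor_mean,normal_mean named per-gene normalized means.
#' @param p optional per-gene p-values (same order).
#' @param fc_threshold absolute log2 fold-change bound (inclusive).
#' @param alpha p-value bound used when `p` is supplied.
#' @param pseudocount see [log2_fold_change()].
#' @return `data.frame`: `gene`, `log2fc`, `p` (NA if absent), `passes`.
#' @export
fold_change_table <- function(tumor_mean, normal_mean, p = NULL,
                              fc_threshold = 1.5, alpha = 0.05,
                              pseudocount = 1) {
  lfc <- log2_fold_change(tumor_mean, normal_mean, pseudocount)
  passes <- abs(lfc) >= fc_threshold
  if (!is.null(p)) passes <- passes & p < alpha
  data.frame(gene = if (!is.null(names(tumor_mean))) names(tumor_mean)
             else seq_along(lfc),
             log2fc = as.numeric(lfc),
             p = if (is.null(p)) NA_real_ else p,
             passes = passes, row.names = NULL, stringsAsFactors = FALSE)
}

#' Correlation tier from the coefficient
#'
#' `strong` iff `|r| > 0.7`, `moderate` iff `0.3 < |r| <= 0.7`, else `none`
#' (the sign is kept in `r` itself).
#'
#' @param r correlation coefficient(s).
#' @return character vector over `{"none","moderate","strong"}`.
#' @export
correlation_tier <- function(r) {
  a <- abs(r)
  out <- rep("none", length(r))
  out[a > 0.3 & a <= 0.7] <- "moderate"
  out[a > 0.7] <- "strong"
  out[is.na(r)] <- NA_character_
  out
}

#' Pearson correlation record
#'
#' Product-moment correlation with a two-sided p-value from the t-transform
#' on n - 2 degrees of freedom, plus the tier label. A constant vector
#' leaves r undefined and flags the record.
#'
#' @param x,y numeric vectors (n >= 3).
#' @return one-row `data.frame`: `r`, `p`, `tier`, `n`, `flagged`.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || sd(x) == 0 || sd(y) == 0) {
    return(data.frame(r = NA_real_, p = NA_real_, tier = NA_character_,
                      n = n, flagged = TRUE, stringsAsFactors = FALSE))
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  data.frame(r = r, p = ct$p.value, tier = correlation_tier(r), n = n,
             flagged = FALSE, stringsAsFactors = FALSE)
}

#' Methylation-expression association per gene
#'
#' Correlates each gene's region methylation (one region type, e.g. the
#' promoter) with its normalized expression across the shared samples, and
#' calls the direction: `inverse` for r < 0, `concordant` for r > 0.
#' Benjamini-Hochberg FDR values are reported alongside the raw p-values.
#'
#' @param summaries long region summary table from [region_summaries()].
#' @param expression genes x samples matrix of normalized abundances.
#' @param region_type region to use (default `"promoter"`).
#' @param ordinal region ordinal (default 0, the promoter).
#' @param min_samples minimum shared samples (genes under this are skipped).
#' @return `data.frame`: `gene_id`, `r`, `p`, `fdr`, `tier`, `n`,
#'   `direction`, `flagged`.
#' @export
meth_expr_association <- function(summaries, expression,
                                  region_type = "promoter", ordinal = 0L,
                                  min_samples = 3L) {
  sub <- summaries[summaries$region_type == region_type &
                     summaries$ordinal == ordinal, , drop = FALSE]
  genes <- intersect(unique(sub$gene_id), rownames(expression))
  recs <- lapply(genes, function(g) {
    s <- sub[sub$gene_id == g, , drop = FALSE]
    shared <- intersect(s$sample_id, colnames(expression))
    if (length(shared) < min_samples) return(NULL)
    m <- s$mean_pct[match(shared, s$sample_id)]
    e <- as.numeric(expression[g, shared])
    cbind(data.frame(gene_id = g, stringsAsFactors = FALSE), pearson(m, e))
  })
  out <- do.call(rbind, recs)
  if (is.null(out)) {
    return(data.frame(gene_id = character(), r = numeric(), p = numeric(),
                      fdr = numeric(), tier = character(), n = integer(),
                      direction = character(), flagged = logical(),
                      stringsAsFactors = FALSE))
  }
  out$fdr <- p.adjust(out$p, method = "BH")
  out$direction <- ifelse(is.na(out$r), NA_character_,
                          ifelse(out$r < 0, "inverse", "concordant"))
  rownames(out) <- NULL
  out[c("gene_id", "r", "p", "fdr", "tier", "n", "direction", "flagged")]
}

#' NAT pair co-expression concordance
#'
#' Pearson correlation between each lncRNA and its antisense partner gene
#' across samples, with tier labels; pairs with a member absent from the
#' expression matrix are skipped.
#'
#' @param nat_pairs table from [find_nat_pairs()].
#' @param expression genes x samples matrix of normalized abundances.
#' @return `data.frame`: `lncrna_id`, `gene_id`, `r`, `p`, `fdr`, `tier`,
#'   `n`, `flagged`.
#' @export
nat_concordance <- function(nat_pairs, expression) {
  recs <- lapply(seq_len(nrow(nat_pairs)), function(i) {
    a <- nat_pairs$lncrna_id[i]; b <- nat_pairs$gene_id[i]
    if (!a %in% rownames(expression) || !b %in% rownames(expression)) {
      return(NULL)
    }
    cbind(data.frame(lncrna_id = a, gene_id = b, stringsAsFactors = FALSE),
          pearson(as.numeric(expression[a, ]), as.numeric(expression[b, ])))
  })
  out <- do.call(rbind, recs)
  if (is.null(out)) {
    return(data.frame(lncrna_id = character(), gene_id = character(),
                      r = numeric(), p = numeric(), fdr = numeric(),
                      tier = character(), n = integer(), flagged = logical(),
                      stringsAsFactors = FALSE))
  }
  out$fdr <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out[c("lncrna_id", "gene_id", "r", "p", "fdr", "tier", "n", "flagged")]
}
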