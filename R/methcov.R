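## Coverage-file reading, region methylation summaries, matched tumor-normal
## differences and hyper/hypo classification.

#' Analysis thresholds
#'
#' Bundles the cut-offs used across the pipeline: the +/-25 % matched
#' difference bound for hyper/hypomethylation calls, the 10 % level under
#' which a locus is considered unmethylated, the 10 % variation band for CUR
#' eligibility, and repo-level floors for read coverage and CpGs per region.
#'
#' @param tau_hyper matched tumour-normal difference (%) above which a region
#'   is called hypermethylated (below `-tau_hyper`: hypomethylated). Strict
#'   inequality; exactly +/-25 classifies as `none`.
#' @param tau_unmeth methylation percent under which a CpG is considered
#'   unmethylated.
#' @param tau_cur_band maximum allowed methylation range (max - min, %)
#'   across all samples at a CUR-eligible CpG.
#' @param min_coverage minimum reads (methylated + unmethylated) to retain a
#'   CpG call.
#' @param min_cpgs_per_region minimum CpGs for a region summary.
#' @return A list of class `meth_thresholds`.
#' @export
meth_thresholds <- function(tau_hyper = 25, tau_unmeth = 10,
                            tau_cur_band = 10, min_coverage = 5,
                            min_cpgs_per_region = 1) {
  stopifnot(tau_hyper >= 0, tau_unmeth >= 0, tau_cur_band >= 0,
            min_coverage >= 0, min_cpgs_per_region >= 0)
  structure(list(tau_hyper = tau_hyper, tau_unmeth = tau_unmeth,
                 tau_cur_band = tau_cur_band, min_coverage = min_coverage,
                 min_cpgs_per_region = min_cpgs_per_region),
            class = "meth_thresholds")
}

#' Read a cytosine coverage file
#'
#' Expects the bismark-style tab-separated dialect: chrom, start (1-based),
#' end, methylation percent, count methylated, count unmethylated. The
#' percent column is recomputed from the counts (counts are authoritative); a
#' reported percent deviating by more than 0.5 from the recomputed value is
#' flagged with a warning. Calls with total reads below `min_coverage` are
#' dropped.
#'
#' @param path coverage file.
#' @param sample_id sample identifier attached to every call.
#' @param min_coverage minimum total reads to retain a call.
#' @return `data.frame` with `chrom`, `pos` (1-based), `sample_id`,
#'   `n_meth`, `n_unmeth`, `pct`.
#' @export
read_coverage <- function(path, sample_id, min_coverage = 5) {
  if (!file.exists(path)) stop("coverage file not found: ", path)
  df <- tryCatch(
    read.table(path, sep = "\t", header = FALSE,
               col.names = c("chrom", "start", "end", "pct_reported",
                             "n_meth", "n_unmeth"),
               colClasses = c("character", "numeric", "numeric", "numeric",
                              "numeric", "numeric")),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e)))
  if (any(!is.finite(df$n_meth)) || any(!is.finite(df$n_unmeth))) {
    bad <- which(!is.finite(df$n_meth) | !is.finite(df$n_unmeth))[1]
    stop("non-numeric counts at line ", bad, " of ", path)
  }
  tot <- df$n_meth + df$n_unmeth
  keep <- tot >= max(1, min_coverage)
  df <- df[keep, , drop = FALSE]
  tot <- tot[keep]
  pct <- 100 * df$n_meth / tot
  off <- abs(pct - df$pct_reported) > 0.5
  if (any(off)) {
    warning(sum(off), " call(s) in ", basename(path),
            " had a reported percent inconsistent with counts; ",
            "counts used")
  }
  data.frame(chrom = df$chrom, pos = df$start, sample_id = sample_id,
             n_meth = df$n_meth, n_unmeth = df$n_unmeth, pct = pct,
             stringsAsFactors = FALSE)
}

#' Read the sample metadata table
#'
#' @param path TSV with required columns `sample_id`, `patient_id`, `tissue`
#'   (`normal`/`tumor`), `group` (`PMOL`/`TN0`/`TN0plus`), `histology`.
#' @return validated `data.frame`.
#' @export
read_metadata <- function(path) {
  md <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("sample_id", "patient_id", "tissue", "group", "histology")
  if (!all(need %in% names(md))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(md$tissue %in% c("normal", "tumor"))) stop("bad tissue value")
  if (!all(md$group %in% c("PMOL", "TN0", "TN0plus"))) stop("bad group value")
  md
}

#' Mean methylation of one sample over one region
#'
#' The unweighted mean of per-CpG methylation percentages (read depth is not
#' used as a weight) over the CpGs falling in the region interval.
#'
#' @param calls per-sample call table from [read_coverage()].
#' @param region one-row region (with `chrom`, 0-based half-open
#'   `start`/`end`) as produced by [derive_regions()].
#' @param min_cpgs minimum CpGs; with fewer the summary is missing (`NA`),
#'   never imputed as 0.
#' @return list with `mean_pct`, `n_cpgs`.
#' @export
region_mean <- function(calls, region, min_cpgs = 1) {
  stopifnot(nrow(region) == 1L)
  inx <- calls$chrom == region$chrom &
    .pos_in_interval(calls$pos, region$start, region$end)
  n <- sum(inx)
  if (n < max(1, min_cpgs)) {
    return(list(mean_pct = NA_real_, n_cpgs = n))
  }
  list(mean_pct = mean(calls$pct[inx]), n_cpgs = n)
}

#' Region-by-sample methylation summary matrix
#'
#' Vectorized [region_mean()] over all regions and samples.
#'
#' @param calls call table (any number of samples) from [read_coverage()].
#' @param regions region table from [derive_regions()].
#' @param min_cpgs minimum CpGs per region summary.
#' @return long `data.frame`: `gene_id`, `region_type`, `ordinal`,
#'   `sample_id`, `mean_pct`, `n_cpgs`.
#' @export
region_summaries <- function(calls, regions, min_cpgs = 1) {
  asg <- assign_cpg(calls$chrom, calls$pos, regions)
  if (nrow(asg) == 0L) {
    return(data.frame(gene_id = character(), region_type = character(),
                      ordinal = integer(), sample_id = character(),
                      mean_pct = numeric(), n_cpgs = integer()))
  }
  key <- paste(asg$gene_id, asg$region_type, asg$ordinal, sep = "\r")
  sample <- calls$sample_id[asg$site]
  pct <- calls$pct[asg$site]
  grp <- paste(key, sample, sep = "\r")
  mu <- tapply(pct, grp, mean)
  n <- tapply(pct, grp, length)
  parts <- do.call(rbind, strsplit(names(mu), "\r", fixed = TRUE))
  out <- data.frame(gene_id = parts[, 1], region_type = parts[, 2],
                    ordinal = as.integer(parts[, 3]), sample_id = parts[, 4],
                    mean_pct = as.numeric(mu), n_cpgs = as.integer(n),
                    stringsAsFactors = FALSE)
  out <- out[out$n_cpgs >= max(1, min_cpgs), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Matched tumour-normal difference for one region
#'
#' @param tumor_summary,normal_summary values of `mean_pct` (same region,
#'   same patient). Either side missing gives `NA` (pair excluded upstream).
#' @return tumour minus normal, in percentage points.
#' @export
matched_delta <- function(tumor_summary, normal_summary) {
  tumor_summary - normal_summary
}

#' Classify a matched methylation difference
#'
#' Strict thresholds: `delta > tau_hyper` is `hyper`, `delta < -tau_hyper`
#' is `hypo`, boundary values classify as `none`.
#'
#' @param delta_pct matched difference(s) in percentage points.
#' @param thresholds a [meth_thresholds()] object.
#' @return character vector over `{"hyper","hypo","none"}`.
#' @export
classify_diff <- function(delta_pct, thresholds = meth_thresholds()) {
  stopifnot(all(is.finite(delta_pct) | is.na(delta_pct)))
  out <- rep("none", length(delta_pct))
  out[delta_pct > thresholds$tau_hyper] <- "hyper"
  out[delta_pct < -thresholds$tau_hyper] <- "hypo"
  out[is.na(delta_pct)] <- NA_character_
  out
}

## match tumor samples to their normal by patient_id; returns data.frame
## (patient_id, tumor_id, normal_id, group)
.matched_pairs <- function(metadata) {
  tum <- metadata[metadata$tissue == "tumor", , drop = FALSE]
  nrm <- metadata[metadata$tissue == "normal", , drop = FALSE]
  m <- merge(tum[c("patient_id", "sample_id", "group")],
             nrm[c("patient_id", "sample_id")],
             by = "patient_id", suffixes = c("_t", "_n"))
  data.frame(patient_id = m$patient_id, tumor_id = m$sample_id_t,
             normal_id = m$sample_id_n, group = m$group,
             stringsAsFactors = FALSE)
}

#' Per-region matched differences across a cohort
#'
#' For every region, pairs each tumour sample with its matched normal
#' (shared `patient_id`), averages the per-pair differences (pair-first, not
#' difference of pooled means) and classifies the mean difference. Pairs in
#' which either side has no region summary are excluded.
#'
#' @param summaries long summary table from [region_summaries()].
#' @param metadata sample metadata (see [read_metadata()]).
#' @param thresholds a [meth_thresholds()] object.
#' @param by_group if `TRUE` (default) one record per region x group, else
#'   pooled over groups.
#' @return `data.frame`: region key columns, `group` (if `by_group`),
#'   `delta_pct`, `call`, `n_pairs`.
#' @export
diff_meth_table <- function(summaries, metadata,
                            thresholds = meth_thresholds(),
                            by_group = TRUE) {
  pairs <- .matched_pairs(metadata)
  key <- paste(summaries$gene_id, summaries$region_type, summaries$ordinal,
               sep = "\r")
  lut <- split(seq_len(nrow(summaries)), key)
  recs <- lapply(names(lut), function(k) {
    sub <- summaries[lut[[k]], , drop = FALSE]
    mt <- sub$mean_pct[match(pairs$tumor_id, sub$sample_id)]
    mn <- sub$mean_pct[match(pairs$normal_id, sub$sample_id)]
    d <- matched_delta(mt, mn)
    ok <- !is.na(d)
    if (!any(ok)) return(NULL)
    grp <- if (by_group) pairs$group[ok] else rep("all", sum(ok))
    mu <- tapply(d[ok], grp, mean)
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    data.frame(gene_id = parts[1], region_type = parts[2],
               ordinal = as.integer(parts[3]), group = names(mu),
               delta_pct = as.numeric(mu),
               n_pairs = as.integer(tapply(d[ok], grp, length)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  if (is.null(out)) {
    return(data.frame(gene_id = character(), region_type = character(),
                      ordinal = integer(), group = character(),
                      delta_pct = numeric(), call = character(),
                      n_pairs = integer()))
  }
  out$call <- classify_diff(out$delta_pct, thresholds)
  rownames(out) <- NULL
  out[order(out$gene_id, out$region_type, out$ordinal, out$group), ,
      drop = FALSE]
}

#' Heatmap-ready region x group matrix of matched differences
#'
#' @param diff_table output of [diff_meth_table()] with `by_group = TRUE`.
#' @return numeric matrix, rows = `gene_id.region_type.ordinal`, columns =
#'   groups, values = mean matched difference (%).
#' @export
delta_matrix <- function(diff_table) {
  rn <- paste(diff_table$gene_id, diff_table$region_type, diff_table$ordinal,
              sep = ".")
  groups <- sort(unique(diff_table$group))
  rows <- unique(rn)
  m <- matrix(NA_real_, length(rows), length(groups),
              dimnames = list(rows, groups))
  m[cbind(match(rn, rows), match(diff_table$group, groups))] <-
    diff_table$delta_pct
  m
}

#' Per-CpG matched-difference profile of a locus set within one group
#'
#' For each CpG in `loci`, the mean over matched pairs of the tumour-normal
#' percent difference and its standard error (sample SD over the square root
#' of the number of pairs). With fewer than two pairs the SE is `NA`.
#'
#' @param calls cohort call table.
#' @param metadata sample metadata.
#' @param group group label to restrict pairs to (`NULL` = all pairs).
#' @param loci `data.frame` with `chrom`, `pos` (1-based) of panel CpGs.
#' @return `data.frame`: `chrom`, `pos`, `mean_delta`, `se`, `n_pairs`.
#' @export
group_cpg_profile <- function(calls, metadata, group = NULL, loci) {
  pairs <- .matched_pairs(metadata)
  if (!is.null(group)) pairs <- pairs[pairs$group == group, , drop = FALSE]
  out <- lapply(seq_len(nrow(loci)), function(i) {
    at <- calls$chrom == loci$chrom[i] & calls$pos == loci$pos[i]
    sub <- calls[at, , drop = FALSE]
    vt <- sub$pct[match(pairs$tumor_id, sub$sample_id)]
    vn <- sub$pct[match(pairs$normal_id, sub$sample_id)]
    d <- vt - vn
    d <- d[!is.na(d)]
    data.frame(chrom = loci$chrom[i], pos = loci$pos[i],
               mean_delta = if (length(d)) mean(d) else NA_real_,
               se = if (length(d) >= 2) sd(d) / sqrt(length(d)) else NA_real_,
               n_pairs = length(d), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
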