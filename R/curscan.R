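## Constitutively unmethylated region (CUR) scanning: maximal CpG runs that
## are low and invariant across every sample and contrast with their flanks.

#' CUR scan configuration
#'
#' @param tau_cur_band maximum variation (%) in methylation across all
#'   samples at an eligible CpG. Variation is the range (max - min) by
#'   default, the strictest common reading; set `stat = "sd"` for a
#'   standard-deviation-based alternative.
#' @param tau_unmeth absolute methylation percent every sample must stay
#'   under at an eligible CpG.
#' @param min_cur_cpgs minimum CpGs per reported run (also the number of
#'   flanking ineligible CpGs used per side for the flank contrast).
#' @param tau_contrast minimum excess (%) of flank methylation over run
#'   methylation; waived when no flanking CpGs exist.
#' @param max_gap_bp maximum distance between consecutive CpGs of a run.
#' @param stat variation statistic: `"range"` (default) or `"sd"`.
#' @return list of class `cur_config`.
#' @export
cur_config <- function(tau_cur_band = 10, tau_unmeth = 10, min_cur_cpgs = 3,
                       tau_contrast = 20, max_gap_bp = 300,
                       stat = c("range", "sd")) {
  stopifnot(tau_cur_band > 0, tau_unmeth > 0, min_cur_cpgs > 0,
            tau_contrast > 0, max_gap_bp > 0)
  structure(list(tau_cur_band = tau_cur_band, tau_unmeth = tau_unmeth,
                 min_cur_cpgs = min_cur_cpgs, tau_contrast = tau_contrast,
                 max_gap_bp = max_gap_bp, stat = match.arg(stat)),
            class = "cur_config")
}

#' Methylation variation across samples at one CpG
#'
#' Range (max - min) of the methylation percentages observed across all
#' samples at a single CpG (or the SD, if configured). With fewer than two
#' samples the site is ineligible and `NA` is returned.
#'
#' @param values methylation percentages across samples at one CpG.
#' @param stat `"range"` or `"sd"`.
#' @return variation in percentage points.
#' @export
cpg_band <- function(values, stat = "range") {
  values <- values[!is.na(values)]
  if (length(values) < 2L) return(NA_real_)
  if (stat == "sd") sd(values) else max(values) - min(values)
}

#' CUR eligibility mask over CpGs
#'
#' A CpG is eligible iff its variation across all samples pooled (which
#' subsumes within-group and case-versus-control variation) stays under
#' `tau_cur_band` and every single sample's methylation stays under
#' `tau_unmeth` (strict inequalities). CpGs observed in fewer than two
#' samples are ineligible.
#'
#' @param pct CpG x sample matrix of methylation percentages (`NA` for
#'   missing calls).
#' @param config a [cur_config()] object.
#' @return logical vector over the CpG rows.
#' @export
eligible_sites <- function(pct, config = cur_config()) {
  n_obs <- rowSums(!is.na(pct))
  band <- apply(pct, 1, cpg_band, stat = config$stat)
  mx <- suppressWarnings(apply(pct, 1, max, na.rm = TRUE))
  ok <- n_obs >= 2 & !is.na(band) & band < config$tau_cur_band &
    mx < config$tau_unmeth
  ok & !is.na(ok)
}

#' Enumerate maximal CUR runs
#'
#' Maximal runs of consecutive eligible CpGs (an ineligible CpG breaks a
#' run, as does an inter-CpG gap above `max_gap_bp`) of length at least
#' `min_cur_cpgs`. The flank contrast is the mean methylation of the nearest
#' `min_cur_cpgs` ineligible CpGs on each available side minus the mean over
#' the run; runs with a contrast under `tau_contrast` are dropped unless no
#' flanking CpGs exist at all (contrast waived, reported `NA`).
#'
#' @param eligible logical eligibility mask over CpGs (position order).
#' @param positions 1-based CpG positions, strictly increasing.
#' @param pct CpG x sample percent matrix aligned with `positions`.
#' @param config a [cur_config()] object.
#' @return `data.frame` with one row per retained run: `start`, `end`
#'   (0-based half-open interval covering first to last CpG), `n_cpgs`,
#'   `max_band`, `mean_pct`, `flank_contrast`.
#' @export
scan_runs <- function(eligible, positions, pct, config = cur_config()) {
  stopifnot(length(eligible) == length(positions),
            nrow(pct) == length(positions))
  if (is.unsorted(positions, strictly = TRUE)) {
    stop("positions must be strictly increasing")
  }
  empty <- data.frame(start = numeric(), end = numeric(), n_cpgs = integer(),
                      max_band = numeric(), mean_pct = numeric(),
                      flank_contrast = numeric())
  n <- length(positions)
  if (n == 0L || !any(eligible)) return(empty)
  ## break runs at ineligible CpGs or oversized gaps
  gap_break <- c(FALSE, diff(positions) > config$max_gap_bp)
  run_id <- cumsum(!eligible | gap_break)
  runs <- list()
  for (rid in unique(run_id[eligible])) {
    idx <- which(run_id == rid & eligible)
    if (length(idx) < config$min_cur_cpgs) next
    sub <- pct[idx, , drop = FALSE]
    band <- apply(sub, 1, cpg_band, stat = config$stat)
    run_mean <- mean(sub, na.rm = TRUE)
    ineligible <- which(!eligible)
    left <- rev(ineligible[ineligible < min(idx)])
    right <- ineligible[ineligible > max(idx)]
    fl <- c(head(left, config$min_cur_cpgs), head(right, config$min_cur_cpgs))
    contrast <- if (length(fl) == 0L) NA_real_ else {
      mean(pct[fl, , drop = FALSE], na.rm = TRUE) - run_mean
    }
    if (!is.na(contrast) && contrast < config$tau_contrast) next
    runs[[length(runs) + 1L]] <- data.frame(
      start = positions[min(idx)] - 1, end = positions[max(idx)],
      n_cpgs = length(idx), max_band = max(band, na.rm = TRUE),
      mean_pct = run_mean, flank_contrast = contrast)
  }
  if (length(runs) == 0L) return(empty)
  do.call(rbind, runs)
}

## CpG x sample percent matrix for calls within [start, end) on chrom
.pivot_pct <- function(calls, chrom, start, end) {
  inx <- calls$chrom == chrom & .pos_in_interval(calls$pos, start, end)
  sub <- calls[inx, , drop = FALSE]
  if (nrow(sub) == 0L) {
    return(list(pct = matrix(numeric(), 0, 0), positions = numeric()))
  }
  positions <- sort(unique(sub$pos))
  samples <- sort(unique(sub$sample_id))
  m <- matrix(NA_real_, length(positions), length(samples),
              dimnames = list(NULL, samples))
  m[cbind(match(sub$pos, positions), match(sub$sample_id, samples))] <- sub$pct
  list(pct = m, positions = positions)
}

#' Scan a cohort for constitutively unmethylated regions
#'
#' Screens each gene's territory (promoter through gene 3' end) for maximal
#' runs of CpGs that are unmethylated and invariant across every sample of
#' every group and contrast with adjacent loci.
#'
#' @param calls cohort call table (all samples) from [read_coverage()] or a
#'   simulated bundle.
#' @param models a [gene_models] object.
#' @param config a [cur_config()] object.
#' @param biotype which gene biotypes to screen (default coding genes).
#' @param upstream,downstream promoter extent defining the territory anchor.
#' @return `data.frame` of CUR calls: `gene_id`, `cur_id`, `chrom`, `start`,
#'   `end` (0-based half-open), `n_cpgs`, `max_band`, `mean_pct`,
#'   `flank_contrast`.
#' @export
cur_scan <- function(calls, models, config = cur_config(),
                     biotype = "coding", upstream = 1000, downstream = 100) {
  prom <- promoter_interval(models, upstream, downstream)
  g <- models$genes
  keep <- g$biotype %in% biotype
  out <- list()
  for (i in which(keep)) {
    terr_start <- min(g$start[i], prom$start[prom$gene_id == g$gene_id[i]])
    terr_end <- max(g$end[i], prom$end[prom$gene_id == g$gene_id[i]])
    piv <- .pivot_pct(calls, g$chrom[i], terr_start, terr_end)
    if (length(piv$positions) == 0L) next
    elig <- eligible_sites(piv$pct, config)
    runs <- scan_runs(elig, piv$positions, piv$pct, config)
    if (nrow(runs) == 0L) next
    runs <- cbind(data.frame(gene_id = g$gene_id[i],
                             cur_id = paste0(g$gene_id[i], ".CUR_",
                                             seq_len(nrow(runs))),
                             chrom = g$chrom[i], stringsAsFactors = FALSE),
                  runs)
    out[[length(out) + 1L]] <- runs
  }
  if (length(out) == 0L) {
    return(data.frame(gene_id = character(), cur_id = character(),
                      chrom = character(), start = numeric(), end = numeric(),
                      n_cpgs = integer(), max_band = numeric(),
                      mean_pct = numeric(), flank_contrast = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
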