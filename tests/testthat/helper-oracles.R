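# Independent brute-force oracles, kept deliberately naive (explicit loops,
# no shared code with the implementation paths they check).

oracle_auc <- function(scores, labels) {
  s1 <- scores[labels == 1]; s0 <- scores[labels == 0]
  tot <- 0
  for (a in s1) for (b in s0) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s0))
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  r <- sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), df = n - 2))
}

oracle_region_mean <- function(calls, chrom, start, end) {
  vals <- c()
  for (i in seq_len(nrow(calls))) {
    if (calls$chrom[i] == chrom && calls$pos[i] > start &&
        calls$pos[i] <= end) {
      vals <- c(vals, calls$pct[i])
    }
  }
  if (length(vals) == 0) NA_real_ else sum(vals) / length(vals)
}

oracle_assign <- function(chrom, pos, regions) {
  hits <- list()
  for (s in seq_along(pos)) {
    for (r in seq_len(nrow(regions))) {
      if (chrom[s] == regions$chrom[r] && pos[s] > regions$start[r] &&
          pos[s] <= regions$end[r]) {
        hits[[length(hits) + 1L]] <- data.frame(
          site = s, gene_id = regions$gene_id[r],
          region_type = regions$region_type[r],
          ordinal = regions$ordinal[r], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(site = integer(), gene_id = character(),
                      region_type = character(), ordinal = integer()))
  }
  out <- do.call(rbind, hits)
  out[order(out$site, out$gene_id, out$region_type, out$ordinal), ]
}

# introns reconstructed as the complement of exons within the gene span
oracle_introns <- function(starts, ends) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  out <- NULL
  for (i in seq_along(starts)[-1]) {
    if (starts[i] > ends[i - 1]) {
      out <- rbind(out, c(ends[i - 1], starts[i]))
    }
  }
  out
}

# plain-loop re-enumeration of CUR runs (eligibility -> maximal runs ->
# length filter -> flank contrast filter)
oracle_runs <- function(eligible, positions, pct, cfg) {
  n <- length(positions)
  runs <- list(); cur <- c()
  close_run <- function(cur, runs) {
    if (length(cur) >= cfg$min_cur_cpgs) runs[[length(runs) + 1L]] <- cur
    runs
  }
  for (i in seq_len(n)) {
    if (!eligible[i]) { runs <- close_run(cur, runs); cur <- c(); next }
    if (length(cur) > 0 &&
        positions[i] - positions[cur[length(cur)]] > cfg$max_gap_bp) {
      runs <- close_run(cur, runs); cur <- c()
    }
    cur <- c(cur, i)
  }
  runs <- close_run(cur, runs)
  keep <- list()
  for (run in runs) {
    inel <- which(!eligible)
    left <- rev(inel[inel < min(run)]); right <- inel[inel > max(run)]
    fl <- c(head(left, cfg$min_cur_cpgs), head(right, cfg$min_cur_cpgs))
    run_mean <- mean(pct[run, , drop = FALSE], na.rm = TRUE)
    if (length(fl) > 0) {
      contrast <- mean(pct[fl, , drop = FALSE], na.rm = TRUE) - run_mean
      if (contrast < cfg$tau_contrast) next
    }
    keep[[length(keep) + 1L]] <-
      c(start = positions[min(run)] - 1, end = positions[max(run)],
        n_cpgs = length(run))
  }
  if (length(keep) == 0) {
    return(data.frame(start = numeric(), end = numeric(),
                      n_cpgs = numeric()))
  }
  as.data.frame(do.call(rbind, keep))
}
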