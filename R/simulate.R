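## Synthetic cohort generator: annotation, coverage calls, expression counts,
## metadata and truth tables, emulating the matched-pair study design.

## ---- fixture annotation ----------------------------------------------------

.proc_exons <- function(s) rbind(c(s, s + 800), c(s + 1600, s + 2500))

#' Synthetic HOX-cluster annotation
#'
#' Builds the packaged fixture annotation: 39 HOX-like coding genes across
#' the four clusters (chr7/chr17/chr12/chr2, at hg19-style coordinates) plus
#' six embedded antisense lncRNAs whose exons overlap a partner gene's exon
#' on the opposite strand. The genes carrying documented unmethylated
#' regions and the gene hosting the intronic CpG panel have hand-laid exon
#' structures so those printed coordinate spans fall in the documented
#' region class (promoter, exon 1 or intron). All coordinates are synthetic.
#'
#' @return A [gene_models] object (39 coding + 6 lncRNA models).
#' @export
hox_annotation <- function() {
  genes <- list(); exons <- list()
  add <- function(symbol, chrom, strand, ex, biotype = "coding") {
    genes[[length(genes) + 1L]] <<- data.frame(
      gene_id = symbol, symbol = symbol, biotype = biotype, chrom = chrom,
      strand = strand, stringsAsFactors = FALSE)
    exons[[length(exons) + 1L]] <<- data.frame(
      gene_id = symbol, start = ex[, 1], end = ex[, 2],
      stringsAsFactors = FALSE)
  }
  ## cluster A (chr7, -)
  add("HOXA1", "chr7", "-", rbind(c(27132614, 27133400), c(27134800, 27135625)))
  proc_a <- c("HOXA2", "HOXA3", "HOXA4", "HOXA5", "HOXA6", "HOXA7", "HOXA9",
              "HOXA10", "HOXA13")
  for (i in seq_along(proc_a)) {
    add(proc_a[i], "chr7", "-", .proc_exons(27140000 + (i - 1) * 6000))
  }
  add("HOXA11", "chr7", "-", rbind(c(27220776, 27222100), c(27223600, 27224835)))
  ## cluster B (chr17, -)
  proc_b <- c("HOXB1", "HOXB2", "HOXB3", "HOXB4", "HOXB7", "HOXB8", "HOXB13")
  for (i in seq_along(proc_b)) {
    add(proc_b[i], "chr17", "-", .proc_exons(46620000 + (i - 1) * 6000))
  }
  add("HOXB5", "chr17", "-", rbind(c(46668619, 46669400), c(46670300, 46671103)))
  add("HOXB6", "chr17", "-", rbind(c(46676000, 46677000), c(46679000, 46680400)))
  add("HOXB9", "chr17", "-", rbind(c(46698518, 46701000), c(46702800, 46703835)))
  ## cluster C (chr12, +)
  proc_c <- c("HOXC4", "HOXC6", "HOXC8", "HOXC9", "HOXC12", "HOXC13")
  for (i in seq_along(proc_c)) {
    add(proc_c[i], "chr12", "+", .proc_exons(54330000 + (i - 1) * 5000))
  }
  add("HOXC11", "chr12", "+", rbind(c(54365000, 54366800), c(54369500, 54370635)))
  add("HOXC10", "chr12", "+", rbind(c(54379000, 54379900), c(54381000, 54382000)))
  add("HOXC5", "chr12", "+", rbind(c(54426600, 54427400), c(54428200, 54429000)))
  ## cluster D (chr2, +)
  proc_d <- c("HOXD1", "HOXD3", "HOXD4", "HOXD8", "HOXD9", "HOXD10", "HOXD11",
              "HOXD12", "HOXD13")
  for (i in seq_along(proc_d)) {
    add(proc_d[i], "chr2", "+", .proc_exons(176940000 + (i - 1) * 5000))
  }
  ## embedded antisense lncRNAs (opposite strand, exonic overlap >= 1 bp)
  add("HOTAIRM1", "chr7", "+", rbind(c(27132200, 27132900)), "lncRNA")
  add("HOXA-AS3", "chr7", "+", rbind(c(27152500, 27153100)), "lncRNA")
  add("HOXA10-AS", "chr7", "+", rbind(c(27183900, 27184300)), "lncRNA")
  add("HOXB-AS1", "chr17", "+", rbind(c(46626300, 46626700)), "lncRNA")
  add("HOXC13-AS", "chr12", "-", rbind(c(54355200, 54355700)), "lncRNA")
  add("HAGLR", "chr2", "-", rbind(c(176940200, 176940700)), "lncRNA")
  gene_models(do.call(rbind, genes), do.call(rbind, exons))
}

.default_curs <- function() {
  data.frame(
    gene_id = c("HOXA1", "HOXA11", "HOXB5", "HOXB6", "HOXB9", "HOXC5",
                "HOXC10", "HOXC11"),
    chrom = c("chr7", "chr7", "chr17", "chr17", "chr17", "chr12", "chr12",
              "chr12"),
    start = c(27135301, 27223858, 46671202, 46679967, 46703139, 54426389,
              54378697, 54367151),
    end = c(27136558, 27224500, 46671443, 46680261, 46703596, 54426695,
            54378899, 54368797),
    stringsAsFactors = FALSE)
}

.default_panel <- function() {
  data.frame(chrom = "chr17",
             pos = 46702528 + c(0, 8, 16, 24, 32, 40, 47, 55),
             stringsAsFactors = FALSE)
}

## ---- configuration ---------------------------------------------------------

#' Synthetic cohort configuration
#'
#' Defaults reproduce the study conditions the pipeline targets: matched
#' normal/tumour pairs in three groups (8 PMOL, 6 TN0, 8 TN0+), a
#' progressively hypermethylated 8-CpG intronic panel, planted
#' constitutively unmethylated runs at the documented spans, inverse
#' promoter-methylation/expression coupling and antisense co-expression.
#'
#' @param seed integer RNG seed; the generator is fully deterministic given
#'   the seed.
#' @param n_pairs named integer vector of matched pairs per group.
#' @param models gene annotation as a [gene_models] object.
#' @param cpg_spacing mean distance (bp) between CpGs in gene territories;
#'   inside planted CURs an additional CpG-island-density stream at
#'   `cpg_spacing / 3` is laid down.
#' @param depth mean read coverage per CpG per sample (Poisson).
#' @param beta_background shape parameters of the Beta methylation level of
#'   ordinary CpGs (drawn per CpG and sample).
#' @param beta_unmeth shape parameters of the Beta methylation level of
#'   planted-CUR CpGs (drawn once per CpG, shared by all samples: a
#'   constitutively unmethylated locus is a locus property).
#' @param planted_curs `data.frame` (`gene_id`, `chrom`, `start`, `end`;
#'   0-based half-open) of planted unmethylated runs.
#' @param panel_loci `data.frame` (`chrom`, `pos` 1-based) of the CpG panel.
#' @param panel_effect named vector: mean tumour-minus-normal shift (%) at
#'   panel CpGs per group, applied on the logit scale.
#' @param dmr_genes genes whose promoters are hypermethylated in tumours.
#' @param dmr_effect tumour promoter shift (%) for `dmr_genes`, logit scale.
#' @param coupled_genes genes with inverse promoter-methylation/expression
#'   coupling (promoter level varies per sample, Beta(2,2)).
#' @param coupling_b log-scale expression decrease per unit promoter
#'   methylation fraction.
#' @param expr_mu mean expression count per gene.
#' @param expr_dispersion negative-binomial size parameter.
#' @param nat_rho SD of the shared log-scale latent factor driving NAT pair
#'   co-expression.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_pairs = c(PMOL = 8L, TN0 = 6L, TN0plus = 8L),
                       models = hox_annotation(),
                       cpg_spacing = 30,
                       depth = 100,
                       beta_background = c(15, 5),
                       beta_unmeth = c(0.5, 30),
                       planted_curs = .default_curs(),
                       panel_loci = .default_panel(),
                       panel_effect = c(PMOL = 5, TN0 = 15, TN0plus = 40),
                       dmr_genes = c("HOXB2", "HOXB7", "HOXC8", "HOXD4"),
                       dmr_effect = 40,
                       coupled_genes = c("HOXA2", "HOXA5", "HOXB4", "HOXC6",
                                         "HOXD9", "HOXD11"),
                       coupling_b = 3,
                       expr_mu = 500,
                       expr_dispersion = 20,
                       nat_rho = 2) {
  stopifnot(cpg_spacing > 0, depth > 0, all(beta_background > 0),
            all(beta_unmeth > 0), expr_mu > 0, expr_dispersion > 0,
            nat_rho > 0, all(n_pairs >= 0), sum(n_pairs) >= 2)
  structure(list(seed = as.integer(seed), n_pairs = n_pairs, models = models,
                 cpg_spacing = cpg_spacing, depth = depth,
                 beta_background = beta_background, beta_unmeth = beta_unmeth,
                 planted_curs = planted_curs, panel_loci = panel_loci,
                 panel_effect = panel_effect, dmr_genes = dmr_genes,
                 dmr_effect = dmr_effect, coupled_genes = coupled_genes,
                 coupling_b = coupling_b, expr_mu = expr_mu,
                 expr_dispersion = expr_dispersion, nat_rho = nat_rho),
            class = "sim_config")
}

## logit shift moving a baseline mean fraction `base` up by `delta` percent
.logit_shift <- function(base, delta) {
  qlogis(pmin(0.99, base + delta / 100)) - qlogis(base)
}

.sim_metadata <- function(n_pairs) {
  hist_of <- c(PMOL = "leukoplakia", TN0 = "WDSCC", TN0plus = "MDSCC")
  rows <- list()
  for (g in names(n_pairs)) {
    if (n_pairs[[g]] == 0L) next
    for (k in seq_len(n_pairs[[g]])) {
      pid <- sprintf("%s%02d", g, k)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = paste0(pid, c(".N", ".T")), patient_id = pid,
        tissue = c("normal", "tumor"), group = g,
        histology = c(NA_character_, hist_of[[g]]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

## Poisson-process CpG positions over [start, end): background stream at
## `spacing`, plus an island-density stream at `spacing/3` inside `curs`.
.sim_positions <- function(start, end, spacing, curs, extra_loci = numeric()) {
  len <- end - start
  n_bg <- max(10, ceiling(len / spacing * 1.6))
  pos <- start + cumsum(ceiling(stats::rexp(n_bg, 1 / spacing)) + 1)
  pos <- pos[pos <= end]
  if (nrow(curs) > 0L) {
    for (i in seq_len(nrow(curs))) {
      clen <- curs$end[i] - curs$start[i]
      n_is <- max(5, ceiling(clen / (spacing / 3) * 1.6))
      ip <- curs$start[i] + cumsum(ceiling(stats::rexp(n_is, 3 / spacing)) + 1)
      pos <- c(pos, ip[ip <= curs$end[i]])
    }
  }
  sort(unique(c(round(pos), extra_loci)))
}

#' Generate a synthetic cohort bundle
#'
#' Produces, deterministically for a given seed, the complete in-memory
#' cohort: CpG methylation calls for every sample, expression counts, sample
#' metadata, the annotation, and truth tables describing exactly what was
#' planted (CUR intervals, panel deltas, couplings, NAT pairs, DMR genes).
#'
#' @param config a [sim_config()] object.
#' @return list of class `cohort_bundle` with elements `models`, `calls`,
#'   `metadata`, `counts`, `truth`, `config`.
#' @export
generate <- function(config = sim_config()) {
  g <- config$models$genes
  coding <- g[g$biotype == "coding", , drop = FALSE]
  prom <- promoter_interval(config$models)
  ## planted CURs must fall inside their gene's screened territory
  for (i in seq_len(nrow(config$planted_curs))) {
    pc <- config$planted_curs[i, ]
    j <- match(pc$gene_id, g$gene_id)
    if (is.na(j)) stop("planted CUR references unknown gene: ", pc$gene_id)
    ts <- min(g$start[j], prom$start[prom$gene_id == pc$gene_id])
    te <- max(g$end[j], prom$end[prom$gene_id == pc$gene_id])
    if (pc$start < ts || pc$end > te) {
      stop("planted CUR outside gene territory: ", pc$gene_id)
    }
  }
  metadata <- .sim_metadata(config$n_pairs)
  samples <- metadata$sample_id
  n_s <- length(samples)
  is_tumor <- metadata$tissue == "tumor"
  grp <- metadata$group

  bundle <- .with_seed(config$seed, function() {
    chrom_v <- pos_v <- smp_v <- nm_v <- nu_v <- list()
    coupled_m <- list()  # realized per-sample promoter level of coupled genes
    for (gi in seq_len(nrow(coding))) {
      gid <- coding$gene_id[gi]
      pr <- prom[prom$gene_id == gid, ]
      ts <- min(coding$start[gi], pr$start)
      te <- max(coding$end[gi], pr$end)
      curs_g <- config$planted_curs[config$planted_curs$gene_id == gid, ,
                                    drop = FALSE]
      extra <- config$panel_loci$pos[config$panel_loci$chrom ==
                                       coding$chrom[gi] &
                                     config$panel_loci$pos > ts &
                                     config$panel_loci$pos <= te]
      pos <- .sim_positions(ts, te, config$cpg_spacing, curs_g, extra)
      n_c <- length(pos)
      if (n_c == 0L) next
      ## baseline: per CpG x sample beta-distributed methylation level
      p <- matrix(rbeta(n_c * n_s, config$beta_background[1],
                        config$beta_background[2]), n_c, n_s)
      ## coupled genes: promoter level varies per sample (shared across the
      ## promoter's CpGs, with CpG-level logit jitter)
      if (gid %in% config$coupled_genes) {
        in_prom <- .pos_in_interval(pos, pr$start, pr$end)
        m_s <- rbeta(n_s, 2, 2)
        jit <- matrix(rnorm(sum(in_prom) * n_s, 0, 0.3), sum(in_prom), n_s)
        p[in_prom, ] <- plogis(sweep(jit, 2, qlogis(m_s), "+"))
        coupled_m[[gid]] <- m_s
      }
      ## DMR genes: promoter low in normals, logit-shifted up in tumours
      if (gid %in% config$dmr_genes) {
        in_prom <- .pos_in_interval(pos, pr$start, pr$end)
        base <- matrix(rbeta(sum(in_prom) * n_s, 2, 18), sum(in_prom), n_s)
        sh <- .logit_shift(0.10, config$dmr_effect)
        base[, is_tumor] <- plogis(qlogis(base[, is_tumor, drop = FALSE]) + sh)
        p[in_prom, ] <- base
      }
      ## planted CURs: one low level per CpG, shared by every sample
      if (nrow(curs_g) > 0L) {
        for (ci in seq_len(nrow(curs_g))) {
          in_cur <- .pos_in_interval(pos, curs_g$start[ci], curs_g$end[ci])
          p[in_cur, ] <- rbeta(sum(in_cur), config$beta_unmeth[1],
                               config$beta_unmeth[2])
        }
      }
      ## panel loci: low baseline, group-wise logit shift in tumours
      if (length(extra) > 0L) {
        at <- pos %in% extra
        base <- matrix(rbeta(sum(at) * n_s, 2, 38), sum(at), n_s)
        for (gname in names(config$panel_effect)) {
          sel <- is_tumor & grp == gname
          if (!any(sel)) next
          sh <- .logit_shift(0.05, config$panel_effect[[gname]])
          base[, sel] <- plogis(qlogis(base[, sel, drop = FALSE]) + sh)
        }
        p[at, ] <- base
      }
      depth <- matrix(rpois(n_c * n_s, config$depth), n_c, n_s)
      nm <- matrix(rbinom(n_c * n_s, depth, p), n_c, n_s)
      keep <- depth > 0
      idx <- which(keep, arr.ind = TRUE)
      chrom_v[[gi]] <- rep(coding$chrom[gi], nrow(idx))
      pos_v[[gi]] <- pos[idx[, 1]]
      smp_v[[gi]] <- samples[idx[, 2]]
      nm_v[[gi]] <- nm[keep]
      nu_v[[gi]] <- depth[keep] - nm[keep]
    }
    nm_all <- unlist(nm_v); nu_all <- unlist(nu_v)
    calls <- data.frame(
      chrom = unlist(chrom_v), pos = unlist(pos_v),
      sample_id = unlist(smp_v), n_meth = nm_all, n_unmeth = nu_all,
      pct = 100 * nm_all / (nm_all + nu_all), stringsAsFactors = FALSE)

    ## expression: NB counts; coupled genes inversely tied to their promoter
    ## level; NAT pairs share a latent log-scale factor
    nat <- find_nat_pairs(config$models)
    all_genes <- g$gene_id
    logmu <- matrix(log(config$expr_mu) + rnorm(length(all_genes), 0, 0.3),
                    length(all_genes), n_s,
                    dimnames = list(all_genes, samples))
    for (gid in names(coupled_m)) {
      logmu[gid, ] <- logmu[gid, ] -
        config$coupling_b * (coupled_m[[gid]] - 0.5)
    }
    if (nrow(nat) > 0L) {
      for (i in seq_len(nrow(nat))) {
        f <- rnorm(n_s, 0, config$nat_rho)
        logmu[nat$lncrna_id[i], ] <- logmu[nat$lncrna_id[i], ] + f
        logmu[nat$gene_id[i], ] <- logmu[nat$gene_id[i], ] + f
      }
    }
    counts <- matrix(rnbinom(length(logmu), mu = exp(logmu),
                             size = config$expr_dispersion),
                     nrow(logmu), ncol(logmu), dimnames = dimnames(logmu))
    list(calls = calls, counts = counts, nat = nat)
  })

  truth <- list(
    curs = config$planted_curs,
    panel = cbind(config$panel_loci,
                  as.data.frame(as.list(config$panel_effect))),
    coupling = data.frame(gene_id = config$coupled_genes,
                          b = config$coupling_b, stringsAsFactors = FALSE),
    nat = bundle$nat[c("lncrna_id", "gene_id")],
    dmr = data.frame(gene_id = config$dmr_genes, delta = config$dmr_effect,
                     stringsAsFactors = FALSE))
  structure(list(models = config$models, calls = bundle$calls,
                 metadata = metadata, counts = bundle$counts, truth = truth,
                 config = config),
            class = "cohort_bundle")
}

#' The packaged worked fixture
#'
#' The small cohort used throughout the documentation and tests: 8 PMOL, 6
#' TN0 and 8 TN0+ matched pairs, an 8-CpG panel inside the HOXB9-like
#' gene's first intron at the documented chr17 coordinates, and planted
#' unmethylated runs at the documented spans. Entirely synthetic data on a
#' fixed seed.
#'
#' @param seed fixture seed (fixed default so the fixture is reproducible).
#' @return a `cohort_bundle`.
#' @export
worked_fixture <- function(seed = 101L) {
  generate(sim_config(seed = seed))
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("cohort_bundle:", nrow(x$metadata), "samples,",
      length(unique(x$metadata$patient_id)), "patients,",
      nrow(x$calls), "CpG calls,", nrow(x$counts), "genes\n")
  invisible(x)
}

#' Write a cohort bundle to disk
#'
#' Emits exactly the formats the analysis functions consume: a GTF
#' annotation, one bismark-style coverage TSV per sample, a metadata TSV, a
#' counts TSV, and the truth tables.
#'
#' @param bundle a `cohort_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "coverage"), showWarnings = FALSE)
  write_annotation_gtf(bundle$models, file.path(dir, "annotation.gtf"))
  for (s in bundle$metadata$sample_id) {
    sub <- bundle$calls[bundle$calls$sample_id == s, , drop = FALSE]
    out <- data.frame(sub$chrom, sub$pos, sub$pos,
                      round(sub$pct, 6), sub$n_meth, sub$n_unmeth)
    write.table(out, file.path(dir, "coverage", paste0(s, ".cov")),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  write.table(bundle$metadata, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cts <- data.frame(gene_id = rownames(bundle$counts), bundle$counts,
                    check.names = FALSE)
  write.table(cts, file.path(dir, "counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (nm in names(bundle$truth)) {
    write.table(bundle$truth[[nm]], file.path(dir, paste0("truth_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
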