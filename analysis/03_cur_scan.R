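#!/usr/bin/env Rscript
# Scan every gene territory (promoter through 3' end) for constitutively
# unmethylated regions: runs of CpGs under 10% methylation in every sample,
# with under 10% cross-sample variation, contrasting with flanking loci.
# Reports BED6 + TSV and scores recovery against the planted truth.

suppressMessages(library(hoxmeth))
dir.create("results", showWarnings = FALSE)

bundle <- worked_fixture()
curs <- cur_scan(bundle$calls, bundle$models)
cur_report(curs, bundle$models, "results/cur_calls.bed",
           "results/cur_calls.tsv")
cat("CUR calls:", nrow(curs), "in",
    length(unique(curs$gene_id)), "genes\n")
print(curs[, c("cur_id", "chrom", "start", "end", "n_cpgs", "mean_pct",
               "flank_contrast")], digits = 3)

truth <- bundle$truth$curs
rec <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
  tc <- truth[i, ]
  hit <- curs[curs$gene_id == tc$gene_id & curs$end > tc$start &
                curs$start < tc$end, , drop = FALSE]
  data.frame(gene_id = tc$gene_id, planted_bp = tc$end - tc$start,
             n_calls = nrow(hit),
             jaccard = interval_jaccard(tc$start, tc$end, hit$start,
                                        hit$end))
}))
write.table(rec, "results/cur_recovery.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nRecovery against planted truth (interval Jaccard of the union of",
    "calls):\n")
print(rec, digits = 2)
cat("\nNote: single-CpG speckle failures of the strict every-sample <10%",
    "gate\nsplit runs and cap the Jaccard well below 1; see the methods",
    "vignette.\n")
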