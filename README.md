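# hoxmeth — HOX cluster methylation landscape analysis

`hoxmeth` is an R package plus analysis workflow for targeted bisulfite
methylation studies of the four **HOX gene clusters** (HOXA–D, 39 coding
genes with embedded antisense lncRNAs) in matched tumour–normal cohorts,
as arise in oral squamous cell carcinoma (OSCC) progression studies with
premalignant (PMOL), non-invasive (TN0) and invasive (TN0+) groups. It is
aimed at epigenomics analysts who have per-sample cytosine coverage files
(bismark-style), a gene annotation (GTF or BED12), sample metadata and an
expression count matrix, and who want a tested, reproducible path from
CpG calls to region-level methylation landscapes, unmethylated-region
segmentation, biomarker evaluation and methylation–expression
integration.

## What it computes

* **Gene-region methylation.** Promoters are `[TSS − 1 kb, TSS + 100 bp)`
  in transcript orientation; exons and introns are numbered 5′→3′. A
  region's methylation in a sample is the *unweighted* mean of its
  per-CpG percentages, `m = (1/n) Σᵢ 100·mᵢ/(mᵢ+uᵢ)`. For matched pairs
  the per-region difference is pair-first, `Δ = (1/P) Σₚ (m_tumour,p −
  m_normal,p)`, and a region is called **hypermethylated** when `Δ > 25`
  and **hypomethylated** when `Δ < −25` (strict; percentage points).
* **Constitutively unmethylated regions (CURs).** A CpG is eligible when
  every sample shows `< 10 %` methylation and the cross-sample range
  (max − min) is `< 10 %`; maximal runs of ≥ 3 consecutive eligible CpGs
  (inter-CpG gap ≤ 300 bp) whose flanking ineligible CpGs are ≥ 20
  percentage points more methylated are reported as CURs (BED6 + TSV).
* **CpG-panel biomarker.** For a locus panel (e.g. the 8 intronic CpGs at
  chr17:46,702,528–46,702,583), per-sample scores come from a logistic
  model on the pooled panel mean; the ROC is built from first principles
  by threshold sweep, with `AUC = P(s₁ > s₀) + ½·P(s₁ = s₀)`
  (Mann–Whitney), a stratified bootstrap percentile 95 % CI (2000
  replicates), and a random-forest out-of-bag AUC as robustness check.
* **Expression integration.** Between-sample upper-quartile
  normalization (each sample's nonzero 75th percentile scaled to the
  geometric mean of all samples'), `log2FC` with pseudocount,
  and tiered Pearson correlation (`|r| > 0.7` strong, `0.3 < |r| ≤ 0.7`
  moderate) for promoter-methylation→expression coupling and for
  natural-antisense (NAT) lncRNA–gene co-expression. NAT pairs are
  detected as opposite-strand exonic overlaps (≥ 1 bp).
* **Synthetic cohorts.** A beta-binomial generator emulates the full
  study design — matched pairs (8 PMOL / 6 TN0 / 8 TN0+), planted CURs,
  a progressively hypermethylated panel, inverse
  methylation–expression coupling, shared-factor NAT co-expression —
  with truth tables, so every stage is testable without external data.

## Worked example

```r
library(hoxmeth)
bundle <- worked_fixture()            # deterministic synthetic cohort
pan    <- build_panel(bundle$calls, bundle$metadata,
                      bundle$truth$panel[, c("chrom", "pos")],
                      contrast = c("PMOL", "TN0plus"))
evaluate_panel(pan, n_boot = 2000, seed = 20)
```

Running the numbered drivers reproduces the full workflow
(`Rscript analysis/01_simulate_cohort.R` … `05_expression_integration.R`),
writing tables under `results/`. On the packaged fixture they print,
among others:

```
Panel mean matched difference (%) by group:
   PMOL     TN0 TN0plus
    5.4    14.4    35.4

PMOL_vs_TN0plus          AUC 1.000  [1.000, 1.000]  forest OOB 1.000  (n=8+8)

  lncrna_id gene_id     r   tier
  HOTAIRM1   HOXA1  0.886 strong
  HOXA10-AS  HOXA10 0.999 strong
```

i.e. the panel's matched tumour–normal methylation gain grows with
disease stage (≈ +5 % in premalignant lesions to ≈ +35–40 % in invasive
tumours), separates PMOL from TN0+ perfectly on this cohort (AUC 1.0,
bootstrap CI lower bound 1.0), and the embedded antisense lncRNAs
co-express strongly with their partner genes. `03_cur_scan.R` reports the
CUR calls with their recovery against the planted truth; the strict
every-sample gate fragments long planted runs (see the methods vignette
for why, and for what that implies on real data).

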