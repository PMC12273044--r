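---
title: "Methods: the hoxmeth HOX-cluster methylation pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the hoxmeth HOX-cluster methylation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hoxmeth)
```

`hoxmeth` analyses targeted bisulfite methylation of the four HOX gene
clusters in matched tumour–normal cohorts. This vignette is the package's
own account of the models and procedures it implements, the parameters
that matter, the design decisions that were genuinely open, and the known
limitations — particularly of the synthetic cohorts used to validate each
stage.

## Coordinates and gene regions

All interval tables in the package are 0-based half-open (BED
convention); CpG positions read from coverage files are 1-based, as is
usual for that dialect, and are converted on the fly for containment
tests. `GRanges` is used internally for overlap machinery only.

A gene model is one canonical transcript per gene (no isoform handling):
ordered exons, introns as their exact complement within the gene span,
and a putative promoter spanning 1 kb upstream to 100 bp downstream of
the TSS in transcript orientation, clamped at coordinate 0. Exon and
intron ordinals run 5′→3′, so on the minus strand exon 1 is the
genomically rightmost. Because the promoter's 100 bp tail overlaps the
head of exon 1, a CpG there is deliberately assigned to *both* regions
(`assign_cpg` is a multi-assignment): promoter and first-exon methylation
act jointly on transcription and are often read together, and region
summaries are computed per key independently, so double-assignment is
harmless. UTR regions are derived only when the annotation carries CDS
features; BED12 input yields promoter/exon/intron partitions only.

Natural-antisense (NAT) pairing uses the weakest defensible geometric
criterion — at least 1 bp of exonic overlap on the opposite strand of the
same chromosome — because positional complementarity, not a specific
overlap length, is what licenses an antisense regulatory hypothesis. The
overlap length and the touched exon ordinals are reported so users can
apply stricter filters downstream.

## Region methylation and matched classification

A region's methylation in one sample is the **unweighted** mean of its
per-CpG percentages. Weighting by read depth would conflate coverage
(a technical property of capture efficiency) with biology; the unweighted
mean treats each cytosine as one observation of the region's state.
Percent values are always recomputed from the methylated/unmethylated
counts — the counts are authoritative, and a reported percent deviating
by more than 0.5 from the counts is flagged. Calls with fewer than
`min_coverage = 5` reads are dropped: below that, a single read moves the
percentage by 20 points or more. Regions with no retained CpG propagate
as missing, never as 0 % — "unmethylated" and "unobserved" must not be
confused.

Matched tumour–normal differences are computed **pair-first**: the
difference is taken within each patient and then averaged, rather than
differencing pooled group means. With matched designs this removes
between-patient baseline variation, which is exactly what the matched
sampling paid for. The classification thresholds are strict inequalities
on percentage points: `Δ > 25` hyper, `Δ < −25` hypo, boundary values
classify as `none`. The package deliberately implements threshold
classification without a hypothesis test here: with 6–8 pairs per group a
region-wise test would be underpowered and would suggest a rigour the
design cannot support; the per-CpG profiles report standard errors
instead.

## Constitutively unmethylated regions (CURs)

A CUR is a run of CpGs that stays unmethylated in *every* sample
regardless of group or disease state and contrasts with its flanks.
The implementation factors this into:

| parameter | default | unit | meaning |
|---|---|---|---|
| `tau_unmeth` | 10 | % | every sample must stay strictly under this at an eligible CpG |
| `tau_cur_band` | 10 | % | cross-sample variation bound (range max−min by default; SD optional) |
| `min_cur_cpgs` | 3 | CpGs | minimum run length; also flank size per side |
| `max_gap_bp` | 300 | bp | larger inter-CpG gaps break a run |
| `tau_contrast` | 20 | % | flank mean minus run mean must reach this (waived if no flanks) |

The variation statistic is the **range**, the strictest common reading of
"low variation within and between samples"; an SD-based alternative sits
behind `cur_config(stat = "sd")` for users who prefer robustness to
single outlying samples. The eligibility gate is applied **per CpG**, the
stricter of the two possible readings (per CpG vs per region average);
users should know that this makes calls sensitive to single noisy
samples at single sites. The screened territory runs from the promoter
through the gene's 3′ end, since documented unmethylated regions occur
both upstream of gene bodies and inside exons/introns. CpG-island
overlap is *not* required — the association with islands is an observed
property, not a definition — so an island track, if available, should be
used for annotation rather than filtering.

Two interacting behaviours deserve emphasis, because the synthetic
recovery experiments (`analysis/03_cur_scan.R`, and the recovery test in
the suite) quantify them:

1. **Speckle fragility.** One ineligible CpG splits a run. Under
   beta-binomial noise a CpG whose latent methylation sits near the 10 %
   gate will, across 44 samples, occasionally throw a read count over the
   line; each such speckle halves a planted run. At realistic depths a
   few percent of deeply-unmethylated CpGs fail the every-sample gate, so
   long runs are recovered as several fragments, and the interval
   Jaccard between planted regions and the union of calls plateaus
   around 0.5–0.8 rather than near 1.
2. **Flank pollution.** The flank contrast is computed from the nearest
   *ineligible* CpGs. For a fragment in the middle of a large
   unmethylated region, the nearest ineligible CpGs are the barely-over-
   threshold speckles (≈ 11 %), not genuinely methylated flanks, so the
   fragment fails `tau_contrast` and is dropped entirely. Edge fragments,
   whose flanks include the real ≈ 75 % background, survive.

Both behaviours follow directly from the strict per-CpG, every-sample
definition; they are properties of the criterion, not bugs. On real data
we recommend inspecting the flank composition of rejected fragments and,
where single-sample speckles dominate, re-running with `stat = "sd"` or a
small `tau_cur_band` relaxation. Tightening `tau_unmeth` or
`tau_cur_band` provably never enlarges a call (the eligible set only
shrinks), which the suite asserts.

## The CpG-panel biomarker

The panel classifier's primary feature is the per-sample **mean over the
panel CpGs** (matched tumour−normal difference by default), pooling the
panel rather than fitting one coefficient per locus: with 6–8 pairs per
class a multivariate fit is unidentifiable, and the panel CpGs move
together. A per-locus multivariate mode exists behind
`fit_logistic(feature = "multivariate")` for larger cohorts.

Scores are in-sample fitted probabilities of a maximum-likelihood
logistic model. Three numerical points:

* **Perfect separation.** The likelihood diverges and coefficients run
  away; since the ROC depends only on score order, scoring falls back to
  the rank of the mean feature. Non-convergence triggers the same
  fallback with a warning.
* **Null calibration.** In-sample scoring adapts the coefficient sign to
  the sample, so against random labels its AUC is distributed as
  `max(A, 1−A)` — biased above 0.5 by ≈ `0.8·√(1/(6m))` for `m` per
  class. The package's null-calibration simulation therefore runs at
  n = 200, where the bias (≈ 0.03) is inside the stated ±0.05 band, and
  permutation checks hold the scores fixed while permuting labels, which
  is exactly null-centred at any n. Users bootstrapping small in-sample
  AUCs should be aware of this bias; it is a property of any
  sign-adaptive scorer, not of this implementation.
* **Ties.** The ROC sweeps unique score values; ties contribute ½ to the
  AUC via the Mann–Whitney identity, and the trapezoid integral over the
  stepped curve equals that statistic exactly (asserted against a
  pairwise-concordance oracle).

The 95 % CI is a stratified bootstrap (resampling within each class, so
every replicate retains both classes) with percentile bounds and 2000
replicates — enough that the Monte-Carlo error on the 2.5/97.5
percentiles is well below the reporting precision. The random-forest
out-of-bag AUC is a robustness check only; zero-variance features are
removed first (they admit no split — the upstream implementation
otherwise never returns), and with no informative feature the OOB vote
is the class prior, AUC 0.5 by definition. All ROC analyses here are
in-sample and **descriptive**: with n = 6–8 per group there is no
held-out validation, and the CIs quantify resampling uncertainty, not
generalization.

## Expression integration

Upper-quartile normalization scales each sample so its 75th percentile of
*nonzero* counts (the standard convention, robust to the zero mass)
equals the **geometric mean** of the per-sample quartiles — a symmetric,
scale-balanced reference; any fixed constant would do for correlations,
but the geometric mean keeps normalized counts on the original scale.
The operation is idempotent and per-sample scale-invariant, both
asserted exactly.

Fold changes use `log2((t + c)/(n + c))` with pseudocount `c = 1` on
normalized means. Differential-expression *p*-values are **not** computed
internally — proper count-model inference (dispersion estimation, batch
handling) belongs to dedicated tools; the fold-change table accepts an
externally computed per-gene *p* column and otherwise applies the
`|log2FC| ≥ 1.5` threshold alone, labelled as threshold-only.

Correlations are product-moment with the two-sided *t*-transform
*p*-value on n−2 degrees of freedom, tiered as strong (`|r| > 0.7`) or
moderate (`0.3 < |r| ≤ 0.7`), strict at both boundaries. Raw *p*-values
and Benjamini–Hochberg FDR are both reported; neither is hidden, because
the tier thresholds themselves already act as an effect-size filter.
Constant vectors leave `r` undefined and flag the record rather than
erroring.

## The synthetic cohort generator

The generator emulates the *structure* the pipeline assumes, not any real
dataset: matched normal/tumour pairs in three groups (8/6/8 by default),
a 39-gene four-cluster annotation with six embedded antisense lncRNAs,
and planted signal of four kinds, each recorded in a truth table.

* **Methylation noise** is beta-binomial: a latent level per CpG is
  drawn from a Beta, read depth is Poisson (default mean 100×, typical
  for targeted capture), and methylated reads are Binomial. Bounded,
  overdispersed percentages are what bisulfite data look like; Gaussian
  noise would leak outside [0, 100].
* **Background** CpGs draw Beta(15, 5) (mean 75 %) independently per CpG
  and sample. **Planted CUR** CpGs draw Beta(0.5, 30) (mean ≈ 1.6 %)
  **once per CpG, shared by every sample**: a constitutively
  unmethylated locus is a property of the locus, not of a sample, and
  the per-locus draw is what "regardless of sample type" means
  generatively. CpG positions follow a Poisson process (mean spacing
  30 bp) with a threefold denser stream inside planted CURs, mimicking
  CpG-island density where such regions live.
* **The panel** plants eight CpGs at chr17:46,702,528–46,702,583 with a
  low Beta(2, 38) baseline and group-wise shifts applied on the **logit
  scale** (+5 / +15 / +40 percentage points at the baseline mean for
  PMOL / TN0 / TN0+ tumours), so the group ordering survives clamping
  near the boundaries.
* **Expression** is negative-binomial (size 20) around a log-normal
  gene baseline. Designated coupled genes get a per-sample promoter
  level `m ~ Beta(2, 2)` shared across their promoter CpGs and a
  log-scale expression term `−b·(m − ½)` with `b = 3`; NAT pairs share a
  per-pair latent factor with SD 2 on the log scale, large against the
  residual noise so co-expression is unambiguous.

Everything is deterministic given the seed, and truth tables describe
exactly the planted structure, so recovery tests consume truth tables,
never generator internals.

What the generator does **not** emulate — and therefore what passing
tests do not demonstrate about real data: promoter hypomethylation of
active genes (background is uniformly ≈ 75 %), spatially correlated
methylation along chromosomes beyond the planted blocks, coverage biases
of capture protocols, incomplete bisulfite conversion, non-CpG contexts,
copy-number effects, and cellular heterogeneity of tumours. The
recovery experiments establish that the implementation does what its
definitions say under controlled noise; they are not a claim about
sensitivity or specificity on patient material.

## Problem sizes and reproducibility

The validation suite uses sizes chosen to make the Monte-Carlo error
small relative to every margin tested: 100 seeded cohorts for CUR
recovery/specificity and for permutation-null calibration, 2000
bootstrap replicates per CI, 200 random instances per brute-force-oracle
comparison, and a 30-sample cohort for coupling recovery. All stochastic
functions take explicit seeds and restore the caller's RNG state, so
interleaving package calls never perturbs a user's stream.

## Known limitations

* One canonical transcript per gene; isoform-level promoters and UTRs
  are out of scope.
* The CUR criterion's per-CpG, every-sample strictness trades recall for
  precision; see the fragility discussion above before interpreting
  fragment counts on deep cohorts.
* ROC analyses are in-sample; treat reported AUCs as descriptive
  separation measures, not validated diagnostic performance.
* Differential-expression inference is intentionally delegated to
  dedicated count-model packages.
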