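write_cov <- function(lines) {
  path <- tempfile(fileext = ".cov")
  writeLines(lines, path)
  path
}

test_that("coverage reading recomputes percent from counts", {
  p <- write_cov(c("chr17\t46702528\t46702528\t75.0\t3\t1",
                   "chr17\t46702600\t46702600\t0.0\t0\t0",
                   "chr17\t46702700\t46702700\t50.0\t10\t10"))
  calls <- read_coverage(p, "S1", min_coverage = 1)
  expect_equal(nrow(calls), 2L)  # the 0,0 site is uninformative and dropped
  expect_equal(calls$pct[calls$pos == 46702528], 75)
  expect_equal(calls$sample_id, rep("S1", 2))

  # counts are authoritative over an inconsistent percent column
  p2 <- write_cov("chr1\t100\t100\t10.0\t3\t1")
  expect_warning(c2 <- read_coverage(p2, "S", min_coverage = 1),
                 "inconsistent")
  expect_equal(c2$pct, 75)

  # coverage floor
  p3 <- write_cov(c("chr1\t1\t1\t75.0\t3\t1", "chr1\t2\t2\t83.33\t5\t1"))
  expect_equal(nrow(read_coverage(p3, "S", min_coverage = 5)), 1L)

  p4 <- write_cov("chr1\t100\t100\t10.0\tx\t1")
  expect_error(read_coverage(p4, "S"), "parse error")
})

test_that("region means are unweighted CpG averages matching the oracle", {
  calls <- rand_calls("c", c(10, 20, 30), "S1", pct = c(10, 20, 30))
  region <- data.frame(gene_id = "G", region_type = "exon", ordinal = 1,
                       chrom = "c", start = 0, end = 100, strand = "+")
  expect_equal(region_mean(calls, region)$mean_pct, 20)
  one <- rand_calls("c", 50, "S1", pct = 100)
  expect_equal(region_mean(one, region)$mean_pct, 100)
  # zero CpGs -> missing, not zero
  off <- data.frame(gene_id = "G", region_type = "exon", ordinal = 1,
                    chrom = "c", start = 1000, end = 1100, strand = "+")
  expect_true(is.na(region_mean(calls, off)$mean_pct))

  set.seed(11)
  for (i in 1:200) {
    pos <- sort(sample(1:500, 50))
    calls <- rand_calls("c", pos, "S1")
    a <- sample(0:400, 1); b <- a + sample(20:100, 1)
    reg <- data.frame(gene_id = "G", region_type = "exon", ordinal = 1,
                      chrom = "c", start = a, end = b, strand = "+")
    want <- oracle_region_mean(calls, "c", a, b)
    got <- region_mean(calls, reg)$mean_pct
    if (is.na(want)) expect_true(is.na(got))
    else expect_equal(got, want, tolerance = 1e-12)
  }

  # permutation invariance in call order
  calls <- rand_calls("c", 1:30, "S1")
  reg <- data.frame(gene_id = "G", region_type = "exon", ordinal = 1,
                    chrom = "c", start = 0, end = 100, strand = "+")
  shuf <- calls[sample(nrow(calls)), ]
  expect_equal(region_mean(shuf, reg)$mean_pct,
               region_mean(calls, reg)$mean_pct)
})

test_that("matched differences and hyper/hypo classification", {
  expect_equal(matched_delta(60, 20), 40)
  expect_equal(matched_delta(33.3, 33.3), 0)
  expect_equal(classify_diff(30), "hyper")
  expect_equal(classify_diff(-30), "hypo")
  expect_equal(classify_diff(25), "none")    # strict inequality at +25
  expect_equal(classify_diff(-25), "none")
  # step function: monotone, exhaustive, mutually exclusive
  grid <- seq(-100, 100, by = 0.5)
  calls <- classify_diff(grid)
  expect_true(all(calls %in% c("hyper", "hypo", "none")))
  code <- c(hypo = -1, none = 0, hyper = 1)[calls]
  expect_true(all(diff(code) >= 0))
})

test_that("cohort diff table averages per-pair deltas (pair-first)", {
  meta <- mk_pairs_meta(2)
  m <- mk_models(list(list(id = "G", chrom = "c", strand = "+",
                           exons = rbind(c(1000, 2000)))))
  regions <- derive_regions(m)
  pos <- seq(1100, 1900, by = 100)
  pcts <- list("PMOL01.N" = 10, "PMOL01.T" = 50,
               "PMOL02.N" = 20, "PMOL02.T" = 80)
  calls <- do.call(rbind, lapply(names(pcts), function(s) {
    rand_calls("c", pos, s, pct = rep(pcts[[s]], length(pos)))
  }))
  summ <- region_summaries(calls, regions)
  dt <- diff_meth_table(summ, meta)
  ex1 <- dt[dt$region_type == "exon", ]
  expect_equal(ex1$delta_pct, mean(c(40, 60)))
  expect_equal(ex1$call, "hyper")
  expect_equal(ex1$n_pairs, 2L)
  # aggregate-then-difference equals difference-then-aggregate under
  # complete shared CpG support
  pooled_t <- mean(c(50, 80)); pooled_n <- mean(c(10, 20))
  expect_equal(ex1$delta_pct, pooled_t - pooled_n)
  dm <- delta_matrix(dt)
  expect_equal(dm["G.exon.1", "PMOL"], 50)
})

test_that("per-CpG group profiles report mean delta and SE over pairs", {
  meta <- mk_pairs_meta(2)
  loci <- data.frame(chrom = "c", pos = 100)
  calls <- rbind(
    rand_calls("c", 100, "PMOL01.N", pct = 10),
    rand_calls("c", 100, "PMOL01.T", pct = 20),
    rand_calls("c", 100, "PMOL02.N", pct = 10),
    rand_calls("c", 100, "PMOL02.T", pct = 40))
  prof <- group_cpg_profile(calls, meta, "PMOL", loci)
  expect_equal(prof$mean_delta, 20)
  expect_equal(prof$se, 10)  # deltas 10 and 30
  expect_equal(prof$n_pairs, 2L)

  # identical deltas give SE zero
  calls2 <- rbind(
    rand_calls("c", 100, "PMOL01.N", pct = 5),
    rand_calls("c", 100, "PMOL01.T", pct = 30),
    rand_calls("c", 100, "PMOL02.N", pct = 15),
    rand_calls("c", 100, "PMOL02.T", pct = 40))
  expect_equal(group_cpg_profile(calls2, meta, "PMOL", loci)$se, 0)

  # sampling property: per-pair delta ~ Normal(40, 10), n = 8 pairs
  set.seed(99)
  meta8 <- mk_pairs_meta(8)
  base <- runif(8, 10, 30)
  delta <- rnorm(8, 40, 10)
  calls3 <- do.call(rbind, lapply(1:8, function(i) {
    rbind(rand_calls("c", 100, meta8$sample_id[i], pct = base[i]),
          rand_calls("c", 100, meta8$sample_id[i + 8],
                     pct = base[i] + delta[i]))
  }))
  prof3 <- group_cpg_profile(calls3, meta8, "PMOL", loci)
  expect_lt(abs(prof3$mean_delta - 40), 3 * prof3$se + 1e-9)
})
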