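test_that("upper-quartile normalization equalizes nonzero 75th percentiles", {
  set.seed(61)
  m <- matrix(rnbinom(300, mu = 100, size = 5), 50, 6,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:6)))
  norm <- upper_quartile_normalize(m)
  uq <- apply(norm, 2, function(x) quantile(x[x > 0], 0.75, names = FALSE))
  expect_lt(max(uq) - min(uq), 1e-9)
  # zeros preserved
  expect_equal(norm == 0, m == 0)
  # idempotence
  expect_equal(upper_quartile_normalize(norm), norm, tolerance = 1e-12)
  # per-sample scale invariance: a doubled copy normalizes to the original
  m2 <- m; m2[, 2] <- m[, 1] * 2; m2[, 1] <- m[, 1]
  n2 <- upper_quartile_normalize(m2)
  expect_equal(n2[, 1], n2[, 2], ignore_attr = TRUE, tolerance = 1e-12)
  # all-zero sample is an error naming the sample
  mz <- m; mz[, 3] <- 0
  expect_error(upper_quartile_normalize(mz), "s3")
})

test_that("upper-quartile factors agree with the established implementation", {
  skip_if_not_installed("edgeR")
  set.seed(62)
  m <- matrix(rnbinom(600, mu = 200, size = 3) + 1, 100, 6)
  norm <- upper_quartile_normalize(m)
  # our scaling divides each sample by uq_j/ref; edgeR's upperquartile
  # factors equal (uq_j/lib_j) normalized to geometric mean 1 -- compare
  # the implied relative scalings
  f_ours <- apply(m / norm, 2, function(x) unique(round(x, 9))[1])
  fq <- edgeR::calcNormFactors(edgeR::DGEList(counts = m),
                               method = "upperquartile", p = 0.75)
  f_theirs <- fq$samples$norm.factors * fq$samples$lib.size
  f_theirs <- f_theirs / exp(mean(log(f_theirs)))
  expect_equal(f_ours / exp(mean(log(f_ours))), f_theirs,
               ignore_attr = TRUE, tolerance = 1e-6)
})

test_that("log2 fold change honours the pseudocount and antisymmetry", {
  expect_equal(log2_fold_change(8, 2, pseudocount = 0), 2)
  expect_equal(log2_fold_change(7, 7), 0)
  expect_equal(log2_fold_change(0, 7, pseudocount = 1), -3)
  set.seed(63)
  a <- runif(50, 0, 1000); b <- runif(50, 0, 1000)
  expect_equal(log2_fold_change(a, b), -log2_fold_change(b, a))

  fc <- fold_change_table(c(g1 = 80, g2 = 10, g3 = 100),
                          c(g1 = 10, g2 = 10, g3 = 400))
  expect_equal(fc$passes, c(TRUE, FALSE, TRUE))
  expect_true(all(abs(fc$log2fc[fc$passes]) >= 1.5))
  fcp <- fold_change_table(c(80, 80), c(10, 10), p = c(0.01, 0.2))
  expect_equal(fcp$passes, c(TRUE, FALSE))
})

test_that("pearson records match the covariance/variance oracle", {
  p1 <- pearson(1:10, 1:10)
  expect_equal(p1$r, 1)
  expect_equal(p1$tier, "strong")
  expect_equal(pearson(1:10, 10:1)$r, -1)
  p2 <- pearson(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(p2$r, 0.6, tolerance = 1e-12)
  expect_equal(p2$tier, "moderate")
  expect_true(pearson(rep(1, 5), 1:5)$flagged)

  set.seed(64)
  for (i in 1:500) {
    n <- sample(3:30, 1)
    x <- rnorm(n); y <- rnorm(n)
    got <- pearson(x, y)
    want <- oracle_pearson(x, y)
    expect_equal(got$r, want$r, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-9)
  }
})

test_that("correlation tiers are exhaustive and mutually exclusive", {
  grid <- c(seq(-1, 1, by = 0.05), -0.7 - 1e-9, -0.7, -0.3, 0.3, 0.3 + 1e-9,
            0.7, 0.7 + 1e-9)
  tiers <- correlation_tier(grid)
  expect_true(all(tiers %in% c("none", "moderate", "strong")))
  expect_equal(correlation_tier(0.7), "moderate")   # strong is strict > 0.7
  expect_equal(correlation_tier(0.3), "none")       # moderate is strict > 0.3
  expect_equal(correlation_tier(-0.71), "strong")
  want <- ifelse(abs(grid) > 0.7, "strong",
                 ifelse(abs(grid) > 0.3, "moderate", "none"))
  expect_equal(tiers, want)
})

test_that("methylation-expression association recovers planted coupling", {
  set.seed(65)
  n <- 30
  samples <- paste0("s", seq_len(n))
  genes <- paste0("g", 1:20)
  meth <- matrix(runif(20 * n, 0, 100), 20, n,
                 dimnames = list(genes, samples))
  expr <- matrix(rnorm(20 * n, 500, 50), 20, n,
                 dimnames = list(genes, samples))
  # plant inverse coupling in the first 10 genes
  for (g in 1:10) expr[g, ] <- 800 - 6 * meth[g, ] + rnorm(n, 0, 60)
  summaries <- do.call(rbind, lapply(genes, function(g) {
    data.frame(gene_id = g, region_type = "promoter", ordinal = 0L,
               sample_id = samples, mean_pct = meth[g, ], n_cpgs = 5L,
               stringsAsFactors = FALSE)
  }))
  assoc <- meth_expr_association(summaries, expr)
  planted <- assoc[assoc$gene_id %in% paste0("g", 1:10), ]
  expect_true(all(planted$r < 0))
  expect_true(all(planted$direction == "inverse"))
  null <- assoc[assoc$gene_id %in% paste0("g", 11:20), ]
  expect_lte(sum(abs(null$r) > 0.7), 1)
  expect_true(all(c("fdr", "p") %in% names(assoc)))
  expect_true(all(assoc$fdr >= assoc$p))

  # constant methylation is skipped with a flag
  summaries$mean_pct[summaries$gene_id == "g20"] <- 40
  assoc2 <- meth_expr_association(summaries, expr)
  expect_true(assoc2$flagged[assoc2$gene_id == "g20"])
})

test_that("NAT concordance finds shared-factor pairs and skips absentees", {
  set.seed(66)
  n <- 30
  expr <- matrix(rnorm(8 * n, 0, 1), 8, n,
                 dimnames = list(c(paste0("lnc", 1:3), paste0("cod", 1:3),
                                   "x1", "x2"), paste0("s", 1:n)))
  for (i in 1:3) {
    f <- rnorm(n, 0, 3)
    expr[paste0("lnc", i), ] <- f + rnorm(n, 0, 1)
    expr[paste0("cod", i), ] <- f + rnorm(n, 0, 1)
  }
  pairs <- data.frame(
    lncrna_id = c(paste0("lnc", 1:3), "x1", "ghost"),
    gene_id = c(paste0("cod", 1:3), "x2", "cod1"),
    stringsAsFactors = FALSE)
  nc <- nat_concordance(pairs, expr)
  expect_equal(nrow(nc), 4L)  # ghost pair skipped
  expect_true(all(nc$tier[1:3] == "strong"))
  expect_equal(nc$tier[nc$lncrna_id == "x1"], "none")
})
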