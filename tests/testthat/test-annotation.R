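test_that("packaged HOX annotation has 39 coding genes in 4 clusters", {
  models <- hox_annotation()
  coding <- models$genes[models$genes$biotype == "coding", ]
  expect_equal(nrow(coding), 39L)
  expect_setequal(unique(coding$cluster), c("A", "B", "C", "D"))
  expect_equal(sum(models$genes$biotype == "lncRNA"), 6L)
})

test_that("GTF round-trips through the parser", {
  models <- hox_annotation()
  path <- tempfile(fileext = ".gtf")
  write_annotation_gtf(models, path)
  re <- parse_annotation(path, "gtf")
  expect_equal(nrow(re$genes), nrow(models$genes))
  expect_equal(sum(re$genes$biotype == "coding"), 39L)
  a <- models$exons[order(models$exons$gene_id, models$exons$start), ]
  b <- re$exons[order(re$exons$gene_id, re$exons$start), ]
  expect_equal(b$start, a$start)
  expect_equal(b$end, a$end)
  expect_equal(b$ordinal, a$ordinal)
})

test_that("BED12 dialect parses blocks, strand and tss", {
  path <- tempfile(fileext = ".bed")
  writeLines(c(
    "chrS\t100\t400\tGENEP\t0\t+\t100\t400\t0\t2\t50,100\t0,200",
    "chrS\t1000\t1500\tDEC-AS1\t0\t-\t1000\t1500\t0\t2\t100,100\t0,400"
  ), path)
  m <- parse_annotation(path, "bed12")
  expect_equal(nrow(m$genes), 2L)
  p <- m$genes[m$genes$gene_id == "GENEP", ]
  expect_equal(p$tss, 101)
  expect_equal(p$cluster, "none")
  expect_equal(m$genes$biotype[m$genes$gene_id == "DEC-AS1"], "lncRNA")
  ex <- m$exons[m$exons$gene_id == "GENEP", ]
  expect_equal(ex$start, c(100, 300))
  expect_equal(ex$end, c(150, 400))
  # minus-strand gene: exon 1 is the rightmost block
  exd <- m$exons[m$exons$gene_id == "DEC-AS1", ]
  expect_equal(exd$ordinal[order(exd$start)], c(2L, 1L))
})

test_that("single- and two-exon gene models orient exons and tss by strand", {
  m1 <- mk_models(list(list(id = "G1", chrom = "chrS", strand = "+",
                            exons = rbind(c(100, 200)))))
  expect_equal(m1$genes$tss, 101)
  r1 <- derive_regions(m1)
  expect_false("intron" %in% r1$region_type)

  m2 <- mk_models(list(list(id = "G2", chrom = "chrS", strand = "-",
                            exons = rbind(c(100, 200), c(300, 400)))))
  ex <- m2$exons
  expect_equal(ex$ordinal[ex$start == 300], 1L)
  r2 <- derive_regions(m2)
  intr <- r2[r2$region_type == "intron", ]
  expect_equal(intr$start, 200)
  expect_equal(intr$end, 300)
  expect_equal(intr$ordinal, 1L)
  expect_equal(m2$genes$tss, 400)
})

test_that("strandless and malformed annotations are rejected", {
  expect_error(mk_models(list(list(id = "G", chrom = "c", strand = ".",
                                   exons = rbind(c(1, 10))))),
               "strandless")
  bad <- tempfile(fileext = ".gtf")
  writeLines(c("chrS\tsrc\texon\t1\t100", "chrS"), bad)
  expect_error(parse_annotation(bad, "gtf"), "line 1")
})

test_that("promoter intervals follow strand and clamp at zero", {
  mp <- mk_models(list(list(id = "P", chrom = "c", strand = "+",
                            exons = rbind(c(10000, 12000)))))
  pr <- promoter_interval(mp)
  expect_equal(c(pr$start, pr$end), c(9000, 10100))

  mm <- mk_models(list(list(id = "M", chrom = "c", strand = "-",
                            exons = rbind(c(8000, 10000)))))
  prm <- promoter_interval(mm)
  expect_equal(c(prm$start, prm$end), c(9900, 11000))

  mc <- mk_models(list(list(id = "C", chrom = "c", strand = "+",
                            exons = rbind(c(500, 900)))))
  prc <- promoter_interval(mc)
  expect_equal(c(prc$start, prc$end), c(0, 600))
})

test_that("derived regions partition the gene span and match the oracle", {
  m3 <- mk_models(list(list(id = "G3", chrom = "c", strand = "+",
                            exons = rbind(c(100, 200), c(300, 400),
                                          c(500, 600)))))
  r3 <- derive_regions(m3)
  expect_equal(nrow(r3), 6L)  # promoter + 3 exons + 2 introns

  set.seed(41)
  for (i in 1:20) {
    sp <- rand_gene_spec(paste0("R", i))
    m <- mk_models(list(sp))
    r <- derive_regions(m)
    ex <- r[r$region_type == "exon", ]
    intr <- r[r$region_type == "intron", ]
    want <- oracle_introns(sp$exons[, 1], sp$exons[, 2])
    if (is.null(want)) {
      expect_equal(nrow(intr), 0L)
    } else {
      expect_equal(intr$start[order(intr$start)], want[, 1])
      expect_equal(intr$end[order(intr$start)], want[, 2])
    }
    # length bookkeeping: exons and introns tile the gene span exactly
    expect_equal(sum(ex$end - ex$start) + sum(intr$end - intr$start),
                 m$genes$end - m$genes$start)
  }
})

test_that("UTR regions are emitted only when CDS is supplied", {
  spec <- list(list(id = "U", chrom = "c", strand = "+",
                    exons = rbind(c(100, 300), c(400, 600))))
  cds <- data.frame(gene_id = "U", start = c(150, 400), end = c(300, 500))
  with_cds <- derive_regions(mk_models(spec, cds = cds))
  expect_true(all(c("utr5", "utr3") %in% with_cds$region_type))
  u5 <- with_cds[with_cds$region_type == "utr5", ]
  expect_equal(c(u5$start, u5$end), c(100, 150))
  u3 <- with_cds[with_cds$region_type == "utr3", ]
  expect_equal(c(u3$start, u3$end), c(500, 600))
  without <- derive_regions(mk_models(spec))
  expect_false(any(without$region_type %in% c("utr5", "utr3")))
})

test_that("CpG assignment matches the brute-force containment oracle", {
  m <- mk_models(list(
    list(id = "GX", chrom = "c1", strand = "+",
         exons = rbind(c(1000, 1400), c(1800, 2400))),
    list(id = "GY", chrom = "c1", strand = "-",
         exons = rbind(c(2200, 2600), c(3000, 3400)))))
  regions <- derive_regions(m)

  # a site in intron 1 of GX only
  one <- assign_cpg("c1", 1500, regions)
  expect_equal(one$gene_id, "GX")
  expect_equal(one$region_type, "intron")

  # overlap zone between GX exon 2 and GY exon 2 -> both genes reported
  both <- assign_cpg("c1", 2300, regions)
  expect_setequal(unique(both$gene_id), c("GX", "GY"))

  set.seed(42)
  pos <- sample(1:4500, 1000, replace = TRUE)
  got <- assign_cpg(rep("c1", 1000), pos, regions)
  want <- oracle_assign(rep("c1", 1000), pos, regions)
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got[c("site", "gene_id", "region_type", "ordinal")], want)
})

test_that("NAT pairing requires exonic opposite-strand overlap", {
  m <- mk_models(list(
    list(id = "GENE", chrom = "c", strand = "+",
         exons = rbind(c(200, 300), c(500, 700))),
    list(id = "LNC-AS1", chrom = "c", strand = "-", biotype = "lncRNA",
         exons = rbind(c(150, 250))),
    list(id = "LNC-AS2", chrom = "c", strand = "+", biotype = "lncRNA",
         exons = rbind(c(210, 260)))))     # same strand: no pair
  nat <- find_nat_pairs(m)
  expect_equal(nrow(nat), 1L)
  expect_equal(nat$lncrna_id, "LNC-AS1")
  expect_equal(nat$gene_id, "GENE")
  expect_equal(nat$overlap_bp, 50)
  expect_equal(nat$overlapped_exons, "1")
})

test_that("fixture NAT pairs include the HOTAIRM1-HOXA1 geometry", {
  nat <- find_nat_pairs(hox_annotation())
  key <- paste(nat$lncrna_id, nat$gene_id)
  expect_true("HOTAIRM1 HOXA1" %in% key)
  expect_equal(nrow(nat), 6L)
})

test_that("NAT pairing is invariant to input order and coordinate mirror", {
  models <- hox_annotation()
  nat <- find_nat_pairs(models)
  # permute gene and exon order
  perm <- models
  set.seed(7)
  perm$genes <- perm$genes[sample(nrow(perm$genes)), ]
  perm$exons <- perm$exons[sample(nrow(perm$exons)), ]
  m2 <- gene_models(perm$genes[c("gene_id", "symbol", "biotype", "chrom",
                                 "strand")],
                    perm$exons[c("gene_id", "start", "end")])
  nat2 <- find_nat_pairs(m2)
  o <- function(x) x[order(x$lncrna_id, x$gene_id), ]
  expect_equal(o(nat2)$overlap_bp, o(nat)$overlap_bp)
  expect_equal(o(nat2)$gene_id, o(nat)$gene_id)

  # mirror: reflected coordinates, flipped strands
  mir <- mirror_models(models, M = 2e8)
  natm <- find_nat_pairs(mir)
  expect_equal(o(natm)$overlap_bp, o(nat)$overlap_bp)
  rm_ <- derive_regions(mir); r_ <- derive_regions(models)
  expect_equal(sort(rm_$end - rm_$start), sort(r_$end - r_$start))
})
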