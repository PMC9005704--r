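test_that("SNP-TE pairing uses a strict sub-kilobase window", {
  loci <- data.frame(group_id = c("2L_5000_5300_pogo", "2L_9000_9100_Doc"),
                     chrom = "2L", start = c(5000, 9000),
                     end = c(5300, 9100), family = c("pogo", "Doc"))
  # 0-based TE [5000,5300); SNP at 1-based 4101 is 900 bp from the edge
  snps <- data.frame(chrom = "2L",
                     pos = c(4101, 4001, 5150, 6400),
                     site = 1:4, statistic = "nsl")
  pr <- pairTeSnp(loci, snps, window = 1000)
  got <- pr[pr$group_id == "2L_5000_5300_pogo", ]
  expect_equal(got$snp_pos, c(4101, 5150))       # 900 bp and inside
  expect_equal(got$distance, c(900, 0))
  # exactly 1000 bp away is rejected (strict <): pos 4001 -> distance 1000
  expect_false(4001 %in% got$snp_pos)
  # 6400 is 1100 bp past the end
  expect_false(6400 %in% got$snp_pos)
})

test_that("the carrier co-occurrence rule follows the printed thresholds", {
  expect_true(cooccurrenceTest(5, 4, 0)$pass)
  expect_false(cooccurrenceTest(6, 3, 0)$pass)
  expect_true(cooccurrenceTest(6, 4, 0)$pass)
  # majority rule for 7+ carriers is strict
  expect_true(cooccurrenceTest(9, 5, 0)$pass)
  expect_false(cooccurrenceTest(8, 4, 0)$pass)
  expect_true(cooccurrenceTest(8, 5, 0)$pass)
  # the absence clause: any TE in an allele-non-carrier fails
  r <- cooccurrenceTest(9, 5, 1)
  expect_false(r$pass)
  expect_equal(r$reason, "te-in-allele-non-carrier")
  # below the rule's domain
  expect_false(cooccurrenceTest(4, 4, 0)$pass)
  expect_error(cooccurrenceTest(5, 6, 0), "inconsistent")
})

test_that("co-occurrence depends only on the tallies", {
  set.seed(31)
  te <- sample(c(TRUE, FALSE), 20, TRUE)
  al <- sample(c(TRUE, FALSE), 20, TRUE)
  t1 <- tallyCooccurrence(te, al)
  perm <- sample(20)
  t2 <- tallyCooccurrence(te[perm], al[perm])
  expect_identical(t1, t2)
  expect_equal(t1$nBoth + t1$nAbsentAlleleWithTE, t1$nTE)
})

test_that("candidate filtering audits every removal", {
  p <- matrix(FALSE, 20, 5, dimnames = list(
    sprintf("S%02d", 1:20),
    c("2L_1000_1030_accord", "2L_5000_5030_INE-1",
      "2L_9000_9030_pogo", "2L_40000_40030_Doc",
      "2L_15000_15030_roo")))
  p[1:12, 1] <- TRUE    # 60%, kept
  p[1:10, 2] <- TRUE    # 50% but INE-1 -> excluded family
  p[1, 3] <- TRUE       # 5% -> rare
  p[1:20, 4] <- TRUE    # 100% -> fixed
  p[1:10, 5] <- TRUE    # 50% but zero recombination at its window
  pm <- PresenceMatrix(p)
  map <- data.frame(chrom = "2L", start = c(0, 12000),
                    end = c(12000, 50000), rate = c(1.5, 0))
  cf <- candidateFilter(pm, map)
  expect_equal(cf$pool$group_id, "2L_1000_1030_accord")
  expect_equal(unname(cf$audit["removed_frequency"]), 2)
  expect_equal(unname(cf$audit["removed_recombination"]), 1)
  expect_equal(unname(cf$audit["removed_family"]), 1)
  # conservation: input = retained + sum(removed)
  expect_equal(unname(cf$audit["input"]),
               sum(cf$audit[c("removed_frequency",
                              "removed_recombination",
                              "removed_family", "retained")]))
  # boundary frequencies are inclusive: exactly 10% and exactly 95%
  p2 <- matrix(FALSE, 20, 2,
               dimnames = list(sprintf("S%02d", 1:20),
                               c("2L_1000_1010_roo",
                                 "2L_2000_2010_roo")))
  p2[1:2, 1] <- TRUE    # 10%
  p2[1:19, 2] <- TRUE   # 95%
  cf2 <- candidateFilter(PresenceMatrix(p2),
                         data.frame(chrom = "2L", start = 0, end = 1e5,
                                    rate = 1))
  expect_equal(nrow(cf2$pool), 2)
})

test_that("gene context resolves promoter, features and intergenic", {
  gm <- makeGeneModels(
    genes = data.frame(gene_id = "gA", chrom = "2L", start = 10000,
                       end = 14000, strand = "+"),
    exons = data.frame(gene_id = "gA", start = c(10000, 12000),
                       end = c(10800, 14000)))
  # TE 300 bp upstream of the TSS on a plus-strand gene -> PROMOTER
  te <- list(chrom = "2L", start = 9600, end = 9700)
  ctx <- assignGeneContext(te, gm)
  expect_equal(ctx$location, "PROMOTER")
  expect_equal(ctx$gene_id, "gA")
  # TE inside the intron
  ctx2 <- assignGeneContext(list(chrom = "2L", start = 11000,
                                 end = 11100), gm)
  expect_equal(ctx2$location, "INTRON")
  # TE overlapping an exon (CDS)
  ctx3 <- assignGeneContext(list(chrom = "2L", start = 12500,
                                 end = 12900), gm)
  expect_equal(ctx3$location, "CDS")
  # 1.2 kb away -> Intergenic
  ctx4 <- assignGeneContext(list(chrom = "2L", start = 8000,
                                 end = 8800), gm)
  expect_equal(ctx4$location, "Intergenic")
  # nearby but not upstream (downstream of gene end) -> not a promoter
  ctx5 <- assignGeneContext(list(chrom = "2L", start = 14100,
                                 end = 14200), gm)
  expect_equal(ctx5$location, "Intergenic")
  expect_equal(ctx5$gene_id, "gA")
  # a TE overlapping two genes reports both
  gm2 <- makeGeneModels(
    genes = data.frame(gene_id = c("g1", "g2"), chrom = "2L",
                       start = c(1000, 1900), end = c(2000, 3000),
                       strand = "+"))
  ctx6 <- assignGeneContext(list(chrom = "2L", start = 1850,
                                 end = 1980), gm2)
  expect_setequal(ctx6$gene_id, c("g1", "g2"))
})

test_that("family enrichment matches closed-form chi-square and BH", {
  # 2x2 table [[30,70],[10,190]], closed form without correction:
  # N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)) = 300 * 5000^2 / 2.08e8
  focal <- c(rep("P", 30), rep("other", 70))
  backg <- c(rep("P", 10), rep("other", 190))
  et <- enrichmentTest(focal, backg, backgroundIncludesFocal = FALSE)
  byHand <- 300 * (30 * 190 - 70 * 10)^2 / (100 * 200 * 40 * 260)
  expect_equal(et$statistic[et$group == "P"], byHand, tolerance = 1e-9)
  tab <- matrix(c(30, 70, 10, 190), 2, byrow = TRUE)
  want <- unname(suppressWarnings(
    stats::chisq.test(tab, correct = FALSE))$statistic)
  expect_equal(et$statistic[et$group == "P"], want)
  # identical composition -> p near 1
  et2 <- enrichmentTest(c("a", "a", "b", "b"),
                        c(rep("a", 50), rep("b", 50)),
                        backgroundIncludesFocal = FALSE)
  expect_true(all(et2$p > 0.9))
  # BH adjustment of {0.01, 0.02, 0.04} -> {0.03, 0.03, 0.04}
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), "BH"),
               c(0.03, 0.03, 0.04))
  expect_equal(et$fdr, p.adjust(et$p, "BH"))
  # sparse cells switch to Fisher's exact test
  et3 <- enrichmentTest(c("z", "a"), c(rep("a", 3), "z"),
                        backgroundIncludesFocal = FALSE)
  expect_true("fisher" %in% et3$test)
})

test_that("the sweep screen flags the linked TE, not the unlinked ones", {
  hits <- 0; fp <- 0; nUn <- 0
  for (s in c(2, 5, 8)) {
    sc <- simulateSweepCohort(seed = s)
    res <- sweepCandidateScreen(sc$panel, sc$pm, sc$gm, sc$recombMap)
    hits <- hits + (sc$linkedGroup %in% res$candidates)
    fp <- fp + sum(sc$unlinkedGroups %in% res$candidates)
    nUn <- nUn + length(sc$unlinkedGroups)
  }
  expect_gte(hits, 2)
  expect_lte(fp / nUn, 0.1)
})
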