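test_that("cohort simulation is deterministic and honours forced loci", {
  cfg <- cohortConfig(nStrains = 10, chromLength = 1.2e5, nTeLoci = 6,
                      seed = 11)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(as.character(a$reference), as.character(b$reference))
  expect_identical(a$annotations, b$annotations)
  expect_identical(a$truth$presence, b$truth$presence)

  # a single locus at target frequency 1 is planted in every strain
  cfg1 <- cohortConfig(nStrains = 10, chromLength = 1e5, nTeLoci = 1,
                       frequencyMixture = list(c(1.0, 1.0)), seed = 2)
  co1 <- simulateCohort(cfg1)
  expect_true(all(co1$truth$presence))
  expect_equal(co1$truth$loci$realized_freq, 1)

  # planted loci too close together are rejected with a diagnostic
  cfgBad <- cohortConfig(nStrains = 5, chromLength = 1e5, nTeLoci = 2,
                         lociPositions = c(30000, 30500), seed = 1)
  expect_error(simulateCohort(cfgBad), "closer than 2x flank")
})

test_that("strain genomes equal the reference with consensi inserted", {
  cfg <- cohortConfig(nStrains = 6, chromLength = 1e5, nTeLoci = 3,
                      frequencyMixture = list(c(0.6, 1.0)), seed = 5)
  co <- simulateCohort(cfg)
  for (i in seq_len(nrow(co$annotations))) {
    r <- co$annotations[i, ]
    g <- co$genomes[[r$strain]][[r$chrom]]
    ins <- as.character(Biostrings::subseq(g, r$start + 1, r$end))
    expect_identical(ins, as.character(co$consensus[[r$family]]))
  }
  # strain genome length = reference + sum of inserted consensi
  for (s in names(co$genomes)) {
    extra <- sum(co$annotations$length[co$annotations$strain == s])
    expect_equal(length(co$genomes[[s]][[1]]),
                 length(co$reference[[1]]) + extra)
  }
})

test_that("realized frequencies track the target mixture binomially", {
  hits <- 0; total <- 0
  for (s in 1:5) {
    cfg <- cohortConfig(nStrains = 40, chromLength = 6.2e5,
                        nTeLoci = 100,
                        frequencyMixture = list(c(0.05, 0.5),
                                                c(0.5, 0.5)),
                        seed = s)
    co <- simulateCohort(cfg)
    tl <- co$truth$loci
    se <- sqrt(tl$target_freq * (1 - tl$target_freq) / 40)
    ok <- abs(tl$realized_freq - tl$target_freq) <= 3 * se
    hits <- hits + sum(ok); total <- total + length(ok)
    # histogram is bimodal near the two mixture points
    expect_gt(sum(tl$realized_freq < 0.25), 20)
    expect_gt(sum(tl$realized_freq > 0.3), 20)
  }
  expect_gte(hits / total, 0.95)
})

test_that("the founder-mosaic panel has distance-decaying LD", {
  # two founders, no recombination, no mutation: every site's pattern is
  # one of two complementary column patterns
  p2 <- simulateHaplotypes(nHaplotypes = 12, nSites = 40,
                           regionLength = 1e5, mutationDensity = 0,
                           nFounders = 2, recombRate = 0, seed = 3)
  h <- haplotypes(p2)
  pat <- apply(h, 2, paste, collapse = "")
  flip <- apply(1L - h, 2, paste, collapse = "")
  expect_lte(length(unique(c(pat, flip))), 2)

  # degenerate single-founder panel has no polymorphism
  expect_error(simulateHaplotypes(nHaplotypes = 8, nSites = 20,
                                  regionLength = 1e5,
                                  mutationDensity = 0, nFounders = 1,
                                  recombRate = 0, seed = 1),
               "polymorphic")

  # adjacent-site r2 beats long-range r2 on average
  r2 <- function(a, b) suppressWarnings(cor(a, b))^2
  adj <- far <- numeric(0)
  for (s in 1:10) {
    p <- simulateHaplotypes(nHaplotypes = 40, seed = s)
    h <- haplotypes(p)
    pos <- positions(p)
    m <- ncol(h)
    aj <- vapply(seq_len(m - 1), function(j) r2(h[, j], h[, j + 1]), 0)
    pairs <- cbind(sample(m, 200, TRUE), sample(m, 200, TRUE))
    d <- abs(pos[pairs[, 1]] - pos[pairs[, 2]])
    sel <- d > 5e5
    fr <- vapply(which(sel), function(k)
      r2(h[, pairs[k, 1]], h[, pairs[k, 2]]), 0)
    adj <- c(adj, mean(aj, na.rm = TRUE))
    far <- c(far, mean(fr, na.rm = TRUE))
  }
  expect_gt(mean(adj), mean(far))
})

test_that("sweep planting gives the carriers the donor haplotype", {
  panel <- simulateHaplotypes(nHaplotypes = 40, seed = 9)
  # infinite decay: all carriers identical across the whole region
  sw <- plantSweep(panel, sweepConfig(corePosition = 5e5,
                                      carrierFraction = 0.5,
                                      decayScale = Inf, seed = 4))
  h <- haplotypes(sw$panel)
  expect_equal(length(sw$carriers), 20)
  expect_equal(sum(h[, sw$coreSite]), 20)
  carrierRows <- h[sw$carriers, ]
  expect_true(all(apply(carrierRows, 2, function(x) length(unique(x))) ==
                    1))
  cv <- computeEHH(sw$panel, sw$coreSite, "derived", cutoff = 0)
  expect_true(all(cv@left$ehh == 1) && all(cv@right$ehh == 1))
  # non-carriers untouched
  expect_equal(h[-sw$carriers, -sw$coreSite],
               haplotypes(panel)[-sw$carriers, -sw$coreSite])
  # single-carrier sweeps are rejected
  expect_error(plantSweep(panel, sweepConfig(5e5,
                                             carrierFraction = 0.02)),
               "at least 2 carriers")
})

test_that("planted sweeps raise |nSL| at the core versus matched nulls", {
  wins <- 0
  for (s in 1:10) {
    panel <- simulateHaplotypes(nHaplotypes = 40, seed = 300 + s)
    sw <- plantSweep(panel, sweepConfig(corePosition = 5e5,
                                        carrierFraction = 0.6,
                                        seed = 300 + s))
    with_ <- abs(computeNSL(sw$panel, sw$coreSite)$value)
    core0 <- sw$coreSite
    null_ <- abs(computeNSL(panel, core0)$value)
    if (is.na(null_)) null_ <- 0   # maf-floored core in the null panel
    if (!is.na(with_) && with_ > null_) wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("expression simulation adds the planted effect", {
  p <- matrix(rep(c(TRUE, FALSE), each = 10), 20, 1,
              dimnames = list(sprintf("S%02d", 1:20), "2L_5_5_pogo"))
  pm <- PresenceMatrix(p)
  ge <- data.frame(gene_id = c("gEff", "gNull"),
                   locus = c("2L_5_5_pogo", NA), effect = c(1, 0))
  # zero noise separates carriers from non-carriers by exactly the effect
  e0 <- simulateExpression(pm, ge, noiseSd = 0,
                           baselineMean = c(5, 5), seed = 1)
  expect_equal(unname(e0["gEff", 1:10] - e0["gEff", 11:20]), rep(1, 10))
  expect_true(all(e0["gNull", ] == 5))
  # with noise, the carrier gap concentrates around +2 sd over seeds
  gaps <- vapply(1:30, function(s) {
    e <- simulateExpression(pm, data.frame(gene_id = "g",
                                           locus = "2L_5_5_pogo",
                                           effect = 2),
                            noiseSd = 1, baselineMean = 5, seed = s)
    mean(e[1, 1:10]) - mean(e[1, 11:20])
  }, 0)
  expect_lt(abs(mean(gaps) - 2), 3 * sqrt(2 / 10) / sqrt(30) * 3)
  expect_error(simulateExpression(pm, data.frame(gene_id = "g",
                                                 locus = "missing",
                                                 effect = 1)),
               "absent")
})

test_that("neutral-intron placement yields valid calibration sites", {
  panel <- simulateHaplotypes(nHaplotypes = 20, nSites = 200, seed = 2)
  gm <- simulateNeutralIntrons(panel, nNeutral = 50, seed = 2)
  intr <- intronsOf(gm)
  expect_true(all(GenomicRanges::width(intr) <= 65))
  ns <- neutralSites(panel, intr)
  expect_gte(length(ns), 45)
})

test_that("cohorts write to disk and read back consistently", {
  cfg <- cohortConfig(nStrains = 5, chromLength = 1e5, nTeLoci = 3,
                      seed = 8)
  co <- simulateCohort(cfg)
  d <- withr::local_tempdir()
  writeCohort(co, d)
  expect_true(file.exists(file.path(d, "MANIFEST.tsv")))
  ref <- Biostrings::readDNAStringSet(file.path(d, "reference.fa"))
  expect_identical(as.character(ref[[1]]),
                   as.character(co$reference[[1]]))
  s1 <- co$annotations$strain[1]
  bed <- readTeBed(file.path(d, paste0(s1, ".te.bed")), strainId = s1)
  ann <- co$annotations[co$annotations$strain == s1, ]
  expect_equal(bed$start, ann$start)
  expect_equal(bed$family, ann$family)
})
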