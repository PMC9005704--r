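# a tiny deterministic genome pair used by the flank-level tests:
# the strain carries one 300 bp insertion at position 5000 of a 20 kb
# random reference
makeToyPair <- function(seed = 1, dupFlank = FALSE) {
  set.seed(seed)
  refSeq <- paste(sample(c("A", "C", "G", "T"), 20000, TRUE),
                  collapse = "")
  if (dupFlank) {
    # copy the left-flank region elsewhere so it maps twice
    block <- substr(refSeq, 4001, 5000)
    refSeq <- paste0(substr(refSeq, 1, 14000), block,
                     substr(refSeq, 15001, 20000))
  }
  te <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  strainSeq <- paste0(substr(refSeq, 1, 5000), te,
                      substr(refSeq, 5001, 20000))
  list(ref = Biostrings::DNAStringSet(c(chr1 = refSeq)),
       strain = Biostrings::DNAStringSet(c(chr1 = strainSeq)),
       te = data.frame(strain = "S1", chrom = "chr1", start = 5000,
                       end = 5300, family = "pogo", length = 300))
}

test_that("flank extraction respects boundaries and truncation", {
  tp <- makeToyPair()
  fl <- extractFlanks(tp$te, tp$strain, flankBp = 1000)
  expect_equal(c(fl$left$start, fl$left$end), c(4000, 5000))
  expect_equal(c(fl$right$start, fl$right$end), c(5300, 6300))
  expect_false(fl$left$truncated)
  # flank sequences re-locate at their source coordinates
  s <- as.character(tp$strain[[1]])
  expect_identical(fl$left$seq, substr(s, 4001, 5000))
  expect_identical(fl$right$seq, substr(s, 5301, 6300))
  # TE near the start: left flank truncated at 0
  te2 <- data.frame(chrom = "chr1", start = 200, end = 500)
  fl2 <- extractFlanks(te2, tp$strain, flankBp = 1000)
  expect_equal(c(fl2$left$start, fl2$left$end), c(0, 200))
  expect_true(fl2$left$truncated)
})

test_that("flank placement classifies unequivocal/multiple/partial", {
  tp <- makeToyPair()
  fl <- extractFlanks(tp$te, tp$strain, flankBp = 1000)
  fp <- placeFlanks(fl, tp$ref)
  expect_equal(fp$left$class, "unequivocal")
  expect_equal(fp$right$class, "unequivocal")
  expect_equal(fp$left$placements$end, 5000)
  expect_equal(fp$right$placements$start, 5000)

  # duplicated left-flank region maps twice -> multiple
  tpd <- makeToyPair(dupFlank = TRUE)
  fld <- extractFlanks(tpd$te, tpd$strain, flankBp = 1000)
  fpd <- placeFlanks(fld, tpd$ref)
  expect_equal(fpd$left$class, "multiple")
  expect_equal(nrow(fpd$left$placements), 2)

  # a flank whose outer half is foreign maps only through its TE-
  # proximal half -> partial
  flp <- fl
  set.seed(99)
  flp$left$seq <- paste0(paste(sample(c("A", "C", "G", "T"), 500, TRUE),
                               collapse = ""),
                         substr(fl$left$seq, 501, 1000))
  fpp <- placeFlanks(flp, tp$ref)
  expect_equal(fpp$left$class, "partial")
})

test_that("transfer classification projects intervals and gives reasons", {
  tp <- makeToyPair()
  fl <- extractFlanks(tp$te, tp$strain, flankBp = 1000)
  fp <- placeFlanks(fl, tp$ref)
  tr <- classifyTransfer(fp, fl, teLength = 300)
  expect_true(tr$reliable)
  # insertion absent from the reference: zero-length projection
  expect_equal(tr$ref_start, 5000)
  expect_equal(tr$ref_end, 5000)

  # flanks placed on different chromosomes -> unreliable
  fpX <- fp
  fpX$right$placements$chrom <- "chr2"
  trX <- classifyTransfer(fpX, fl, teLength = 300)
  expect_false(trX$reliable)
  expect_equal(trX$reason, "different-chromosomes")

  # a 4 bp reference gap stays reliable (target-site duplication scale)
  fp4 <- fp
  fp4$right$placements$start <- 5004
  tr4 <- classifyTransfer(fp4, fl, teLength = 300)
  expect_true(tr4$reliable)
  expect_equal(tr4$ref_end - tr4$ref_start, 4)

  # gap far beyond tolerance -> unreliable
  fpG <- fp
  fpG$right$placements$start <- 9000
  trG <- classifyTransfer(fpG, fl, teLength = 300)
  expect_false(trG$reliable)
  expect_equal(trG$reason, "gap-exceeds-tolerance")

  # both flanks unmapped -> explicit reason
  fpU <- fp
  fpU$left$class <- fpU$right$class <- "unmapped"
  expect_equal(classifyTransfer(fpU, fl, 300)$reason,
               "both-flanks-unmapped")
})

test_that("a multiple-mapping flank is rescued by a shared gene anchor", {
  tp <- makeToyPair(dupFlank = TRUE)
  fl <- extractFlanks(tp$te, tp$strain, flankBp = 1000)
  fp <- placeFlanks(fl, tp$ref)
  expect_equal(fp$left$class, "multiple")
  # without anchors the transfer is unreliable
  expect_false(classifyTransfer(fp, fl, 300)$reliable)
  # shared nearest gene on strain and reference rescues the placement
  refGenes <- GenomicRanges::GRanges("chr1",
                                     IRanges::IRanges(3000, 3500),
                                     gene_id = "gA")
  strainGenes <- refGenes  # same coordinates upstream of the insertion
  tr <- classifyTransfer(fp, fl, 300, strainGenes = strainGenes,
                         refGenes = refGenes)
  expect_true(tr$reliable)
  expect_equal(tr$note, "rescued")
  expect_equal(tr$ref_start, 5000)
  # an anchor mismatch blocks the rescue
  refGenes2 <- GenomicRanges::GRanges("chr1",
                                      IRanges::IRanges(3000, 3500),
                                      gene_id = "gB")
  trBad <- classifyTransfer(fp, fl, 300, strainGenes = strainGenes,
                            refGenes = refGenes2)
  expect_false(trBad$reliable)
})

test_that("ortholog clustering is family-aware with 1-D single linkage", {
  mk <- function(strain, start, family, len = 200)
    data.frame(strain = strain, chrom = "chr1", start = 1, end = 1 + len,
               family = family, length = len, ref_chrom = "2L",
               ref_start = start, ref_end = start, strand = "+",
               reliable = TRUE, reason = "ok", note = "clean")
  strains <- c("S1", "S2", "S3")
  # same position, same family -> one group of frequency 2/3
  tr <- rbind(mk("S1", 1000, "pogo"), mk("S2", 1000, "pogo"))
  og <- clusterOrthologs(tr, strains)
  expect_equal(ncol(presence(og$pm)), 1)
  expect_equal(unname(teFrequencies(og$pm)), 2 / 3)
  # same position, different family -> two groups
  tr2 <- rbind(mk("S1", 1000, "pogo"), mk("S2", 1000, "Doc"))
  og2 <- clusterOrthologs(tr2, strains)
  expect_equal(ncol(presence(og2$pm)), 2)
  # 250 bp apart with 100 bp tolerance -> two groups
  tr3 <- rbind(mk("S1", 1000, "pogo"), mk("S2", 1250, "pogo"))
  og3 <- clusterOrthologs(tr3, strains, positionTolerance = 100)
  expect_equal(ncol(presence(og3$pm)), 2)
  # brute-force pairwise single linkage agrees on random 1-D instances
  for (s in 1:10) {
    set.seed(s)
    n <- 15
    mids <- sort(sample(1e5, n))
    trR <- do.call(rbind, lapply(seq_len(n), function(i)
      mk(paste0("S", i), mids[i], "pogo")))
    og <- clusterOrthologs(trR, paste0("S", 1:n),
                           positionTolerance = 500)
    # oracle: connected components of the <=500 bp adjacency graph
    adj <- abs(outer(mids, mids, "-")) <= 500
    comp <- seq_len(n)
    repeat {
      new <- vapply(seq_len(n), function(i) min(comp[adj[i, ]]), 0)
      if (identical(new, comp)) break
      comp <- new
    }
    expect_equal(ncol(presence(og$pm)), length(unique(comp)))
  }
  # two insertions of one strain in a cluster: one kept, one tandem
  tr4 <- rbind(mk("S1", 1000, "pogo"), mk("S1", 1050, "pogo"),
               mk("S2", 1010, "pogo"))
  og4 <- clusterOrthologs(tr4, strains)
  expect_equal(ncol(presence(og4$pm)), 1)
  expect_equal(sum(og4$members$tandem), 1)
})

test_that("clustering is invariant to strain input order", {
  cfg <- cohortConfig(nStrains = 8, chromLength = 1.2e5, nTeLoci = 8,
                      seed = 21)
  co <- simulateCohort(cfg)
  tr <- transferCohort(co$annotations, co$genomes, co$reference)
  og1 <- clusterOrthologs(tr, rownames(co$truth$presence))
  perm <- tr[rev(seq_len(nrow(tr))), ]
  og2 <- clusterOrthologs(perm, rownames(co$truth$presence))
  expect_equal(colnames(presence(og1$pm)), colnames(presence(og2$pm)))
  expect_equal(presence(og1$pm), presence(og2$pm))
  # bookkeeping: records in = reliable + unreliable
  expect_equal(nrow(tr), sum(tr$reliable) + sum(!tr$reliable))
})

test_that("the length-majority group filter is strict", {
  mkOg <- function(lengths) {
    members <- data.frame(group_id = "g", strain = paste0("S",
                                                          seq_along(lengths)),
                          length = lengths, ref_start = 1, ref_end = 1,
                          tandem = FALSE)
    pres <- matrix(TRUE, length(lengths), 1,
                   dimnames = list(members$strain, "g"))
    structure(list(pm = PresenceMatrix(pres, lociInfo = data.frame(
      group_id = "g", chrom = "2L", start = 1, end = 1,
      family = "pogo", row.names = "g")), members = members),
      class = "orthologGroups")
  }
  # 3 of 5 above 120 bp -> kept
  expect_equal(ncol(presence(filterGroupsByLength(
    mkOg(c(150, 130, 140, 90, 80)))$pm)), 1)
  # 1 of 3 -> removed
  expect_equal(ncol(presence(filterGroupsByLength(
    mkOg(c(90, 80, 150)))$pm)), 0)
  # exactly half -> removed (strictly more than half required)
  expect_equal(ncol(presence(filterGroupsByLength(
    mkOg(c(150, 130, 90, 80)))$pm)), 0)
})

test_that("annotation post-filters drop short and satellite copies", {
  rec <- data.frame(chrom = "2L", start = c(0, 0, 1000),
                    end = c(99, 100, 1200), family = "pogo")
  out <- postfilterAnnotation(rec)
  # 99 bp removed, 100 bp retained (strict <100)
  expect_equal(out$end, c(100, 1200))
  # 85% satellite overlap removes the copy; 80% keeps it
  sat <- data.frame(chrom = "2L", start = 1000, end = 1170)
  out2 <- postfilterAnnotation(rec[3, ], satellites = sat)
  expect_equal(nrow(out2), 0)
  sat2 <- data.frame(chrom = "2L", start = 1000, end = 1160)
  out3 <- postfilterAnnotation(rec[3, ], satellites = sat2)
  expect_equal(nrow(out3), 1)
})

test_that("annotation comparison enforces reciprocal coverage + family", {
  a <- data.frame(chrom = "2L", start = c(100, 5000),
                  end = c(1100, 6000), family = c("pogo", "Doc"))
  # identical sets match fully both ways
  cmp <- compareAnnotations(a, a)
  expect_equal(cmp$summary$matchedA, 2)
  expect_equal(cmp$summary$fracB, 1)
  # 96%/97% reciprocal overlap, same family -> matched
  b <- data.frame(chrom = "2L", start = 130, end = 1100,
                  family = "pogo")
  cmp2 <- compareAnnotations(a[1, ], b)
  expect_equal(cmp2$summary$matchedA, 1)
  # same overlap, different family -> unmatched
  b2 <- transform(b, family = "Doc")
  cmp3 <- compareAnnotations(a[1, ], b2)
  expect_equal(cmp3$summary$matchedA, 0)
  # 50% overlap fails the 95% requirement
  b3 <- data.frame(chrom = "2L", start = 600, end = 1600,
                   family = "pogo")
  expect_equal(compareAnnotations(a[1, ], b3)$summary$matchedA, 0)
})

test_that("synthetic cohorts round-trip with truth-equal presence", {
  recs <- vapply(1:3, function(s) {
    cfg <- cohortConfig(nStrains = 12, chromLength = 1.5e5,
                        nTeLoci = 12, seed = 400 + s)
    rt <- orthologyRoundTrip(simulateCohort(cfg))
    rt$recovery
  }, 0)
  expect_true(all(recs >= 0.99))
})
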