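test_that("EHH follows the pair-counting definition on a hand example", {
  # 3 derived carriers with flanking alleles (0,0), (0,0), (0,1):
  # EHH at the first right flank site = 1, at the second = C(2,2)/C(3,2)
  hap <- rbind(c(1, 0, 0),
               c(1, 0, 0),
               c(1, 0, 1),
               c(0, 1, 1),
               c(0, 1, 0))
  p <- HaplotypePanel(hap, c(100, 200, 300))
  cv <- computeEHH(p, 1, "derived", cutoff = 0)
  expect_equal(cv@right$ehh, c(1, 1 / 3))
  # 4 identical carriers: EHH = 1 at every extension
  hap2 <- rbind(matrix(1L, 4, 5), matrix(0L, 2, 5))
  hap2[5:6, 3] <- 1L  # keep non-core sites polymorphic
  hap2[5, 5] <- 1L
  p2 <- HaplotypePanel(hap2, seq(100, 500, 100))
  cv2 <- computeEHH(p2, 1, "derived", cutoff = 0)
  expect_true(all(cv2@right$ehh == 1))
})

test_that("EHH curves are non-increasing and match brute force", {
  for (s in 1:30) {
    panel <- randomPanel(sample(6:14, 1), sample(12:30, 1), seed = s)
    hap <- haplotypes(panel)
    core <- sample(ncol(hap), 1)
    for (allele in c(0L, 1L)) {
      rows <- which(hap[, core] == allele)
      if (length(rows) < 2) next
      nm <- if (allele == 1L) "derived" else "ancestral"
      cv <- computeEHH(panel, core, nm, cutoff = 0)
      for (df in list(cv@left, cv@right))
        if (nrow(df) > 1) expect_true(all(diff(df$ehh) <= 1e-12))
      if (nrow(cv@right)) {
        want <- vapply(cv@right$site, function(j)
          bruteEhhAt(hap, rows, core, j), 0)
        expect_equal(cv@right$ehh, want, tolerance = 1e-12)
      }
      if (nrow(cv@left)) {
        want <- vapply(cv@left$site, function(j)
          bruteEhhAt(hap, rows, core, j), 0)
        expect_equal(cv@left$ehh, want, tolerance = 1e-12)
      }
    }
  }
})

test_that("iHH integration applies the trapezoid and truncation rule", {
  cv <- new("EHHCurve", core = 1L, allele = "derived",
            left = data.frame(site = integer(0), distPhys = numeric(0),
                              distGen = numeric(0),
                              distSites = integer(0), ehh = numeric(0)),
            right = data.frame(site = 2:3, distPhys = c(1000, 2000),
                               distGen = NA_real_, distSites = 1:2,
                               ehh = c(0.5, 0.04)),
            truncLeft = "cutoff", truncRight = "cutoff")
  # (0,1),(1000,0.5),(2000,0.04): 750 + 270, left side contributes 0
  expect_equal(integrateIHH(cv, 0.05, "physical")$value, 1020)
  # cutoff 0: the whole curve integrates
  expect_equal(integrateIHH(cv, 0, "physical")$value,
               750 + 270)
  # flat EHH = 1 over 10 kb: rectangle
  cv2 <- new("EHHCurve", core = 1L, allele = "derived",
             left = cv@left,
             right = data.frame(site = 2L, distPhys = 10000,
                                distGen = NA_real_, distSites = 1L,
                                ehh = 1),
             truncLeft = "cutoff", truncRight = "chromosome-end")
  r <- integrateIHH(cv2, 0.05, "physical")
  expect_equal(r$value, 10000)
  expect_true(r$truncated)
})

test_that("iHS is zero under allele-label symmetry and negates on swap", {
  # panel symmetric under relabeling 0<->1 at the core
  hap <- rbind(c(1, 1, 0, 1), c(1, 0, 1, 1),
               c(0, 0, 1, 0), c(0, 1, 0, 0))
  p <- HaplotypePanel(hap, c(10, 500, 900, 1300))
  v <- computeIHS(p, 2, cutoff = 0, mafFloor = 0)
  expect_equal(v$value, 0)
  for (s in 1:10) {
    panel <- randomPanel(10, 20, seed = 100 + s)
    hap <- haplotypes(panel)
    core <- 10L
    v1 <- computeIHS(panel, core, mafFloor = 0)
    hap2 <- hap; hap2[, core] <- 1L - hap2[, core]
    v2 <- computeIHS(HaplotypePanel(hap2, positions(panel)), core,
                     mafFloor = 0)
    if (!is.na(v1$value) && !is.na(v2$value))
      expect_equal(v1$value, -v2$value, tolerance = 1e-12)
    n1 <- computeNSL(panel, core, mafFloor = 0)
    n2 <- computeNSL(HaplotypePanel(hap2, positions(panel)), core,
                     mafFloor = 0)
    expect_equal(n1$value, -n2$value, tolerance = 1e-12)
  }
})

test_that("nSL counts sites in the maximal shared interval", {
  # two derived carriers identical over 7 sites left and 4 right of the
  # core: pair length 12 (7 + core + 4)
  m <- 16
  core <- 9L
  h1 <- rep(0L, m)
  h2 <- rep(0L, m)
  h1[core] <- h2[core] <- 1L
  h2[1] <- 1L      # breaks identity beyond 7 sites left
  h2[14] <- 1L     # breaks identity beyond 4 sites right
  filler1 <- rep(c(0L, 1L), length.out = m)
  filler2 <- rep(c(1L, 0L), length.out = m)
  filler1[core] <- filler2[core] <- 0L
  hap <- rbind(h1, h2, filler1, filler2)
  p <- HaplotypePanel(hap, seq_len(m) * 100)
  got <- computeNSL(p, core, mafFloor = 0)
  want <- bruteNSL(hap, core, mafFloor = 0)
  expect_equal(got$value, want, tolerance = 1e-12)
  # the derived pair length is exactly 12
  cvD <- computeEHH(p, core, "derived", cutoff = 0)
  expect_equal(1 + sum(cvD@left$ehh) + sum(cvD@right$ehh), 12)
})

test_that("iHH12 pools the two largest classes", {
  # classes of sizes {2,2,1}: EHH12 = C(4,2)/C(5,2) = 6/10
  hap <- rbind(c(1, 0, 0), c(1, 0, 0),
               c(0, 1, 0), c(0, 1, 0),
               c(0, 0, 1))
  expect_equal(bruteEhh12At(hap, 1, 2), 6 / 10)
  p <- HaplotypePanel(hap, c(100, 200, 300))
  cv <- computeEHH(p, 1, "combined-top2", cutoff = 0)
  expect_equal(cv@right$ehh[1], 6 / 10)
  # pooled EHH12 >= plain EHH over all haplotypes at every extension
  for (s in 1:10) {
    panel <- randomPanel(8, 15, seed = 200 + s)
    hap <- haplotypes(panel)
    core <- 8L
    cv <- computeEHH(panel, core, "combined-top2", cutoff = 0)
    for (j in seq_len(nrow(cv@right))) {
      plain <- bruteEhhAt(hap, seq_len(nrow(hap)), core,
                          cv@right$site[j])
      expect_gte(cv@right$ehh[j] + 1e-12, plain)
    }
  }
})

test_that("standardization uses 10 frequency bins and sample sd", {
  s <- data.frame(chrom = "2L", site = 1:6, pos = 1:6 * 100,
                  daf = c(0.05, 0.05, 0.05, 0.349, 0.62, 0.62),
                  ihs = c(-1, 0, 1, 5, 2, 4),
                  nsl = NA_real_, ihh12 = NA_real_,
                  ihs_reason = "ok", nsl_reason = "maf",
                  ihh12_reason = "maf")
  ss <- new("SelectionScores", scores = s, thresholds = data.frame())
  out <- scoreTable(normalizeScores(ss, nBins = 10))
  # frequency 0.349 falls in the fourth bin [0.3, 0.4)
  expect_equal(out$bin[4], 4L)
  # bin values {-1,0,1} standardize to themselves with sample sd
  expect_equal(out$std_ihs[1:3], c(-1, 0, 1))
  # singleton bin cannot be standardized
  expect_true(is.na(out$std_ihs[4]))
  # two-point bin: mean 3, sd sqrt(2)
  expect_equal(out$std_ihs[5:6], c(-1, 1) / sqrt(2))
})

test_that("neutral sites obey the small-intron offset rule", {
  # intron of 65 bp starting at 1001 on +: offsets 8-30 are 1008..1030
  introns <- GenomicRanges::GRanges(
    "2L", IRanges::IRanges(c(1001, 2001, 3001), width = c(65, 66, 60)),
    strand = c("+", "+", "-"))
  pos <- c(1008, 1030, 1031, 2010, 3031, 3053, 3054, 3060)
  hap <- matrix(rep(c(0L, 1L), each = length(pos)), nrow = 2,
                byrow = TRUE)
  panel <- HaplotypePanel(rbind(hap, 1 - hap), pos)
  got <- neutralSites(panel, introns)
  # 1008 and 1030 in (offset 8 and 30); 1031 out (offset 31);
  # 2010 out (intron 66 bp); minus-strand intron [3001,3060]:
  # offsets from the 3' coordinate end: positions 3031..3053 qualify
  expect_equal(got, c(1L, 2L, 5L, 6L))
})

test_that("significance thresholds are strict and percentile-based", {
  s <- data.frame(chrom = "2L", site = 1:102, pos = 1:102,
                  daf = 0.5, ihs = 0, nsl = 0, ihh12 = 0,
                  ihs_reason = "ok", nsl_reason = "ok",
                  ihh12_reason = "ok")
  s$std_ihs <- s$std_nsl <- s$std_ihh12 <- c(1:100, 95.05, 96)
  ss <- new("SelectionScores", scores = s, thresholds = data.frame())
  out <- callSignificantScores(ss, neutral = 1:100)
  thr <- scoreThresholds(out)
  # neutral values 1..100: linear-interpolation 95th percentile = 95.05
  expect_equal(thr$threshold[thr$statistic == "ihs"], 95.05)
  st <- scoreTable(out)
  # site exactly at the threshold is NOT flagged (strict >)
  expect_false(st$sig_ihs[101])
  expect_true(st$sig_ihs[102])
  # too few neutral sites is an error
  expect_error(callSignificantScores(ss, neutral = 1:5), "neutral")
})

test_that("scan skips low-frequency cores and flags truncation", {
  panel <- randomPanel(10, 25, seed = 7)
  ss <- scanPanel(panel, mafFloor = 0.2)
  st <- scoreTable(ss)
  low <- st$daf < 0.2 | st$daf > 0.8
  expect_true(all(is.na(st$ihs[low])))
  expect_true(all(st$ihs_reason[low] == "maf"))
  expect_s4_class(computeEHH(panel, 1, "derived"), "EHHCurve")
})
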