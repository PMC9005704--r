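#' Which core allele is swept at a significant site?
#'
#' For iHS and nSL the sign of the standardized score identifies the
#' allele with the long haplotypes (strongly negative = derived, positive
#' = ancestral). For iHH12, which is computed over pooled classes, the
#' allele whose carriers have the larger integrated EHH is taken.
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param site site index.
#' @param statistic "ihs", "nsl" or "ihh12".
#' @param z the standardized score at the site (sign used for iHS/nSL).
#' @param cutoff EHH cutoff for the iHH12 tie-break.
#' @return 0 or 1 (the swept core allele).
#' @export
sweptAllele <- function(panel, site, statistic, z, cutoff = 0.05) {
  if (statistic %in% c("ihs", "nsl"))
    return(if (z < 0) 1L else 0L)
  vals <- vapply(c("ancestral", "derived"), function(al) {
    cv <- tryCatch(computeEHH(panel, site, al, cutoff),
                   error = function(e) NULL)
    if (is.null(cv)) return(-Inf)
    integrateIHH(cv, cutoff, "physical")$value
  }, 0)
  if (vals["derived"] >= vals["ancestral"]) 1L else 0L
}

#' Simulate a cohort with a planted sweep linked to a TE insertion
#'
#' Builds the inputs of a full sweep screen: a haplotype panel (one
#' haplotype per strain) with a planted incomplete sweep, a linked TE
#' whose carrier strains are exactly the sweep carriers and whose
#' interval lies within the SNP pairing window of the core, a set of
#' unlinked common TEs with random carrier sets, neutral-intron
#' annotation, and a uniform positive recombination map.
#'
#' @param seed RNG seed (sub-seeds are derived from it).
#' @param nStrains strains (= haplotypes).
#' @param nSites SNP sites before the polymorphism filter.
#' @param regionLength region span in bp.
#' @param carrierFraction sweep carrier fraction.
#' @param decayScale sweep tract decay scale in bp.
#' @param nUnlinkedCommon number of unlinked common TEs planted.
#' @param nNeutral neutral-intron calibration sites.
#' @return list with \code{panel}, \code{coreSite}, \code{pm},
#'   \code{linkedGroup}, \code{unlinkedGroups}, \code{gm} (introns),
#'   \code{recombMap}, \code{carrierStrains}.
#' @export
simulateSweepCohort <- function(seed = 1L, nStrains = 40, nSites = 500,
                                regionLength = 1e6,
                                carrierFraction = 0.6,
                                decayScale = 5e4,
                                nUnlinkedCommon = 20, nNeutral = 80) {
  panel <- simulateHaplotypes(nHaplotypes = nStrains, nSites = nSites,
                              regionLength = regionLength, seed = seed)
  sw <- plantSweep(panel, sweepConfig(corePosition = regionLength / 2,
                                      carrierFraction = carrierFraction,
                                      decayScale = decayScale,
                                      seed = seed + 1000L))
  panel <- sw$panel
  strains <- unique(strainOf(panel))
  corePos <- positions(panel)[sw$coreSite]
  set.seed(seed + 2000L)
  # linked TE: a few hundred bp from the core, carriers = sweep carriers
  linkStart <- corePos + 200
  loci <- data.frame(group_id = paste0(panelChrom(panel), "_", linkStart,
                                       "_", linkStart + 30, "_pogo"),
                     chrom = panelChrom(panel), start = linkStart,
                     end = linkStart + 30, family = "pogo")
  pres <- matrix(FALSE, length(strains), 1,
                 dimnames = list(strains, loci$group_id))
  pres[sw$carrierStrains, 1] <- TRUE
  fams <- c("Doc", "roo", "jockey", "hobo", "297", "412")
  upos <- sort(sample(seq(2000, regionLength - 2000), nUnlinkedCommon))
  for (i in seq_len(nUnlinkedCommon)) {
    f <- runif(1, 0.15, 0.9)
    carriers <- sample(strains, max(2, round(f * length(strains))))
    fam <- sample(fams, 1)
    gid <- paste0(panelChrom(panel), "_", upos[i], "_", upos[i] + 30,
                  "_", fam)
    loci <- rbind(loci, data.frame(group_id = gid,
                                   chrom = panelChrom(panel),
                                   start = upos[i], end = upos[i] + 30,
                                   family = fam))
    col <- matrix(FALSE, length(strains), 1,
                  dimnames = list(strains, gid))
    col[carriers, 1] <- TRUE
    pres <- cbind(pres, col)
  }
  rownames(loci) <- loci$group_id
  pm <- PresenceMatrix(pres, lociInfo = loci)
  gm <- simulateNeutralIntrons(panel, nNeutral = nNeutral,
                               seed = seed + 3000L)
  recombMap <- data.frame(chrom = panelChrom(panel), start = 0,
                          end = regionLength + 1e4, rate = 2)
  list(panel = panel, coreSite = sw$coreSite, pm = pm,
       linkedGroup = loci$group_id[1L],
       unlinkedGroups = loci$group_id[-1L], gm = gm,
       recombMap = recombMap, carrierStrains = sw$carrierStrains)
}

#' Screen a cohort for TE insertions linked to selective sweeps
#'
#' The full selection arm of the pipeline: scan the panel (iHS, nSL,
#' iHH12), standardize in frequency bins, calibrate significance on
#' neutral-intron SNPs, filter the TE pool (frequency 10-95%,
#' recombination > 0, excluded families), pair significant SNPs with
#' pool TEs within the pairing window, and apply the carrier
#' co-occurrence rule to every pair. A TE is a candidate when at least
#' one of its pairs passes.
#'
#' @param panel a \linkS4class{HaplotypePanel} (haploid per strain by
#'   default: strain allele = haplotype allele).
#' @param pm a \linkS4class{PresenceMatrix} over the same strains.
#' @param gm a \linkS4class{GeneModels} supplying intron annotation.
#' @param recombMap recombination map data.frame.
#' @param params parameter list from \code{\link{teParams}}.
#' @return list with \code{candidates} (group ids), \code{pairs}
#'   (evaluated pairs with tallies and verdicts), \code{scores}
#'   (a \linkS4class{SelectionScores}), \code{pool} (candidate pool),
#'   \code{audit}.
#' @export
sweepCandidateScreen <- function(panel, pm, gm, recombMap,
                                 params = teParams()) {
  ss <- scanPanel(panel, cutoff = params$ehhCutoff,
                  mafFloor = params$mafFloor)
  ss <- normalizeScores(ss, nBins = params$nBins)
  neutral <- neutralSites(panel, intronsOf(gm),
                          intronMaxLen = params$intronMaxLen,
                          offsets = params$intronOffsets)
  ss <- callSignificantScores(ss, neutral,
                              percentile = params$neutralPercentile)
  s <- scoreTable(ss)
  sig <- list()
  for (st in c("ihs", "nsl", "ihh12")) {
    idx <- which(s[[paste0("sig_", st)]])
    if (length(idx))
      sig[[st]] <- data.frame(chrom = s$chrom[idx], pos = s$pos[idx],
                              site = s$site[idx], statistic = st,
                              z = s[[paste0("std_", st)]][idx])
  }
  cf <- candidateFilter(pm, recombMap, minFreq = params$rareBelow,
                        maxFreq = params$fixedAbove,
                        excludedFamilies = params$excludedFamilies)
  if (!length(sig) || !nrow(cf$pool))
    return(list(candidates = character(0),
                pairs = data.frame(), scores = ss, pool = cf$pool,
                audit = cf$audit))
  sigSnps <- do.call(rbind, sig)
  pairs <- pairTeSnp(cf$pool, sigSnps, window = params$pairWindow)
  if (!nrow(pairs))
    return(list(candidates = character(0), pairs = pairs, scores = ss,
                pool = cf$pool, audit = cf$audit))
  strains <- rownames(presence(pm))
  hapStrain <- strainOf(panel)
  hap <- haplotypes(panel)
  verdicts <- character(nrow(pairs))
  pass <- logical(nrow(pairs))
  tallies <- matrix(0L, nrow(pairs), 3,
                    dimnames = list(NULL, c("nTE", "nBoth",
                                            "nAbsentAlleleWithTE")))
  for (i in seq_len(nrow(pairs))) {
    site <- pairs$site[i]
    zi <- sigSnps$z[match(paste(pairs$site[i], pairs$statistic[i]),
                          paste(sigSnps$site, sigSnps$statistic))]
    al <- sweptAllele(panel, site, pairs$statistic[i], zi,
                      cutoff = params$ehhCutoff)
    carrier <- vapply(strains, function(s)
      any(hap[hapStrain == s, site] == al), TRUE)
    tl <- tallyCooccurrence(presence(pm)[, pairs$group_id[i]], carrier)
    tallies[i, ] <- c(tl$nTE, tl$nBoth, tl$nAbsentAlleleWithTE)
    v <- cooccurrenceTest(tl$nTE, tl$nBoth, tl$nAbsentAlleleWithTE)
    verdicts[i] <- v$reason
    pass[i] <- v$pass
  }
  pairs <- cbind(pairs, as.data.frame(tallies),
                 verdict = verdicts, pass = pass)
  list(candidates = unique(pairs$group_id[pairs$pass]),
       pairs = pairs, scores = ss, pool = cf$pool, audit = cf$audit)
}

#' Round-trip a synthetic cohort through the orthology module
#'
#' Transfers every strain annotation back onto the reference, clusters
#' the reliable transfers into ortholog groups and compares the result
#' to the cohort truth table: a planted locus counts as recovered when a
#' group of the same family lies within \code{positionTolerance} bp of
#' the planted insertion point and its presence vector equals the truth.
#' Loci planted in zero strains are unobservable and excluded from the
#' denominator.
#'
#' @param cohort output of \code{\link{simulateCohort}}.
#' @param flankBp flank length for the transfer.
#' @param positionTolerance clustering / matching tolerance (bp).
#' @return list with \code{og} (ortholog groups), \code{transferred},
#'   \code{nPlanted}, \code{nRecovered}, \code{recovery} (fraction).
#' @export
orthologyRoundTrip <- function(cohort, flankBp = 1000,
                               positionTolerance = 100) {
  tr <- transferCohort(cohort$annotations, cohort$genomes,
                       cohort$reference, flankBp = flankBp)
  og <- clusterOrthologs(tr, strains = rownames(cohort$truth$presence),
                         positionTolerance = positionTolerance,
                         strainInfo = cohort$truth$metadata)
  li <- lociInfo(og$pm)
  truthLoci <- cohort$truth$loci
  observable <- which(truthLoci$realized_freq > 0)
  recovered <- 0L
  for (j in observable) {
    cand <- which(li$chrom == truthLoci$chrom[j] &
                    li$family == truthLoci$family[j] &
                    abs((li$start + li$end) / 2 - truthLoci$pos[j]) <=
                      positionTolerance)
    if (!length(cand)) next
    truthVec <- cohort$truth$presence[, j]
    hit <- any(vapply(cand, function(ci)
      all(presence(og$pm)[, ci] == truthVec), TRUE))
    if (hit) recovered <- recovered + 1L
  }
  list(og = og, transferred = tr, nPlanted = length(observable),
       nRecovered = recovered,
       recovery = recovered / max(1L, length(observable)))
}
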