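#' Configuration for a synthetic TE insertion cohort
#'
#' The generator emulates a cohort of inbred-strain genome assemblies that
#' all derive from one reference by planting TE insertions at target
#' population frequencies spanning the rare, common and fixed classes.
#' Defaults follow the study design the package targets: a 47-genome
#' cohort with a rare-variant-heavy insertion frequency spectrum, scaled
#' to a short chromosome so that complete cohorts can be simulated in
#' seconds.
#'
#' @param nStrains number of strain genomes (>= 5).
#' @param nChromosomes number of chromosomes in the reference.
#' @param chromLength chromosome length in bp; must be at least 10x the
#'   longest family consensus.
#' @param nTeLoci number of planted insertion loci.
#' @param frequencyMixture list of \code{c(frequency, weight)} pairs; each
#'   locus draws its target frequency from this mixture (weights sum
#'   to 1).
#' @param teFamilies named numeric vector: family name -> consensus length
#'   in bp.
#' @param flankUniqueness when TRUE (default) the reference is i.i.d.
#'   random sequence, so kb-scale flanks are unique with overwhelming
#'   probability; FALSE plants a duplicated segment to exercise
#'   multiple-mapping code paths.
#' @param flankBp flank length the downstream transfer will use; planted
#'   loci keep at least \code{2 * flankBp} apart.
#' @param lociPositions optional numeric vector (or list per chromosome)
#'   of fixed 0-based insertion points; spacing is validated.
#' @param seed RNG seed.
#' @return A list of class \code{cohortConfig}.
#' @export
cohortConfig <- function(nStrains = 47,
                         nChromosomes = 1,
                         chromLength = 3e5,
                         nTeLoci = 40,
                         frequencyMixture = list(c(0.04, 0.45),
                                                 c(0.20, 0.20),
                                                 c(0.50, 0.20),
                                                 c(0.80, 0.05),
                                                 c(0.98, 0.10)),
                         teFamilies = c(pogo = 2100, Doc = 4700,
                                        accord = 7400, `P-element` = 2900,
                                        roo = 9100),
                         flankUniqueness = TRUE,
                         flankBp = 1000,
                         lociPositions = NULL,
                         seed = 1L) {
  stopifnot(nStrains >= 5, nChromosomes >= 1, nTeLoci >= 1)
  w <- vapply(frequencyMixture, `[`, 0, 2L)
  f <- vapply(frequencyMixture, `[`, 0, 1L)
  if (abs(sum(w) - 1) > 1e-8) stop("mixture weights must sum to 1")
  if (any(f < 0 | f > 1)) stop("mixture frequencies must be in [0,1]")
  if (chromLength < 10 * max(teFamilies))
    stop("chromLength must be >= 10x the longest consensus")
  structure(list(nStrains = nStrains, nChromosomes = nChromosomes,
                 chromLength = chromLength, nTeLoci = nTeLoci,
                 frequencyMixture = frequencyMixture,
                 teFamilies = teFamilies,
                 flankUniqueness = flankUniqueness,
                 flankBp = flankBp, lociPositions = lociPositions,
                 seed = seed),
            class = "cohortConfig")
}

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a cohort of strain genomes with planted TE insertions
#'
#' Each strain genome equals the reference with family-consensus sequences
#' inserted at the loci planted in that strain; annotation intervals (in
#' strain coordinates) exactly cover the inserted sequences. The returned
#' truth table records, per locus, the reference insertion point, family,
#' planted presence vector and realized frequency. Byte-identical output
#' is guaranteed for a fixed config (including seed).
#'
#' Strain metadata assigns strains round-robin to two synthetic continents
#' ("Europe", "NorthAmerica") so that geographic set logic can be
#' exercised.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @return list with elements \code{reference} (DNAStringSet),
#'   \code{genomes} (named list of DNAStringSet), \code{annotations}
#'   (data.frame of per-strain TE records in strain coordinates),
#'   \code{consensus} (DNAStringSet of family consensi), \code{truth}
#'   (list: \code{loci} data.frame, \code{presence} logical matrix,
#'   \code{metadata} strain data.frame).
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "cohortConfig"))
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$nChromosomes))
  ref <- Biostrings::DNAStringSet(
    vapply(chroms, function(ch) randomDna(config$chromLength), ""))
  names(ref) <- chroms
  if (!config$flankUniqueness) {
    # duplicate a 3 kb block to create repeated flanks on chromosome 1
    s <- as.character(ref[[1]])
    block <- substr(s, 10001, 13000)
    substr(s, config$chromLength - 12999, config$chromLength - 10000) <-
      block
    ref[[1]] <- Biostrings::DNAString(s)
  }
  fams <- config$teFamilies
  consensus <- Biostrings::DNAStringSet(
    vapply(fams, function(len) randomDna(len), ""))
  names(consensus) <- names(fams)

  minGap <- 2 * config$flankBp
  lociPerChrom <- diff(floor(seq(0, config$nTeLoci,
                                 length.out = config$nChromosomes + 1)))
  loci <- list()
  k <- 0
  for (ci in seq_along(chroms)) {
    nl <- lociPerChrom[ci]
    if (nl == 0) next
    if (!is.null(config$lociPositions)) {
      pos <- if (is.list(config$lociPositions))
        config$lociPositions[[ci]] else config$lociPositions
      pos <- sort(pos)
      if (length(pos) > 1 && any(diff(pos) < minGap))
        stop("planted loci closer than 2x flank length (",
             minGap, " bp) on ", chroms[ci])
    } else {
      # jittered grid: slot width minGap + flankBp, jitter < flankBp,
      # so adjacent picks stay at least minGap apart
      lo <- config$flankBp
      hi <- config$chromLength - config$flankBp
      slotW <- minGap + config$flankBp
      slots <- floor((hi - lo) / slotW)
      if (slots < nl)
        stop("chromosome too short for ", nl, " loci at spacing ", minGap)
      pick <- sort(sample(slots, nl))
      pos <- lo + (pick - 1) * slotW + floor(runif(nl, 0, config$flankBp))
      pos <- pmin(pos, hi)
    }
    for (p in pos) {
      k <- k + 1
      loci[[k]] <- list(chrom = chroms[ci], pos = p)
    }
  }
  nl <- length(loci)
  mixF <- vapply(config$frequencyMixture, `[`, 0, 1L)
  mixW <- vapply(config$frequencyMixture, `[`, 0, 2L)
  target <- mixF[sample(length(mixF), nl, replace = TRUE, prob = mixW)]
  family <- names(fams)[sample(length(fams), nl, replace = TRUE)]
  strains <- sprintf("S%02d", seq_len(config$nStrains))
  pres <- matrix(FALSE, config$nStrains, nl,
                 dimnames = list(strains, NULL))
  for (j in seq_len(nl))
    pres[, j] <- runif(config$nStrains) < target[j]
  lociDf <- data.frame(
    locus_id = vapply(seq_len(nl), function(j)
      paste(loci[[j]]$chrom, loci[[j]]$pos, loci[[j]]$pos, family[j],
            sep = "_"), ""),
    chrom = vapply(loci, `[[`, "", "chrom"),
    pos = vapply(loci, `[[`, 0, "pos"),
    family = family,
    target_freq = target,
    realized_freq = colMeans(pres))
  colnames(pres) <- lociDf$locus_id

  genomes <- list()
  annot <- list()
  for (si in seq_along(strains)) {
    gseqs <- character(length(chroms))
    names(gseqs) <- chroms
    rows <- list()
    for (ci in seq_along(chroms)) {
      idx <- which(lociDf$chrom == chroms[ci] & pres[si, ])
      idx <- idx[order(lociDf$pos[idx])]
      s <- as.character(ref[[ci]])
      if (length(idx)) {
        pieces <- character(0)
        prev <- 0
        offset <- 0
        for (j in idx) {
          p <- lociDf$pos[j]
          pieces <- c(pieces, substr(s, prev + 1, p))
          ins <- as.character(consensus[[lociDf$family[j]]])
          start_strain <- p + offset
          offset <- offset + nchar(ins)
          pieces <- c(pieces, ins)
          prev <- p
          rows[[length(rows) + 1]] <- data.frame(
            strain = strains[si], chrom = chroms[ci],
            start = start_strain, end = start_strain + nchar(ins),
            family = lociDf$family[j], identity = 100, strand = "+",
            length = nchar(ins), locus_id = lociDf$locus_id[j])
        }
        pieces <- c(pieces, substr(s, prev + 1, nchar(s)))
        gseqs[ci] <- paste(pieces, collapse = "")
      } else {
        gseqs[ci] <- s
      }
    }
    genomes[[strains[si]]] <- Biostrings::DNAStringSet(gseqs)
    annot[[si]] <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  annotations <- do.call(rbind, annot[!vapply(annot, is.null, TRUE)])
  rownames(annotations) <- NULL
  metadata <- data.frame(
    strain = strains,
    population = rep(c("EU-pop", "NA-pop"), length.out = length(strains)),
    continent = rep(c("Europe", "NorthAmerica"),
                    length.out = length(strains)),
    climate = rep(c("temperate", "cold", "arid"),
                  length.out = length(strains)),
    row.names = strains)
  list(reference = ref, genomes = genomes, annotations = annotations,
       consensus = consensus,
       truth = list(loci = lociDf, presence = pres, metadata = metadata))
}

#' Simulate a phased haplotype panel with background LD
#'
#' A lightweight founder-mosaic model: founder haplotypes carry derived
#' alleles at frequencies drawn from a 1/k spectrum; each sampled
#' haplotype is a mosaic of founders with geometric (per-bp) breakpoints;
#' private mutations are then sprinkled on top. The result has LD that
#' decays with physical distance, which is the property extended-haplotype
#' statistics rely on; it makes no attempt at a calibrated coalescent.
#' Monomorphic sites are dropped after sampling.
#'
#' @param nHaplotypes haplotypes to sample (one per strain by default
#'   downstream).
#' @param nSites candidate SNP sites before the polymorphism filter.
#' @param regionLength region span in bp.
#' @param mutationDensity expected private mutations per bp per haplotype.
#' @param nFounders founder haplotypes (<= nHaplotypes).
#' @param recombRate per-bp probability scale of switching founders
#'   between adjacent sites (breakpoint density).
#' @param chrom chromosome name for the panel.
#' @param seed RNG seed.
#' @return A \linkS4class{HaplotypePanel}.
#' @export
simulateHaplotypes <- function(nHaplotypes = 46, nSites = 500,
                               regionLength = 1e6,
                               mutationDensity = 2e-5,
                               nFounders = 8, recombRate = 2e-5,
                               chrom = "2L", seed = 1L) {
  stopifnot(nFounders <= nHaplotypes, nSites >= 2)
  set.seed(seed)
  pos <- sort(sample(seq_len(regionLength - 1), nSites))
  # founder alleles: derived carried by k founders, P(k) ~ 1/k
  founders <- matrix(0L, nFounders, nSites)
  if (nFounders > 1) {
    kprob <- 1 / seq_len(nFounders - 1)
    ks <- sample(nFounders - 1, nSites, replace = TRUE,
                 prob = kprob / sum(kprob))
    for (j in seq_len(nSites))
      founders[sample(nFounders, ks[j]), j] <- 1L
  }
  switchP <- 1 - exp(-recombRate * diff(pos))
  hap <- matrix(0L, nHaplotypes, nSites)
  for (i in seq_len(nHaplotypes)) {
    cur <- sample(nFounders, 1L)
    path <- integer(nSites)
    path[1L] <- cur
    sw <- runif(nSites - 1L) < switchP
    if (any(sw)) {
      bp <- which(sw)
      seg_start <- c(1L, bp + 1L)
      seg_founder <- c(cur, sample(nFounders, length(bp), replace = TRUE))
      seg_end <- c(bp, nSites)
      for (s in seq_along(seg_start))
        path[seg_start[s]:seg_end[s]] <- seg_founder[s]
    } else {
      path[] <- cur
    }
    hap[i, ] <- founders[cbind(path, seq_len(nSites))]
  }
  pMut <- min(1, mutationDensity * regionLength / nSites)
  if (pMut > 0) {
    flips <- matrix(runif(nHaplotypes * nSites) < pMut,
                    nHaplotypes, nSites)
    hap[flips] <- 1L - hap[flips]
  }
  cnt <- colSums(hap)
  poly <- cnt > 0 & cnt < nHaplotypes
  if (sum(poly) < 2)
    stop("fewer than 2 polymorphic sites survived; increase diversity")
  HaplotypePanel(hap[, poly, drop = FALSE], pos[poly], chrom = chrom)
}

#' Sweep configuration
#'
#' @param corePosition physical position (bp) of the sweep core.
#' @param carrierFraction fraction of haplotypes carrying the swept
#'   haplotype, in (0, 1); defaults to 0.6, an incomplete sweep.
#' @param linkedTeLocus optional locus id of a TE whose carriers must
#'   match the sweep carriers (recorded in the truth table).
#' @param decayScale expected per-side identity-tract length (bp) of the
#'   swept haplotype; \code{Inf} copies the donor across the whole region.
#' @param seed RNG seed.
#' @return list of class \code{sweepConfig}.
#' @export
sweepConfig <- function(corePosition, carrierFraction = 0.6,
                        linkedTeLocus = NA_character_,
                        decayScale = 5e4, seed = 1L) {
  stopifnot(carrierFraction > 0, carrierFraction < 1)
  structure(list(corePosition = corePosition,
                 carrierFraction = carrierFraction,
                 linkedTeLocus = linkedTeLocus,
                 decayScale = decayScale, seed = seed),
            class = "sweepConfig")
}

#' Plant an incomplete selective sweep into a haplotype panel
#'
#' A donor haplotype is copied onto the chosen carriers over a tract
#' around the core site; each carrier's per-side tract length is geometric
#' with mean \code{decayScale} bp, producing the long shared haplotypes
#' that EHH statistics detect. The core site's derived allele is carried
#' by exactly the carrier set; non-carriers are untouched.
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param sweep a \code{\link{sweepConfig}}; \code{corePosition} must lie
#'   within the panel span and the carrier count must be at least 2.
#' @return list with \code{panel} (modified), \code{coreSite} (column
#'   index of the core), \code{carriers} (haplotype row indices),
#'   \code{carrierStrains} (strain ids of the carriers).
#' @export
plantSweep <- function(panel, sweep) {
  stopifnot(inherits(sweep, "sweepConfig"))
  pos <- positions(panel)
  if (sweep$corePosition < min(pos) || sweep$corePosition > max(pos))
    stop("core position outside panel span")
  set.seed(sweep$seed)
  n <- nHaplotypes(panel)
  nCar <- round(sweep$carrierFraction * n)
  if (nCar < 2) stop("sweep needs at least 2 carriers (EHH undefined)")
  carriers <- sort(sample(n, nCar))
  core <- which.min(abs(pos - sweep$corePosition))
  hap <- haplotypes(panel)
  donor <- hap[carriers[1L], ]
  for (i in carriers) {
    if (is.finite(sweep$decayScale)) {
      p <- 1 / sweep$decayScale
      left <- rgeom(1L, p)
      right <- rgeom(1L, p)
    } else {
      left <- right <- Inf
    }
    tract <- pos >= pos[core] - left & pos <= pos[core] + right
    hap[i, tract] <- donor[tract]
  }
  hap[, core] <- 0L
  hap[carriers, core] <- 1L
  out <- HaplotypePanel(hap, pos, chrom = panelChrom(panel),
                        geneticPositions = geneticPositions(panel),
                        strains = strainOf(panel))
  list(panel = out, coreSite = core, carriers = carriers,
       carrierStrains = unique(strainOf(panel)[carriers]))
}

#' Simulate normalized expression with additive TE effects
#'
#' expression(gene, strain) = baseline(gene) + effect x presence(locus,
#' strain) + Gaussian noise, on the normalized (rlog-like) scale.
#'
#' @param pm a \linkS4class{PresenceMatrix}.
#' @param geneEffects data.frame with columns \code{gene_id},
#'   \code{locus} (an id among \code{colnames(presence(pm))}, or NA for a
#'   null gene) and \code{effect} (expression units).
#' @param noiseSd Gaussian noise standard deviation.
#' @param baselineMean optional numeric vector of per-gene baselines;
#'   drawn from N(8, 2) when omitted.
#' @param seed RNG seed.
#' @return numeric matrix genes x strains.
#' @export
simulateExpression <- function(pm, geneEffects, noiseSd = 1,
                               baselineMean = NULL, seed = 1L) {
  set.seed(seed)
  p <- presence(pm)
  ng <- nrow(geneEffects)
  known <- geneEffects$locus[!is.na(geneEffects$locus)]
  if (!all(known %in% colnames(p)))
    stop("geneEffects refers to loci absent from the presence matrix")
  if (is.null(baselineMean))
    baselineMean <- rnorm(ng, 8, 2)
  expr <- matrix(rnorm(ng * nrow(p), 0, noiseSd), ng, nrow(p),
                 dimnames = list(geneEffects$gene_id, rownames(p)))
  expr <- expr + baselineMean
  for (g in seq_len(ng)) {
    loc <- geneEffects$locus[g]
    if (!is.na(loc))
      expr[g, ] <- expr[g, ] + geneEffects$effect[g] * as.numeric(p[, loc])
  }
  expr
}

#' Place small introns so that chosen SNPs become neutral calibration
#' sites
#'
#' Emulates the annotation input a selection scan needs: introns of at
#' most 65 bp whose first 8-30 bp contain SNPs of the panel. A random
#' subset of panel sites is chosen and a plus-strand intron is placed
#' around each so that the SNP falls at a valid offset.
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param nNeutral number of sites to wrap in qualifying introns.
#' @param intronLength intron length in bp (<= 65).
#' @param seed RNG seed.
#' @return A \linkS4class{GeneModels} object whose features are the
#'   introns (one synthetic gene per intron).
#' @export
simulateNeutralIntrons <- function(panel, nNeutral = 60,
                                   intronLength = 60, seed = 1L) {
  stopifnot(intronLength <= 65)
  set.seed(seed)
  pos <- positions(panel)
  nNeutral <- min(nNeutral, length(pos))
  sites <- sort(sample(length(pos), nNeutral))
  offs <- sample(8:min(30, intronLength), nNeutral, replace = TRUE)
  istart <- pmax(1, pos[sites] - offs + 1)
  iend <- istart + intronLength - 1
  ch <- panelChrom(panel)
  introns <- GenomicRanges::GRanges(
    ch, IRanges::IRanges(istart, iend), strand = "+",
    gene_id = sprintf("ngene%03d", seq_len(nNeutral)), type = "intron")
  genes <- GenomicRanges::GRanges(
    ch, IRanges::IRanges(pmax(1, istart - 100), iend + 100), strand = "+",
    gene_id = sprintf("ngene%03d", seq_len(nNeutral)),
    tss = pmax(1, istart - 100))
  new("GeneModels", genes = genes, features = introns)
}

#' Write a synthetic cohort to disk
#'
#' Reference and per-strain genomes as FASTA, TE annotations as BED6 per
#' strain, the truth table and strain metadata as TSV, plus a manifest.
#'
#' @param cohort output of \code{\link{simulateCohort}}.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(reference = file.path(dir, "reference.fa"))
  Biostrings::writeXStringSet(cohort$reference, paths["reference"])
  for (s in names(cohort$genomes)) {
    fp <- file.path(dir, paste0(s, ".fa"))
    Biostrings::writeXStringSet(cohort$genomes[[s]], fp)
    paths[paste0("genome_", s)] <- fp
    bp <- file.path(dir, paste0(s, ".te.bed"))
    writeTeBed(cohort$annotations[cohort$annotations$strain == s, ], bp)
    paths[paste0("te_bed_", s)] <- bp
  }
  tp <- file.path(dir, "truth_loci.tsv")
  write.table(cohort$truth$loci, tp, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths["truth_loci"] <- tp
  pp <- file.path(dir, "truth_presence.tsv")
  write.table(data.frame(strain = rownames(cohort$truth$presence),
                         cohort$truth$presence * 1L, check.names = FALSE),
              pp, sep = "\t", quote = FALSE, row.names = FALSE)
  paths["truth_presence"] <- pp
  mp <- file.path(dir, "metadata.tsv")
  write.table(cohort$truth$metadata, mp, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths["metadata"] <- mp
  man <- file.path(dir, "MANIFEST.tsv")
  write.table(data.frame(key = names(paths), path = unname(paths)),
              man, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(man)
}
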