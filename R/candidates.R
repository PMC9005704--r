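#' Pair significant sweep SNPs with nearby TE insertions
#'
#' Every significant SNP is paired with each TE whose interval lies
#' strictly within \code{window} bp (minimum gap between the SNP position
#' and the TE interval; 0 when the SNP falls inside the TE).
#'
#' @param loci data.frame of TE loci (\code{group_id}, \code{chrom},
#'   \code{start}, \code{end}, 0-based half-open), e.g.
#'   \code{lociInfo(pm)}.
#' @param snps data.frame of significant SNPs with columns \code{chrom},
#'   \code{pos} (1-based bp) and optionally \code{statistic} and
#'   \code{site}.
#' @param window pairing window in bp; pairs at exactly \code{window} are
#'   rejected (strictly less than).
#' @return data.frame of pairs: group_id, chrom, snp_pos, site,
#'   statistic, distance.
#' @export
pairTeSnp <- function(loci, snps, window = 1000) {
  out <- list()
  for (i in seq_len(nrow(snps))) {
    p0 <- snps$pos[i] - 1  # 0-based point
    sameChrom <- loci$chrom == snps$chrom[i]
    d <- ifelse(p0 < loci$start, loci$start - p0,
                ifelse(p0 >= loci$end, p0 - (loci$end - 1), 0))
    hit <- which(sameChrom & d < window)
    if (length(hit))
      out[[length(out) + 1]] <- data.frame(
        group_id = loci$group_id[hit], chrom = snps$chrom[i],
        snp_pos = snps$pos[i],
        site = if ("site" %in% names(snps)) snps$site[i] else NA,
        statistic = if ("statistic" %in% names(snps))
          snps$statistic[i] else NA,
        distance = d[hit])
  }
  if (!length(out))
    return(data.frame(group_id = character(0), chrom = character(0),
                      snp_pos = numeric(0), site = numeric(0),
                      statistic = character(0), distance = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Tally strain co-occurrence of a TE and a swept allele
#'
#' A strain "contains the swept allele" when any of its haplotypes
#' carries it; the TE and the allele "co-occur" in a strain when the
#' strain has both. For haploid-per-strain panels the linked tally is
#' simply TE AND allele.
#'
#' @param tePresent logical per strain.
#' @param alleleCarrier logical per strain (any haplotype carries the
#'   swept allele).
#' @return list of tallies \code{nTE}, \code{nBoth},
#'   \code{nAbsentAlleleWithTE} (strains lacking the allele entirely but
#'   carrying the TE).
#' @export
tallyCooccurrence <- function(tePresent, alleleCarrier) {
  stopifnot(length(tePresent) == length(alleleCarrier))
  list(nTE = sum(tePresent),
       nBoth = sum(tePresent & alleleCarrier),
       nAbsentAlleleWithTE = sum(tePresent & !alleleCarrier))
}

#' Carrier co-occurrence rule for a TE-SNP pair
#'
#' Pass requires: for TEs present in 5-6 strains, at least 4 strains
#' carrying both the swept allele and the TE; for TEs in 7 or more
#' strains, a strict majority carrying both; in all cases the TE must be
#' absent from 100% of the strains that lack the swept allele. TEs in
#' fewer than 5 strains are below the rule's domain and fail.
#'
#' @param nTE strains carrying the TE.
#' @param nBoth strains carrying both TE and swept allele.
#' @param nAbsentAlleleWithTE strains lacking the swept allele but
#'   carrying the TE (must be 0).
#' @return list with \code{pass} and \code{reason}.
#' @export
cooccurrenceTest <- function(nTE, nBoth, nAbsentAlleleWithTE = 0) {
  if (nBoth > nTE || nTE < 0 || nBoth < 0 || nAbsentAlleleWithTE < 0 ||
      nAbsentAlleleWithTE > nTE)
    stop("inconsistent tallies: nBoth and nAbsentAlleleWithTE must not ",
         "exceed nTE")
  if (nTE < 5)
    return(list(pass = FALSE, reason = "fewer-than-5-carriers"))
  countOk <- if (nTE <= 6) nBoth >= 4 else nBoth > nTE / 2
  if (!countOk)
    return(list(pass = FALSE, reason = "co-carrier-count"))
  if (nAbsentAlleleWithTE > 0)
    return(list(pass = FALSE, reason = "te-in-allele-non-carrier"))
  list(pass = TRUE, reason = "ok")
}

#' Filter ortholog groups into the candidate-adaptive pool
#'
#' Keeps groups at population frequency between 10% and 95% (inclusive,
#' exact count comparisons), located where the recombination rate is
#' strictly positive, and not in the excluded (anciently abundant)
#' families. Each group is attributed to the first filter that removes
#' it, in the order frequency, recombination, family, so the audit
#' counts sum to the input count.
#'
#' @param pm a \linkS4class{PresenceMatrix}.
#' @param recombMap recombination map data.frame
#'   (\code{chrom,start,end,rate}).
#' @param minFreq,maxFreq inclusive frequency bounds.
#' @param excludedFamilies families removed from the pool.
#' @param verbose log audit counts.
#' @return list with \code{pool} (kept lociInfo rows + frequency),
#'   \code{audit} (named removal counts).
#' @export
candidateFilter <- function(pm, recombMap, minFreq = 0.10,
                            maxFreq = 0.95,
                            excludedFamilies = c("INE-1", "LARD"),
                            verbose = FALSE) {
  li <- lociInfo(pm)
  k <- colSums(presence(pm))
  n <- nrow(presence(pm))
  li$frequency <- k / n
  freqOk <- k * 100 >= minFreq * 100 * n & k * 100 <= maxFreq * 100 * n
  mid <- (li$start + li$end) / 2
  rate <- vapply(seq_len(nrow(li)), function(i)
    recombRateAt(recombMap, li$chrom[i], mid[i]), 0)
  li$recomb_rate <- rate
  recOk <- !is.na(rate) & rate > 0
  famOk <- !(li$family %in% excludedFamilies)
  removedFreq <- !freqOk
  removedRec <- freqOk & !recOk
  removedFam <- freqOk & recOk & !famOk
  keep <- freqOk & recOk & famOk
  audit <- c(input = nrow(li), removed_frequency = sum(removedFreq),
             removed_recombination = sum(removedRec),
             removed_family = sum(removedFam), retained = sum(keep))
  if (verbose)
    message("candidate filter: ", paste(names(audit), audit,
                                        sep = "=", collapse = ", "))
  list(pool = li[keep, , drop = FALSE], audit = audit)
}

#' Gene-body context of a TE insertion
#'
#' Resolves the insertion's position relative to the longest transcript
#' of the closest gene(s): 3UTR / 5UTR / CDS / INTRON when overlapping a
#' feature, PROMOTER when within 1 kb upstream of the TSS, and Intergenic
#' when no gene lies within \code{window} bp. All genes at distance 0 are
#' reported, as are equidistant nearest genes; when a TE overlaps several
#' feature types of one gene the label with the largest overlap wins.
#'
#' @param te one TE interval (list/row with \code{chrom}, \code{start},
#'   \code{end}, 0-based half-open).
#' @param gm a \linkS4class{GeneModels}.
#' @param window nearest-gene search window in bp (strictly less than).
#' @return data.frame with one row per reported gene: \code{gene_id},
#'   \code{distance}, \code{location}; a single Intergenic row when no
#'   gene qualifies.
#' @export
assignGeneContext <- function(te, gm, window = 1000) {
  g <- genes(gm)
  teGr <- GenomicRanges::GRanges(te$chrom,
                                 IRanges::IRanges(te$start + 1, te$end))
  d <- rep(NA_real_, length(g))
  same <- as.character(GenomicRanges::seqnames(g)) == te$chrom
  if (any(same)) {
    dd <- GenomicRanges::distance(teGr, g[same], ignore.strand = TRUE)
    d[same] <- dd
  }
  inWin <- which(!is.na(d) & d < window)
  if (!length(inWin))
    return(data.frame(gene_id = NA_character_, distance = NA_real_,
                      location = "Intergenic"))
  dmin <- min(d[inWin])
  nearest <- inWin[d[inWin] == dmin]
  out <- lapply(nearest, function(i) {
    gid <- g$gene_id[i]
    if (d[i] > 0) {
      # non-overlapping: promoter when within 1 kb upstream of the TSS
      st <- as.character(GenomicRanges::strand(g[i]))
      tss <- g$tss[i]
      upstream <- if (st == "+")
        te$end <= tss - 1 && tss - te$end <= 1000
      else te$start >= tss && te$start - tss < 1000
      loc <- if (upstream) "PROMOTER" else "Intergenic"
      return(data.frame(gene_id = gid, distance = d[i], location = loc))
    }
    f <- geneFeatures(gm)
    f <- f[f$gene_id == gid]
    loc <- "INTRON"
    if (length(f)) {
      ov <- GenomicRanges::findOverlaps(teGr, f, ignore.strand = TRUE)
      if (length(ov)) {
        w <- GenomicRanges::width(GenomicRanges::pintersect(
          teGr[S4Vectors::queryHits(ov)],
          f[S4Vectors::subjectHits(ov)]))
        types <- as.character(f$type[S4Vectors::subjectHits(ov)])
        best <- tapply(w, types, sum)
        loc <- switch(names(best)[which.max(best)],
                      five_prime_UTR = "5UTR",
                      three_prime_UTR = "3UTR",
                      CDS = "CDS", intron = "INTRON", "INTRON")
      }
    }
    data.frame(gene_id = gid, distance = 0, location = loc)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Family (or superfamily) enrichment of a focal TE set
#'
#' Per group, a 2x2 chi-square test of focal-set membership against the
#' background composition, switching to Fisher's exact test when an
#' expected cell drops below 1; p-values are Benjamini-Hochberg adjusted
#' across groups.
#'
#' @param focal character vector of family (or superfamily) labels of the
#'   focal TEs.
#' @param background labels of the background TEs. Set
#'   \code{backgroundIncludesFocal = TRUE} (default) when the background
#'   is a superset of the focal set; FALSE when disjoint.
#' @param backgroundIncludesFocal see above.
#' @param correct apply continuity correction in the chi-square test.
#' @return data.frame per group: counts, statistic, test used, p,
#'   FDR-adjusted p.
#' @export
enrichmentTest <- function(focal, background,
                           backgroundIncludesFocal = TRUE,
                           correct = FALSE) {
  if (backgroundIncludesFocal) {
    rest <- background
    # remove one instance per focal element so the two rows are disjoint
    for (x in focal) {
      i <- match(x, rest)
      if (!is.na(i)) rest <- rest[-i]
    }
  } else rest <- background
  fams <- sort(unique(c(focal, rest)))
  out <- lapply(fams, function(fm) {
    a <- sum(focal == fm); b <- length(focal) - a
    c_ <- sum(rest == fm); d <- length(rest) - c_
    tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
    expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expd < 1)) {
      ft <- stats::fisher.test(tab)
      data.frame(group = fm, n_focal = a, n_background = c_,
                 statistic = NA_real_, test = "fisher",
                 p = ft$p.value)
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
      data.frame(group = fm, n_focal = a, n_background = c_,
                 statistic = unname(ct$statistic), test = "chisq",
                 p = ct$p.value)
    }
  })
  res <- do.call(rbind, out)
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  rownames(res) <- NULL
  res
}
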