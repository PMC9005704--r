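#' Extract the flanking sequences of a TE insertion
#'
#' Returns the left and right flanks of the insertion in strain
#' coordinates (0-based half-open), truncated at chromosome ends and
#' flagged when truncated; a zero-length flank at a contig edge leaves
#' placement to proceed one-sided.
#'
#' @param te one annotation record (list or single-row data.frame with
#'   \code{chrom}, \code{start}, \code{end}).
#' @param genome DNAStringSet of the strain genome.
#' @param flankBp flank length in bp.
#' @return list with \code{left}, \code{right}, each holding \code{seq}
#'   (character), \code{start}, \code{end}, \code{truncated}; plus
#'   \code{chrom}.
#' @export
extractFlanks <- function(te, genome, flankBp = 1000) {
  ch <- as.character(te$chrom)
  if (!ch %in% names(genome)) stop("chromosome ", ch, " not in genome")
  L <- length(genome[[ch]])
  ls <- max(0, te$start - flankBp)
  le <- te$start
  rs <- te$end
  re <- min(L, te$end + flankBp)
  s <- as.character(genome[[ch]])
  list(chrom = ch,
       left = list(seq = if (le > ls) substr(s, ls + 1, le) else "",
                   start = ls, end = le, truncated = ls == 0 &&
                     te$start < flankBp),
       right = list(seq = if (re > rs) substr(s, rs + 1, re) else "",
                    start = rs, end = re,
                    truncated = re == L && te$end + flankBp > L))
}

matchOneStrand <- function(pattern, subject, maxMismatch) {
  if (nchar(pattern) == 0) return(NULL)
  m <- Biostrings::matchPattern(Biostrings::DNAString(pattern), subject,
                                max.mismatch = maxMismatch)
  if (!length(m)) return(NULL)
  data.frame(start = Biostrings::start(m) - 1L,
             end = Biostrings::end(m))
}

placeOneFlank <- function(seqchar, reference, minIdentity, minCov,
                          proximalSide) {
  len <- nchar(seqchar)
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      coverage = numeric(0))
  if (len == 0)
    return(list(placements = empty, class = "unmapped"))
  maxMM <- floor(len * (1 - minIdentity / 100))
  hits <- list()
  tryMatch <- function(p, coverage) {
    for (ch in names(reference)) {
      fwd <- matchOneStrand(p, reference[[ch]], maxMM)
      if (!is.null(fwd))
        hits[[length(hits) + 1]] <<- cbind(chrom = ch, fwd,
                                           strand = "+",
                                           coverage = coverage)
      rev <- matchOneStrand(
        as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(p))), reference[[ch]], maxMM)
      if (!is.null(rev))
        hits[[length(hits) + 1]] <<- cbind(chrom = ch, rev,
                                           strand = "-",
                                           coverage = coverage)
    }
  }
  tryMatch(seqchar, 1)
  cls <- NULL
  if (!length(hits)) {
    # fall back to the TE-proximal half: a hit here is a partial mapping
    half <- floor(len / 2)
    frag <- if (proximalSide == "right")
      substr(seqchar, len - half + 1, len) else substr(seqchar, 1, half)
    maxMM <- floor(nchar(frag) * (1 - minIdentity / 100))
    tryMatch(frag, half / len)
    if (length(hits)) cls <- "partial"
  }
  if (!length(hits)) return(list(placements = empty, class = "unmapped"))
  placements <- do.call(rbind, hits)
  if (is.null(cls))
    cls <- if (nrow(placements) == 1L) "unequivocal" else "multiple"
  if (cls == "partial" && nrow(placements) > 1L) cls <- "multiple"
  list(placements = placements, class = cls)
}

#' Place the two flanks of an insertion on the reference
#'
#' Internal placement mode: exact (or near-exact, via a mismatch
#' allowance derived from \code{minIdentity}) full-length matching of
#' each flank against both strands of the reference, falling back to the
#' TE-proximal half of the flank, whose hits are classified partial
#' (aligned fraction below \code{minCov}). Each flank is classified
#' unequivocal / multiple / partial / unmapped; if the two flanks map
#' unequivocally with contradictory orientations both are demoted to
#' multiple. Alternatively, precomputed PAF alignments of the flanks may
#' be supplied.
#'
#' @param flanks output of \code{\link{extractFlanks}}.
#' @param reference DNAStringSet of the reference genome.
#' @param minIdentity minimum percent identity of a placement (default
#'   100: exact matching, appropriate for assemblies derived from the
#'   same reference; lower it for diverged genomes).
#' @param minCov minimum aligned fraction for a non-partial placement.
#' @param paf optional data.frame from \code{\link{readPaf}} with query
#'   names "left" and "right" replacing the internal matcher.
#' @return list (flank placement) with \code{left}, \code{right}: each
#'   \code{placements} data.frame (chrom, start, end 0-based half-open,
#'   strand, coverage) and \code{class}.
#' @export
placeFlanks <- function(flanks, reference = NULL, minIdentity = 100,
                        minCov = 0.8, paf = NULL) {
  if (is.null(paf)) {
    if (is.null(reference)) stop("supply a reference or PAF alignments")
    L <- placeOneFlank(flanks$left$seq, reference, minIdentity, minCov,
                       proximalSide = "right")
    R <- placeOneFlank(flanks$right$seq, reference, minIdentity, minCov,
                       proximalSide = "left")
  } else {
    fromPaf <- function(qn, len) {
      rows <- paf[paf$qname == qn, , drop = FALSE]
      if (!nrow(rows))
        return(list(placements = data.frame(chrom = character(0),
                                            start = numeric(0),
                                            end = numeric(0),
                                            strand = character(0),
                                            coverage = numeric(0)),
                    class = "unmapped"))
      cov <- (rows$qend - rows$qstart) / rows$qlen
      ident <- rows$nmatch / rows$alnlen * 100
      keep <- ident >= minIdentity
      rows <- rows[keep, , drop = FALSE]; cov <- cov[keep]
      if (!nrow(rows))
        return(list(placements = data.frame(chrom = character(0),
                                            start = numeric(0),
                                            end = numeric(0),
                                            strand = character(0),
                                            coverage = numeric(0)),
                    class = "unmapped"))
      pl <- data.frame(chrom = rows$tname, start = rows$tstart,
                       end = rows$tend, strand = rows$strand,
                       coverage = cov)
      cls <- if (all(cov < minCov)) "partial"
             else if (nrow(pl) == 1L) "unequivocal" else "multiple"
      list(placements = pl, class = cls)
    }
    L <- fromPaf("left", nchar(flanks$left$seq))
    R <- fromPaf("right", nchar(flanks$right$seq))
  }
  if (L$class == "unequivocal" && R$class == "unequivocal" &&
      L$placements$strand[1L] != R$placements$strand[1L]) {
    L$class <- "multiple"
    R$class <- "multiple"
  }
  list(left = L, right = R)
}

nearestGeneId <- function(gr, point_chrom, point_pos) {
  if (is.null(gr) || !length(gr)) return(NA_character_)
  pt <- GenomicRanges::GRanges(point_chrom,
                               IRanges::IRanges(point_pos, point_pos))
  i <- GenomicRanges::nearest(pt, gr, ignore.strand = TRUE)
  if (is.na(i)) NA_character_ else gr$gene_id[i]
}

#' Classify a flank placement into a reliable or unreliable transfer
#'
#' A transfer is reliable when both flanks map unequivocally with
#' concordant orientation on one chromosome and the reference gap between
#' them is consistent with either an insertion absent from the reference
#' (gap between 0 and \code{gapTolerance}) or present in it (gap within
#' \code{gapTolerance} of the TE length). A single multiple-mapping flank
#' is rescued when its placement nearest the unequivocal flank shares the
#' same nearest flanking gene on the strain and the reference; everything
#' else is unreliable, with the reason recorded. The projected reference
#' interval is the gap between the placed flanks (zero-length for
#' insertions absent from the reference).
#'
#' @param fp flank placement from \code{\link{placeFlanks}}.
#' @param flanks the flank record from \code{\link{extractFlanks}}.
#' @param teLength length of the TE copy in the strain (bp).
#' @param strainGenes,refGenes optional GRanges with \code{gene_id} used
#'   as synteny anchors for the rescue rule.
#' @param gapTolerance bp tolerance on the reference gap.
#' @return one-row data.frame: \code{ref_chrom}, \code{ref_start},
#'   \code{ref_end}, \code{strand}, \code{reliable}, \code{reason},
#'   \code{note} ("clean" or "rescued").
#' @export
classifyTransfer <- function(fp, flanks, teLength,
                             strainGenes = NULL, refGenes = NULL,
                             gapTolerance = 50) {
  fail <- function(reason) data.frame(
    ref_chrom = NA_character_, ref_start = NA_real_, ref_end = NA_real_,
    strand = NA_character_, reliable = FALSE, reason = reason,
    note = "clean")
  note <- "clean"
  cl <- fp$left$class; cr <- fp$right$class
  if (cl == "unmapped" && cr == "unmapped")
    return(fail("both-flanks-unmapped"))
  if (cl %in% c("partial", "unmapped") || cr %in% c("partial", "unmapped"))
    return(fail(paste0("flank-", cl, "/", cr)))
  lp <- fp$left$placements
  rp <- fp$right$placements
  if (cl == "multiple" && cr == "multiple")
    return(fail("both-flanks-multiple"))
  if (xor(cl == "multiple", cr == "multiple")) {
    if (is.null(strainGenes) || is.null(refGenes))
      return(fail("multiple-mapping-no-anchor"))
    if (cl == "multiple") {
      anchor <- rp[1L, ]
      cand <- lp[lp$chrom == anchor$chrom, , drop = FALSE]
      if (!nrow(cand)) return(fail("multiple-mapping-off-chrom"))
      cand <- cand[which.min(abs((cand$start + cand$end) / 2 -
                                 (anchor$start + anchor$end) / 2)), ]
      strainGene <- nearestGeneId(strainGenes, flanks$chrom,
                                  flanks$left$start + 1)
      refGene <- nearestGeneId(refGenes, cand$chrom, cand$start + 1)
      if (is.na(strainGene) || is.na(refGene) || strainGene != refGene)
        return(fail("multiple-mapping-anchor-mismatch"))
      lp <- cand
    } else {
      anchor <- lp[1L, ]
      cand <- rp[rp$chrom == anchor$chrom, , drop = FALSE]
      if (!nrow(cand)) return(fail("multiple-mapping-off-chrom"))
      cand <- cand[which.min(abs((cand$start + cand$end) / 2 -
                                 (anchor$start + anchor$end) / 2)), ]
      strainGene <- nearestGeneId(strainGenes, flanks$chrom,
                                  flanks$right$end)
      refGene <- nearestGeneId(refGenes, cand$chrom, cand$end)
      if (is.na(strainGene) || is.na(refGene) || strainGene != refGene)
        return(fail("multiple-mapping-anchor-mismatch"))
      rp <- cand
    }
    note <- "rescued"
  }
  lp <- lp[1L, ]; rp <- rp[1L, ]
  if (lp$chrom != rp$chrom) return(fail("different-chromosomes"))
  if (lp$strand != rp$strand) return(fail("discordant-orientation"))
  if (lp$strand == "+") {
    gap <- rp$start - lp$end
    iv <- c(lp$end, rp$start)
  } else {
    gap <- lp$start - rp$end
    iv <- c(rp$end, lp$start)
  }
  okAbsent <- gap >= 0 && gap <= gapTolerance
  okPresent <- abs(gap - teLength) <= gapTolerance
  if (!okAbsent && !okPresent) {
    if (gap < 0) return(fail("flank-overlap"))
    return(fail("gap-exceeds-tolerance"))
  }
  data.frame(ref_chrom = lp$chrom, ref_start = iv[1L], ref_end = iv[2L],
             strand = lp$strand, reliable = TRUE, reason = "ok",
             note = note)
}

#' Transfer all TE annotations of a cohort onto the reference
#'
#' Runs flank extraction, placement and reliability classification for
#' every record; no record is dropped silently (records in = reliable +
#' unreliable, each unreliable with a reason). Counts per stage are
#' logged via \code{message}.
#'
#' @param annotations data.frame of per-strain TE records (columns
#'   \code{strain}, \code{chrom}, \code{start}, \code{end},
#'   \code{family}, \code{length}).
#' @param genomes named list of strain DNAStringSet genomes.
#' @param reference DNAStringSet reference genome.
#' @param flankBp flank length (bp).
#' @param minIdentity,minCov see \code{\link{placeFlanks}}.
#' @param gapTolerance see \code{\link{classifyTransfer}}.
#' @param strainGenes,refGenes optional synteny anchors (refGenes shared;
#'   strainGenes a named list per strain).
#' @param verbose log per-strain counts.
#' @return data.frame: the input records plus transfer columns.
#' @export
transferCohort <- function(annotations, genomes, reference,
                           flankBp = 1000, minIdentity = 100,
                           minCov = 0.8, gapTolerance = 50,
                           strainGenes = NULL, refGenes = NULL,
                           verbose = FALSE) {
  out <- vector("list", nrow(annotations))
  for (i in seq_len(nrow(annotations))) {
    te <- annotations[i, ]
    fl <- extractFlanks(te, genomes[[te$strain]], flankBp)
    fp <- placeFlanks(fl, reference, minIdentity, minCov)
    tr <- classifyTransfer(
      fp, fl, teLength = te$end - te$start,
      strainGenes = if (is.null(strainGenes)) NULL
                    else strainGenes[[te$strain]],
      refGenes = refGenes, gapTolerance = gapTolerance)
    out[[i]] <- cbind(te, tr)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (verbose) {
    message(nrow(res), " records in; ", sum(res$reliable),
            " reliable, ", sum(!res$reliable), " unreliable")
    tab <- table(res$reason[!res$reliable])
    for (nm in names(tab)) message("  unreliable/", nm, ": ", tab[[nm]])
  }
  res
}

#' Cluster reliable transfers into orthologous insertion groups
#'
#' Family-aware single-linkage clustering of projected reference
#' intervals: transfers of the same family on the same chromosome whose
#' interval midpoints lie within \code{positionTolerance} bp chain into
#' one group. A group never holds two insertions from one strain: the
#' member nearest the group's representative interval is kept and the
#' others are flagged tandem. Group ids are minted as
#' \code{chrom_start_end_family} from the representative (modal)
#' reference interval.
#'
#' @param transferred data.frame from \code{\link{transferCohort}}; only
#'   reliable rows are used.
#' @param strains character vector of all cohort strains (defines the
#'   presence-vector length, including strains with no members).
#' @param positionTolerance bp linkage tolerance.
#' @param strainInfo optional strain metadata for the presence matrix.
#' @return list of class \code{orthologGroups}: \code{pm} (a
#'   \linkS4class{PresenceMatrix}), \code{members} (data.frame with
#'   group_id, strain, length, tandem flag).
#' @export
clusterOrthologs <- function(transferred, strains,
                             positionTolerance = 100,
                             strainInfo = NULL) {
  rel <- transferred[transferred$reliable, , drop = FALSE]
  if (!nrow(rel)) stop("no reliable transfers to cluster")
  rel$mid <- (rel$ref_start + rel$ref_end) / 2
  groups <- list()
  members <- list()
  for (key in unique(paste(rel$ref_chrom, rel$family, sep = "\r"))) {
    parts <- strsplit(key, "\r")[[1L]]
    sub <- rel[rel$ref_chrom == parts[1L] & rel$family == parts[2L], ,
               drop = FALSE]
    sub <- sub[order(sub$mid, sub$strain), , drop = FALSE]
    breaks <- c(0, which(diff(sub$mid) > positionTolerance), nrow(sub))
    for (b in seq_len(length(breaks) - 1L)) {
      rows <- sub[(breaks[b] + 1L):breaks[b + 1L], , drop = FALSE]
      # representative interval: modal (start,end), smallest on ties
      ivs <- paste(rows$ref_start, rows$ref_end)
      rep_iv <- names(sort(table(ivs), decreasing = TRUE))[1L]
      rep_se <- as.numeric(strsplit(rep_iv, " ")[[1L]])
      gid <- paste(parts[1L], rep_se[1L], rep_se[2L], parts[2L],
                   sep = "_")
      rows$tandem <- FALSE
      dup <- names(table(rows$strain))[table(rows$strain) > 1]
      for (s in dup) {
        si <- which(rows$strain == s)
        keep <- si[which.min(abs(rows$mid[si] -
                                 (rep_se[1L] + rep_se[2L]) / 2))]
        rows$tandem[setdiff(si, keep)] <- TRUE
      }
      groups[[gid]] <- data.frame(
        group_id = gid, chrom = parts[1L], start = rep_se[1L],
        end = rep_se[2L], family = parts[2L])
      members[[gid]] <- data.frame(
        group_id = gid, strain = rows$strain, length = rows$length,
        ref_start = rows$ref_start, ref_end = rows$ref_end,
        tandem = rows$tandem)
    }
  }
  groupDf <- do.call(rbind, groups)
  memberDf <- do.call(rbind, members)
  rownames(groupDf) <- groupDf$group_id
  rownames(memberDf) <- NULL
  o <- order(groupDf$chrom, groupDf$start, groupDf$family)
  groupDf <- groupDf[o, , drop = FALSE]
  pres <- matrix(FALSE, length(strains), nrow(groupDf),
                 dimnames = list(strains, groupDf$group_id))
  for (i in seq_len(nrow(memberDf)))
    if (!memberDf$tandem[i])
      pres[memberDf$strain[i], memberDf$group_id[i]] <- TRUE
  structure(list(pm = PresenceMatrix(pres, strainInfo = strainInfo,
                                     lociInfo = groupDf),
                 members = memberDf),
            class = "orthologGroups")
}

#' Drop ortholog groups dominated by short members
#'
#' A group is kept only when strictly more than half of its member copies
#' are longer than \code{minLen} bp; groups of mostly short fragments are
#' likely annotation artifacts.
#'
#' @param og an \code{orthologGroups} list from
#'   \code{\link{clusterOrthologs}}.
#' @param minLen length threshold in bp (members must exceed it).
#' @param verbose log the number of groups removed.
#' @return the filtered \code{orthologGroups}.
#' @export
filterGroupsByLength <- function(og, minLen = 120, verbose = FALSE) {
  keepGid <- vapply(split(og$members$length, og$members$group_id),
                    function(l) sum(l > minLen) > length(l) / 2, TRUE)
  keep <- names(keepGid)[keepGid]
  pm <- og$pm
  sel <- colnames(presence(pm)) %in% keep
  if (verbose)
    message(sum(!sel), " of ", length(sel),
            " groups removed by the length-majority filter (", minLen,
            " bp)")
  structure(list(
    pm = PresenceMatrix(presence(pm)[, sel, drop = FALSE],
                        strainInfo = strainInfo(pm),
                        lociInfo = lociInfo(pm)[sel, , drop = FALSE]),
    members = og$members[og$members$group_id %in% keep, , drop = FALSE]),
    class = "orthologGroups")
}

#' Post-annotation filtering of raw TE copies
#'
#' Removes copies shorter than \code{minCopyLen} bp (too short to
#' annotate confidently) and copies with more than \code{maxSatOverlap}
#' of their length covered by satellite annotation.
#'
#' @param records data.frame of TE records (\code{chrom}, \code{start},
#'   \code{end}, 0-based half-open).
#' @param minCopyLen copies strictly shorter are removed (default 100).
#' @param satellites optional GRanges (1-based) or data.frame
#'   (\code{chrom,start,end}, 0-based half-open) of satellite intervals.
#' @param maxSatOverlap maximum tolerated covered fraction.
#' @param verbose log counts removed per filter.
#' @return the filtered records.
#' @export
postfilterAnnotation <- function(records, minCopyLen = 100,
                                 satellites = NULL, maxSatOverlap = 0.8,
                                 verbose = FALSE) {
  len <- records$end - records$start
  shortDrop <- len < minCopyLen
  satDrop <- rep(FALSE, nrow(records))
  if (!is.null(satellites)) {
    if (is.data.frame(satellites))
      satellites <- GenomicRanges::GRanges(
        satellites$chrom,
        IRanges::IRanges(satellites$start + 1, satellites$end))
    if (length(satellites)) {
      gr <- GenomicRanges::GRanges(
        records$chrom,
        IRanges::IRanges(records$start + 1, records$end))
      satellites <- GenomicRanges::reduce(satellites)
      ov <- GenomicRanges::findOverlaps(gr, satellites)
      covered <- numeric(nrow(records))
      if (length(ov)) {
        pint <- GenomicRanges::pintersect(
          gr[S4Vectors::queryHits(ov)],
          satellites[S4Vectors::subjectHits(ov)])
        w <- GenomicRanges::width(pint)
        for (k in seq_along(w))
          covered[S4Vectors::queryHits(ov)[k]] <-
            covered[S4Vectors::queryHits(ov)[k]] + w[k]
      }
      satDrop <- covered / len > maxSatOverlap
    }
  }
  if (verbose)
    message(sum(shortDrop), " copies < ", minCopyLen, " bp removed; ",
            sum(satDrop & !shortDrop), " removed for satellite overlap > ",
            maxSatOverlap)
  records[!(shortDrop | satDrop), , drop = FALSE]
}

#' Compare two TE annotation sets at reciprocal breadth of coverage
#'
#' Family-aware matching: two copies match when each covers at least
#' \code{reciprocalCov} of the other's length and the families agree.
#' Reports matched/unique counts per set and per family.
#'
#' @param setA,setB data.frames (\code{chrom,start,end,family}, 0-based
#'   half-open) on the same coordinate system.
#' @param reciprocalCov minimum mutual breadth of coverage.
#' @return list with \code{summary} (counts and matched fractions) and
#'   \code{perFamily} data.frame.
#' @export
compareAnnotations <- function(setA, setB, reciprocalCov = 0.95) {
  grA <- GenomicRanges::GRanges(setA$chrom,
                                IRanges::IRanges(setA$start + 1,
                                                 setA$end))
  grB <- GenomicRanges::GRanges(setB$chrom,
                                IRanges::IRanges(setB$start + 1,
                                                 setB$end))
  ov <- GenomicRanges::findOverlaps(grA, grB)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  w <- GenomicRanges::width(GenomicRanges::pintersect(grA[qh], grB[sh]))
  good <- w >= reciprocalCov * GenomicRanges::width(grA[qh]) &
    w >= reciprocalCov * GenomicRanges::width(grB[sh]) &
    setA$family[qh] == setB$family[sh]
  matchedA <- unique(qh[good])
  matchedB <- unique(sh[good])
  fams <- sort(unique(c(setA$family, setB$family)))
  perFamily <- do.call(rbind, lapply(fams, function(fm) data.frame(
    family = fm,
    nA = sum(setA$family == fm), nB = sum(setB$family == fm),
    matchedA = length(intersect(matchedA, which(setA$family == fm))),
    matchedB = length(intersect(matchedB, which(setB$family == fm))))))
  list(summary = data.frame(
         nA = nrow(setA), nB = nrow(setB),
         matchedA = length(matchedA), matchedB = length(matchedB),
         fracA = if (nrow(setA)) length(matchedA) / nrow(setA) else NA,
         fracB = if (nrow(setB)) length(matchedB) / nrow(setB) else NA),
       perFamily = perFamily)
}
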