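#' EHHCurve: extended haplotype homozygosity decay around a core site
#'
#' EHH at distance x is the probability that two randomly drawn carriers
#' of the core allele are identical at every site from the core out to x.
#' With identical-haplotype classes of sizes c_h among the n carriers,
#' EHH(x) = sum_h C(c_h, 2) / C(n, 2). The curve starts at 1 and is
#' non-increasing within each side because classes only ever split as the
#' window grows. For the pooled variant used by iHH12, the two largest
#' classes over all haplotypes are merged before counting pairs.
#'
#' @slot core integer column index of the core site.
#' @slot allele "derived", "ancestral" or "combined-top2".
#' @slot left,right data.frames with columns \code{site}, \code{distPhys}
#'   (bp), \code{distGen} (cM, NA without a map), \code{distSites},
#'   \code{ehh}; the core point (distance 0, EHH 1) is implicit.
#' @slot truncLeft,truncRight why each side stopped: "cutoff",
#'   "chromosome-end" or "max-extension".
#' @exportClass EHHCurve
setClass("EHHCurve",
  slots = c(core = "integer", allele = "character",
            left = "data.frame", right = "data.frame",
            truncLeft = "character", truncRight = "character"))

#' @rdname EHHCurve-class
#' @param object an EHHCurve.
#' @export
setMethod("show", "EHHCurve", function(object) {
  cat("EHHCurve at site", object@core, "(", object@allele, ")\n",
      " left:", nrow(object@left), "steps (", object@truncLeft, ")",
      " right:", nrow(object@right), "steps (", object@truncRight, ")\n")
})

# one-directional EHH walk with partition refinement; classes refine
# monotonically (once split, never merge), so EHH is non-increasing
ehhWalk <- function(hap, rows, initGroups, core, dir, cutoff,
                    maxExtentSites, pooledTop2 = FALSE) {
  m <- ncol(hap)
  n <- length(rows)
  npairs <- n * (n - 1) / 2
  js <- if (dir > 0) {
    if (core >= m) integer(0) else seq(core + 1L, m)
  } else {
    if (core <= 1L) integer(0) else seq(core - 1L, 1L)
  }
  groups <- initGroups
  ehh <- numeric(0)
  sites <- integer(0)
  trunc <- "chromosome-end"
  homoz <- function(g) {
    sz <- tabulate(g)
    if (pooledTop2) {
      sz <- sort(sz[sz > 0], decreasing = TRUE)
      top <- sum(sz[seq_len(min(2L, length(sz)))])
      rest <- if (length(sz) > 2) sz[-(1:2)] else integer(0)
      (top * (top - 1) / 2 + sum(rest * (rest - 1) / 2)) / npairs
    } else {
      sum(sz * (sz - 1) / 2) / npairs
    }
  }
  step <- 0L
  for (j in js) {
    step <- step + 1L
    key <- groups * 2L + hap[rows, j]
    groups <- match(key, unique(key))
    e <- homoz(groups)
    ehh <- c(ehh, e)
    sites <- c(sites, j)
    if (e < cutoff || e == 0) { trunc <- "cutoff"; break }
    if (step >= maxExtentSites) { trunc <- "max-extension"; break }
  }
  list(ehh = ehh, sites = sites, trunc = trunc)
}

#' Compute an EHH curve around a core site
#'
#' The curve is computed outward site by site in both directions, for the
#' carriers of the requested core allele ("derived" = allele 1,
#' "ancestral" = allele 0) or, for "combined-top2", over all haplotypes
#' with the two largest extended-haplotype classes pooled (the quantity
#' integrated by iHH12). Extension stops at the first point below
#' \code{cutoff} (that point is kept, matching the downstream integration
#' rule), at \code{maxExtentSites}, or at the chromosome end.
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param core column index of the core site.
#' @param allele "derived", "ancestral" or "combined-top2".
#' @param cutoff EHH value at which extension stops (0 = never).
#' @param maxExtentSites maximum sites to extend per side.
#' @return An \linkS4class{EHHCurve}.
#' @export
computeEHH <- function(panel, core, allele = c("derived", "ancestral",
                                               "combined-top2"),
                       cutoff = 0.05, maxExtentSites = Inf) {
  allele <- match.arg(allele)
  hap <- haplotypes(panel)
  core <- as.integer(core)
  a <- hap[, core]
  if (all(a == a[1L])) stop("monomorphic core site")
  if (allele == "combined-top2") {
    rows <- seq_len(nrow(hap))
    if (length(rows) < 4) stop("iHH12 pooling needs at least 4 haplotypes")
    initGroups <- a + 1L
    pooled <- TRUE
  } else {
    rows <- which(a == if (allele == "derived") 1L else 0L)
    if (length(rows) < 2)
      stop("EHH undefined for fewer than 2 carriers of the ", allele,
           " allele")
    initGroups <- rep(1L, length(rows))
    pooled <- FALSE
  }
  pos <- positions(panel)
  gen <- geneticPositions(panel)
  sideDf <- function(w) {
    if (!length(w$sites))
      return(data.frame(site = integer(0), distPhys = numeric(0),
                        distGen = numeric(0), distSites = integer(0),
                        ehh = numeric(0)))
    data.frame(site = w$sites,
               distPhys = abs(pos[w$sites] - pos[core]),
               distGen = if (length(gen)) abs(gen[w$sites] - gen[core])
                         else NA_real_,
               distSites = seq_along(w$sites),
               ehh = w$ehh)
  }
  L <- ehhWalk(hap, rows, initGroups, core, -1L, cutoff, maxExtentSites,
               pooled)
  R <- ehhWalk(hap, rows, initGroups, core, 1L, cutoff, maxExtentSites,
               pooled)
  new("EHHCurve", core = core, allele = allele,
      left = sideDf(L), right = sideDf(R),
      truncLeft = L$trunc, truncRight = R$trunc)
}

#' Integrate an EHH curve into an iHH value
#'
#' Trapezoidal integral of EHH over distance, each side integrated
#' outward from the core (distance 0, EHH 1) up to and including the
#' first point with EHH below \code{cutoff}, then summed over the two
#' sides. When a side reaches the chromosome end while still above the
#' cutoff the value is returned with \code{truncated = TRUE} so the
#' caller may discard the site.
#'
#' @param curve an \linkS4class{EHHCurve}.
#' @param cutoff EHH truncation cutoff.
#' @param scale "physical" (bp), "genetic" (cM) or "sites".
#' @return list with \code{value} and \code{truncated}.
#' @export
integrateIHH <- function(curve, cutoff = 0.05,
                         scale = c("physical", "genetic", "sites")) {
  scale <- match.arg(scale)
  distcol <- switch(scale, physical = "distPhys", genetic = "distGen",
                    sites = "distSites")
  one <- function(df, truncReason) {
    x <- c(0, df[[distcol]])
    y <- c(1, df$ehh)
    if (anyNA(x)) stop("genetic distances unavailable for this panel")
    below <- which(y < cutoff)
    truncated <- FALSE
    if (length(below)) {
      last <- below[1L]
      x <- x[seq_len(last)]
      y <- y[seq_len(last)]
    } else if (truncReason == "chromosome-end") {
      truncated <- TRUE
    }
    v <- if (length(x) > 1)
      sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2) else 0
    list(v = v, truncated = truncated)
  }
  L <- one(curve@left, curve@truncLeft)
  R <- one(curve@right, curve@truncRight)
  list(value = L$v + R$v, truncated = L$truncated || R$truncated)
}

#' Unstandardized iHS at a core site
#'
#' ln(iHH_A / iHH_D): the log-ratio of the integrated EHH of the
#' ancestral-allele carriers over that of the derived-allele carriers.
#' Long shared haplotypes around a derived allele (an incomplete sweep)
#' drive iHS strongly negative.
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param core column index of the core site.
#' @param cutoff EHH truncation cutoff.
#' @param scale distance scale for integration ("physical", "genetic").
#' @param mafFloor minimum minor/derived allele frequency.
#' @return list with \code{value} (NA when undefined) and \code{reason}
#'   ("ok", "maf", "carriers", "truncated", "zero-ihh").
#' @export
computeIHS <- function(panel, core, cutoff = 0.05,
                       scale = c("physical", "genetic"),
                       mafFloor = 0.05) {
  scale <- match.arg(scale)
  a <- haplotypes(panel)[, core]
  f <- mean(a)
  if (f < mafFloor || f > 1 - mafFloor)
    return(list(value = NA_real_, reason = "maf"))
  if (sum(a == 1L) < 2 || sum(a == 0L) < 2)
    return(list(value = NA_real_, reason = "carriers"))
  iA <- integrateIHH(computeEHH(panel, core, "ancestral", cutoff),
                     cutoff, scale)
  iD <- integrateIHH(computeEHH(panel, core, "derived", cutoff),
                     cutoff, scale)
  if (iA$truncated || iD$truncated)
    return(list(value = NA_real_, reason = "truncated"))
  if (iA$value == 0 || iD$value == 0)
    return(list(value = NA_real_, reason = "zero-ihh"))
  list(value = log(iA$value / iD$value), reason = "ok")
}

#' Unstandardized nSL at a core site
#'
#' Distance is measured in numbers of segregating sites instead of map
#' units: for each pair of carriers of an allele, L is the number of
#' sites in the maximal interval around the core (core included) over
#' which the two haplotypes are identical; SL is the mean of L over
#' pairs, and nSL = ln(SL_A / SL_D). Computed via the identity
#' SL = 1 + sum_k EHH_left(k) + sum_k EHH_right(k), summing the pairwise
#' identity probability over site steps; no EHH cutoff is applied.
#'
#' @inheritParams computeIHS
#' @param maxExtentSites optional cap on per-side extension (site count).
#' @return list with \code{value} and \code{reason} as in
#'   \code{\link{computeIHS}}.
#' @export
computeNSL <- function(panel, core, mafFloor = 0.05,
                       maxExtentSites = Inf) {
  a <- haplotypes(panel)[, core]
  f <- mean(a)
  if (f < mafFloor || f > 1 - mafFloor)
    return(list(value = NA_real_, reason = "maf"))
  if (sum(a == 1L) < 2 || sum(a == 0L) < 2)
    return(list(value = NA_real_, reason = "carriers"))
  slOf <- function(allele) {
    cv <- computeEHH(panel, core, allele, cutoff = 0,
                     maxExtentSites = maxExtentSites)
    1 + sum(cv@left$ehh) + sum(cv@right$ehh)
  }
  sA <- slOf("ancestral")
  sD <- slOf("derived")
  list(value = log(sA / sD), reason = "ok")
}

#' Unstandardized iHH12 at a core site
#'
#' Integrated EHH12, where EHH12 pools the two largest extended-haplotype
#' classes over all haplotypes before counting identical pairs; pooling
#' the top classes gives power against soft sweeps in which two swept
#' haplotypes segregate.
#'
#' @inheritParams computeIHS
#' @return list with \code{value} (>= 0 when defined) and \code{reason}.
#' @export
computeIHH12 <- function(panel, core, cutoff = 0.05,
                         scale = c("physical", "genetic"),
                         mafFloor = 0.05) {
  scale <- match.arg(scale)
  a <- haplotypes(panel)[, core]
  f <- mean(a)
  if (f < mafFloor || f > 1 - mafFloor)
    return(list(value = NA_real_, reason = "maf"))
  cv <- computeEHH(panel, core, "combined-top2", cutoff)
  ii <- integrateIHH(cv, cutoff, scale)
  if (ii$truncated)
    return(list(value = NA_real_, reason = "truncated"))
  list(value = ii$value, reason = "ok")
}

#' Scan every eligible site of a panel
#'
#' Computes unstandardized iHS, nSL and iHH12 for every site whose
#' derived-allele frequency clears \code{mafFloor}. Sites whose EHH
#' integration hits the chromosome end before reaching the cutoff get NA
#' for the affected statistic and are excluded from standardization.
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param cutoff EHH truncation cutoff.
#' @param scale distance scale for iHS/iHH12 integration; "genetic" is
#'   used automatically when the panel carries genetic positions.
#' @param mafFloor minimum derived/minor allele frequency.
#' @param maxExtentSites per-side extension cap for nSL.
#' @return A \linkS4class{SelectionScores} with unstandardized values.
#' @export
scanPanel <- function(panel, cutoff = 0.05, scale = NULL,
                      mafFloor = 0.05, maxExtentSites = Inf) {
  if (is.null(scale))
    scale <- if (length(geneticPositions(panel))) "genetic" else "physical"
  m <- nSites(panel)
  daf <- derivedFreq(panel)
  res <- data.frame(chrom = panelChrom(panel), site = seq_len(m),
                    pos = positions(panel), daf = daf,
                    ihs = NA_real_, nsl = NA_real_, ihh12 = NA_real_,
                    ihs_reason = "maf", nsl_reason = "maf",
                    ihh12_reason = "maf")
  for (j in seq_len(m)) {
    if (daf[j] < mafFloor || daf[j] > 1 - mafFloor) next
    hs <- computeIHS(panel, j, cutoff, scale, mafFloor)
    res$ihs[j] <- hs$value; res$ihs_reason[j] <- hs$reason
    ns <- computeNSL(panel, j, mafFloor, maxExtentSites)
    res$nsl[j] <- ns$value; res$nsl_reason[j] <- ns$reason
    h12 <- computeIHH12(panel, j, cutoff, scale, mafFloor)
    res$ihh12[j] <- h12$value; res$ihh12_reason[j] <- h12$reason
  }
  new("SelectionScores", scores = res, thresholds = data.frame())
}

#' Standardize selection statistics in frequency bins
#'
#' Sites are partitioned into \code{nBins} equal-width derived-allele
#' frequency bins within each chromosome and each statistic is z-scored
#' ((u - mean) / sd, sample sd) within its (chromosome, bin) cell. Cells
#' with fewer than two values or zero spread leave their sites
#' unstandardizable (NA, excluded from significance calling).
#'
#' @param ss a \linkS4class{SelectionScores} from \code{\link{scanPanel}}.
#' @param nBins number of frequency bins.
#' @return The \linkS4class{SelectionScores} with \code{bin} and
#'   \code{std_*} columns added.
#' @export
normalizeScores <- function(ss, nBins = 10) {
  s <- scoreTable(ss)
  s$bin <- pmin(floor(s$daf * nBins) + 1L, nBins)
  for (st in c("ihs", "nsl", "ihh12")) {
    z <- rep(NA_real_, nrow(s))
    for (ch in unique(s$chrom)) {
      for (b in unique(s$bin)) {
        idx <- which(s$chrom == ch & s$bin == b & !is.na(s[[st]]))
        if (length(idx) < 2) next
        mu <- mean(s[[st]][idx])
        sdev <- sd(s[[st]][idx])
        if (sdev == 0) next
        z[idx] <- (s[[st]][idx] - mu) / sdev
      }
    }
    s[[paste0("std_", st)]] <- z
  }
  new("SelectionScores", scores = s, thresholds = ss@thresholds)
}

#' Neutral calibration sites: SNPs in the 5' ends of small introns
#'
#' Selects the panel sites located at offsets 8-30 (1-based from the
#' intron's 5' end on the transcribed strand) of introns no longer than
#' \code{intronMaxLen} bp; such positions evolve close to neutrally and
#' calibrate the significance threshold of the selection statistics.
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param introns GRanges of intron intervals with strand (e.g. from
#'   \code{\link{intronsOf}}).
#' @param intronMaxLen maximum qualifying intron length (bp).
#' @param offsets integer length-2, inclusive 1-based offset window.
#' @return integer vector of panel site indices.
#' @export
neutralSites <- function(panel, introns, intronMaxLen = 65,
                         offsets = c(8L, 30L)) {
  introns <- introns[GenomicRanges::width(introns) <= intronMaxLen]
  introns <- introns[as.character(GenomicRanges::seqnames(introns)) ==
                       panelChrom(panel)]
  if (!length(introns)) return(integer(0))
  st <- as.character(GenomicRanges::strand(introns))
  winStart <- ifelse(st == "-",
                     GenomicRanges::end(introns) - offsets[2L] + 1L,
                     GenomicRanges::start(introns) + offsets[1L] - 1L)
  winEnd <- ifelse(st == "-",
                   GenomicRanges::end(introns) - offsets[1L] + 1L,
                   GenomicRanges::start(introns) + offsets[2L] - 1L)
  winStart <- pmax(winStart, GenomicRanges::start(introns))
  winEnd <- pmin(winEnd, GenomicRanges::end(introns))
  pos <- positions(panel)
  hit <- logical(length(pos))
  for (i in seq_along(winStart))
    hit <- hit | (pos >= winStart[i] & pos <= winEnd[i])
  which(hit)
}

#' Call significant sites against the neutral distribution
#'
#' Per statistic, the threshold is the \code{percentile}-th percentile
#' (linear interpolation between order statistics) of the standardized
#' neutral-site values; sites strictly greater are flagged. iHS and nSL
#' are compared on |z| (sweeps push either tail), iHH12 on z.
#'
#' @param ss a standardized \linkS4class{SelectionScores}.
#' @param neutral integer site indices from \code{\link{neutralSites}}.
#' @param percentile percentile defining the threshold (default 95).
#' @param minNeutral minimum neutral sites with standardized values
#'   required per statistic.
#' @param absStats statistics thresholded on |z|.
#' @return The \linkS4class{SelectionScores} with \code{sig_*} flag
#'   columns and the thresholds table filled.
#' @export
callSignificantScores <- function(ss, neutral, percentile = 95,
                                  minNeutral = 20,
                                  absStats = c("ihs", "nsl")) {
  s <- scoreTable(ss)
  thr <- list()
  for (st in c("ihs", "nsl", "ihh12")) {
    col <- paste0("std_", st)
    if (!col %in% names(s))
      stop("scores are not standardized; run normalizeScores() first")
    z <- s[[col]]
    transform <- if (st %in% absStats) abs else identity
    nv <- transform(z[intersect(neutral, which(!is.na(z)))])
    if (length(nv) < minNeutral)
      stop("only ", length(nv), " neutral sites with standardized ", st,
           " values (need >= ", minNeutral, "); enlarge the neutral set ",
           "or supply an explicit threshold")
    t95 <- as.numeric(quantile(nv, percentile / 100, type = 7))
    s[[paste0("sig_", st)]] <- !is.na(z) & transform(z) > t95
    thr[[st]] <- data.frame(statistic = st, threshold = t95,
                            n_neutral = length(nv),
                            on_abs = st %in% absStats)
  }
  new("SelectionScores", scores = s, thresholds = do.call(rbind, thr))
}
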