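#' Classify an insertion frequency into rare / common / fixed
#'
#' rare: present in fewer than 10% of genomes; fixed: more than 95%;
#' common: everything in between (both bounds inclusive). When counts are
#' supplied (\code{k} present among \code{n} considered) the comparison is
#' exact on rationals, avoiding floating-point boundary artifacts.
#'
#' @param f frequency (fraction in [0,1]); ignored when \code{k,n} given.
#' @param rareBelow rare threshold (strictly below).
#' @param fixedAbove fixed threshold (strictly above).
#' @param k,n optional counts: present in k of n genomes.
#' @return character vector: "rare", "common" or "fixed".
#' @export
#' @examples
#' classifyFrequency(0.62)            # common
#' classifyFrequency(c(0.95, 0.96))   # common, fixed
classifyFrequency <- function(f = NULL, rareBelow = 0.10,
                              fixedAbove = 0.95, k = NULL, n = NULL) {
  if (!is.null(k)) {
    stopifnot(!is.null(n), all(k >= 0), all(k <= n))
    # exact rational comparison on counts (e.g. <10% of 47 means <=4)
    return(ifelse(k * 100 < rareBelow * 100 * n, "rare",
                  ifelse(k * 100 > fixedAbove * 100 * n, "fixed",
                         "common")))
  }
  if (any(f < 0 | f > 1)) stop("frequency outside [0, 1]")
  ifelse(f < rareBelow, "rare",
         ifelse(f > fixedAbove, "fixed", "common"))
}

classCounts <- function(presSub, rareBelow, fixedAbove) {
  k <- colSums(presSub)
  n <- nrow(presSub)
  seen <- k > 0
  cls <- classifyFrequency(k = k[seen], n = n,
                           rareBelow = rareBelow, fixedAbove = fixedAbove)
  c(rare = sum(cls == "rare"), common = sum(cls == "common"),
    fixed = sum(cls == "fixed"))
}

#' Rarefaction of frequency-class counts over genome counts
#'
#' For each cohort size k from \code{kMin} to \code{kMax}, draws
#' \code{replicates} random strain subsets without replacement,
#' recomputes each insertion's frequency among the k chosen strains,
#' classifies it, and reports the mean and SD of the per-class counts.
#' Insertions absent from every sampled strain are unobservable at that k
#' and are not counted. At k = cohort size every replicate is the full
#' cohort, so the SD is 0 and counts equal the full classification.
#'
#' @param pm a \linkS4class{PresenceMatrix}.
#' @param kMin smallest genome count (>= 2).
#' @param kMax largest genome count (defaults to the cohort size).
#' @param replicates random subsets per k.
#' @param seed RNG seed.
#' @param rareBelow,fixedAbove class thresholds.
#' @param exhaustive enumerate every k-subset instead of sampling
#'   (exact means; only allowed while choose(N, k) stays below 20000).
#' @return data.frame (long) with columns \code{k}, \code{class},
#'   \code{mean}, \code{sd}, \code{replicates}.
#' @export
rarefy <- function(pm, kMin = 5, kMax = NULL, replicates = 30,
                   seed = 1L, rareBelow = 0.10, fixedAbove = 0.95,
                   exhaustive = FALSE) {
  p <- presence(pm)
  N <- nrow(p)
  if (is.null(kMax)) kMax <- N
  if (kMin < 2) stop("kMin must be >= 2")
  if (kMin > kMax) stop("kMin > kMax")
  if (kMax > N) stop("kMax exceeds cohort size")
  set.seed(seed)
  out <- list()
  for (k in kMin:kMax) {
    if (exhaustive) {
      if (choose(N, k) > 20000)
        stop("choose(N, k) too large for exhaustive enumeration")
      subsets <- combn(N, k)
      cc <- t(apply(subsets, 2L, function(rows)
        classCounts(p[rows, , drop = FALSE], rareBelow, fixedAbove)))
      colnames(cc) <- c("rare", "common", "fixed")
      replicates <- ncol(subsets)
    } else {
      cc <- matrix(0, replicates, 3,
                   dimnames = list(NULL, c("rare", "common", "fixed")))
      for (r in seq_len(replicates)) {
        rows <- sample(N, k)
        cc[r, ] <- classCounts(p[rows, , drop = FALSE],
                               rareBelow, fixedAbove)
      }
    }
    for (cl in colnames(cc))
      out[[length(out) + 1]] <- data.frame(
        k = k, class = cl, mean = mean(cc[, cl]), sd = sd(cc[, cl]),
        replicates = replicates)
  }
  do.call(rbind, out)
}

#' Intersection lattice of common-TE sets at several cohort sizes
#'
#' For each k, one seeded random subset of strains defines the set of
#' insertions classified common among those k; the output is the full
#' intersection lattice (count of insertions per membership pattern,
#' UpSet style) across the k-specific common sets.
#'
#' @param pm a \linkS4class{PresenceMatrix}.
#' @param ks genome counts to compare (the cohort size yields the full
#'   cohort itself).
#' @param seed RNG seed.
#' @param rareBelow,fixedAbove class thresholds.
#' @param aggregate when TRUE, a TE belongs to the common set of k if it
#'   is common in the majority of \code{replicates} random subsets.
#' @param replicates subsets per k when \code{aggregate} is TRUE.
#' @return data.frame with one 0/1 membership column per k plus
#'   \code{count}; attribute \code{"sets"} holds the named member lists.
#' @export
commonSetIntersections <- function(pm, ks = NULL, seed = 1L,
                                   rareBelow = 0.10, fixedAbove = 0.95,
                                   aggregate = FALSE, replicates = 30) {
  p <- presence(pm)
  N <- nrow(p)
  if (is.null(ks)) ks <- unique(pmin(c(10, 20, 30, 40, N), N))
  stopifnot(all(ks <= N))
  set.seed(seed)
  commonSet <- function(k) {
    one <- function() {
      rows <- sample(N, k)
      sub <- p[rows, , drop = FALSE]
      kk <- colSums(sub)
      seen <- kk > 0
      ids <- colnames(p)[seen]
      cls <- classifyFrequency(k = kk[seen], n = k,
                               rareBelow = rareBelow,
                               fixedAbove = fixedAbove)
      ids[cls == "common"]
    }
    if (!aggregate) return(one())
    tallies <- table(unlist(replicate(replicates, one(),
                                      simplify = FALSE)))
    names(tallies)[tallies > replicates / 2]
  }
  sets <- lapply(ks, commonSet)
  names(sets) <- paste0("k", ks)
  universe <- unique(unlist(sets))
  memb <- vapply(sets, function(s) universe %in% s,
                 logical(length(universe)))
  if (length(universe) == 1L) memb <- matrix(memb, nrow = 1L,
                                             dimnames = list(NULL,
                                                             names(sets)))
  pattern <- apply(memb, 1L, paste, collapse = "")
  out <- do.call(rbind, lapply(unique(pattern), function(pt) {
    rows <- pattern == pt
    cbind(as.data.frame(t(as.integer(memb[which(rows)[1L], ]))),
          count = sum(rows))
  }))
  names(out)[seq_along(sets)] <- names(sets)
  attr(out, "sets") <- sets
  out
}

#' Frequency classes per continent and region-specific common insertions
#'
#' Frequencies are recomputed within each region's strains and classified
#' there. The summary lists insertions common in exactly one region and,
#' among those, the ones entirely absent (frequency 0) from each other
#' region — the geography-specific candidates.
#'
#' @param pm a \linkS4class{PresenceMatrix}.
#' @param metadata data.frame with columns \code{strain} and
#'   \code{continent}; defaults to \code{strainInfo(pm)}.
#' @param rareBelow,fixedAbove class thresholds.
#' @return list with \code{perRegion} (data.frame group_id x region ->
#'   class, frequency) and \code{summary} (data.frame of region-specific
#'   common insertions with absence flags per other region).
#' @export
continentalSets <- function(pm, metadata = NULL, rareBelow = 0.10,
                            fixedAbove = 0.95) {
  p <- presence(pm)
  if (is.null(metadata)) metadata <- strainInfo(pm)
  if (!all(c("strain", "continent") %in% names(metadata)))
    stop("metadata needs 'strain' and 'continent' columns")
  i <- match(rownames(p), metadata$strain)
  if (anyNA(i)) stop("strains missing from metadata: ",
                     paste(rownames(p)[is.na(i)], collapse = ", "))
  continent <- metadata$continent[i]
  regions <- unique(continent)
  small <- regions[table(continent)[regions] < 2]
  if (length(small)) {
    warning("excluding region(s) with <2 strains: ",
            paste(small, collapse = ", "))
    regions <- setdiff(regions, small)
  }
  perRegion <- list()
  for (rg in regions) {
    sub <- p[continent == rg, , drop = FALSE]
    k <- colSums(sub)
    cls <- rep(NA_character_, ncol(p))
    seen <- k > 0
    cls[seen] <- classifyFrequency(k = k[seen], n = nrow(sub),
                                   rareBelow = rareBelow,
                                   fixedAbove = fixedAbove)
    perRegion[[rg]] <- data.frame(group_id = colnames(p), region = rg,
                                  frequency = k / nrow(sub), class = cls)
  }
  perRegion <- do.call(rbind, perRegion)
  rownames(perRegion) <- NULL
  isCommon <- with(perRegion, tapply(class == "common", group_id,
                                     function(x) sum(x, na.rm = TRUE)))
  focal <- names(isCommon)[isCommon == 1]
  summ <- list()
  for (g in focal) {
    rows <- perRegion[perRegion$group_id == g, ]
    home <- rows$region[!is.na(rows$class) & rows$class == "common"]
    others <- setdiff(regions, home)
    absent <- others[vapply(others, function(o)
      rows$frequency[rows$region == o] == 0, TRUE)]
    summ[[g]] <- data.frame(group_id = g, common_in = home,
                            absent_elsewhere = length(absent) ==
                              length(others),
                            absent_regions = paste(absent,
                                                   collapse = ","))
  }
  list(perRegion = perRegion,
       summary = if (length(summ)) do.call(rbind, summ)
                 else data.frame(group_id = character(0),
                                 common_in = character(0),
                                 absent_elsewhere = logical(0),
                                 absent_regions = character(0)))
}
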