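#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom stats sd quantile rbinom rnorm rgeom runif setNames
#' @importFrom utils read.delim write.table combn head tail
NULL

#' HaplotypePanel: phased biallelic SNP haplotypes
#'
#' Holds a matrix of phased haplotypes (rows = haplotypes, columns = SNP
#' sites) with alleles coded 0 (ancestral) and 1 (derived), together with
#' physical positions (bp, 1-based as in VCF), optional genetic positions
#' (cM), the chromosome name, and the strain each haplotype belongs to
#' (two rows per strain for diploids, one for haploid consensus genomes).
#'
#' Sites must be strictly ordered by physical position and free of missing
#' data; both constraints are enforced by the validity method because every
#' extended-haplotype computation assumes them.
#'
#' @slot haplotypes integer matrix of 0/1 alleles, haplotypes x sites.
#' @slot positions numeric, physical positions in bp, strictly increasing.
#' @slot geneticPositions numeric, cM positions (length 0 when absent).
#' @slot chrom character(1), chromosome identifier.
#' @slot strains character, strain id of each haplotype row.
#' @exportClass HaplotypePanel
setClass("HaplotypePanel",
  slots = c(
    haplotypes = "matrix",
    positions = "numeric",
    geneticPositions = "numeric",
    chrom = "character",
    strains = "character"
  )
)

setValidity("HaplotypePanel", function(object) {
  h <- object@haplotypes
  msg <- character(0)
  if (!is.numeric(h) && !is.integer(h))
    msg <- c(msg, "haplotype matrix must be numeric")
  if (anyNA(h))
    msg <- c(msg, "missing genotypes are not allowed")
  else if (!all(h %in% c(0L, 1L)))
    msg <- c(msg, "alleles must be coded 0/1")
  if (length(object@positions) != ncol(h))
    msg <- c(msg, "one physical position required per site")
  if (ncol(h) > 1 && any(diff(object@positions) <= 0))
    msg <- c(msg, "positions must be strictly increasing")
  gp <- object@geneticPositions
  if (length(gp) && length(gp) != ncol(h))
    msg <- c(msg, "genetic positions must match site count")
  if (length(gp) > 1 && any(diff(gp) < 0))
    msg <- c(msg, "genetic positions must be non-decreasing")
  if (length(object@strains) != nrow(h))
    msg <- c(msg, "one strain label required per haplotype")
  if (length(object@chrom) != 1)
    msg <- c(msg, "chrom must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a HaplotypePanel
#'
#' @param haplotypes 0/1 matrix, haplotypes x sites.
#' @param positions physical positions (bp), strictly increasing.
#' @param chrom chromosome name.
#' @param geneticPositions optional cM positions.
#' @param strains strain label per haplotype; defaults to "S1", "S2", ...
#'   (one haplotype per strain).
#' @return A \linkS4class{HaplotypePanel}.
#' @export
HaplotypePanel <- function(haplotypes, positions, chrom = "2L",
                           geneticPositions = numeric(0),
                           strains = NULL) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  if (is.null(strains))
    strains <- paste0("S", seq_len(nrow(haplotypes)))
  new("HaplotypePanel",
      haplotypes = haplotypes,
      positions = as.numeric(positions),
      geneticPositions = as.numeric(geneticPositions),
      chrom = chrom, strains = as.character(strains))
}

#' @rdname HaplotypePanel
#' @param object,x a HaplotypePanel.
#' @export
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))
#' @rdname HaplotypePanel
#' @export
setMethod("haplotypes", "HaplotypePanel", function(x) x@haplotypes)

#' @rdname HaplotypePanel
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))
#' @rdname HaplotypePanel
#' @export
setMethod("positions", "HaplotypePanel", function(x) x@positions)

#' @rdname HaplotypePanel
#' @export
setGeneric("geneticPositions", function(x) standardGeneric("geneticPositions"))
#' @rdname HaplotypePanel
#' @export
setMethod("geneticPositions", "HaplotypePanel", function(x) x@geneticPositions)

#' @rdname HaplotypePanel
#' @export
setGeneric("strainOf", function(x) standardGeneric("strainOf"))
#' @rdname HaplotypePanel
#' @export
setMethod("strainOf", "HaplotypePanel", function(x) x@strains)

#' @rdname HaplotypePanel
#' @export
setGeneric("panelChrom", function(x) standardGeneric("panelChrom"))
#' @rdname HaplotypePanel
#' @export
setMethod("panelChrom", "HaplotypePanel", function(x) x@chrom)

#' @rdname HaplotypePanel
#' @export
nHaplotypes <- function(x) nrow(x@haplotypes)
#' @rdname HaplotypePanel
#' @export
nSites <- function(x) ncol(x@haplotypes)

#' @rdname HaplotypePanel
#' @export
setMethod("show", "HaplotypePanel", function(object) {
  cat("HaplotypePanel on", object@chrom, "\n",
      " ", nrow(object@haplotypes), "haplotypes x",
      ncol(object@haplotypes), "sites\n",
      " span:", min(object@positions), "-", max(object@positions), "bp",
      if (length(object@geneticPositions)) " (genetic map attached)", "\n")
})

#' Derived allele frequencies of a panel
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @return numeric vector of per-site derived allele frequencies.
#' @export
derivedFreq <- function(panel) colMeans(panel@haplotypes)

#' PresenceMatrix: strains x orthologous TE insertions
#'
#' Boolean presence/absence of each orthologous TE insertion locus in each
#' strain, with strain metadata (population, continent, climate) and locus
#' annotation (reference interval, family).
#'
#' @slot presence logical matrix, strains x loci.
#' @slot strainInfo data.frame keyed by strain id (rownames match
#'   rownames of \code{presence}).
#' @slot lociInfo data.frame with columns \code{group_id}, \code{chrom},
#'   \code{start}, \code{end} (0-based half-open), \code{family}; rownames
#'   match colnames of \code{presence}.
#' @exportClass PresenceMatrix
setClass("PresenceMatrix",
  slots = c(
    presence = "matrix",
    strainInfo = "data.frame",
    lociInfo = "data.frame"
  )
)

setValidity("PresenceMatrix", function(object) {
  p <- object@presence
  msg <- character(0)
  if (!is.logical(p))
    msg <- c(msg, "presence must be a logical matrix")
  if (anyNA(p))
    msg <- c(msg, "presence may not contain NA")
  if (nrow(object@strainInfo) != nrow(p))
    msg <- c(msg, "strainInfo rows must match strains")
  if (nrow(object@lociInfo) != ncol(p))
    msg <- c(msg, "lociInfo rows must match loci")
  need <- c("group_id", "chrom", "start", "end", "family")
  if (!all(need %in% names(object@lociInfo)))
    msg <- c(msg, paste("lociInfo must have columns:",
                        paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a PresenceMatrix
#'
#' @param presence logical matrix, strains x loci; rownames are strain ids,
#'   colnames are ortholog-group ids.
#' @param strainInfo optional data.frame of strain metadata (rownames =
#'   strain ids); a minimal frame is built when omitted.
#' @param lociInfo optional data.frame of locus annotation; a minimal frame
#'   is parsed from group ids of the form \code{chrom_start_end_family}
#'   when omitted.
#' @return A \linkS4class{PresenceMatrix}.
#' @export
PresenceMatrix <- function(presence, strainInfo = NULL, lociInfo = NULL) {
  presence <- as.matrix(presence)
  storage.mode(presence) <- "logical"
  if (is.null(rownames(presence)) && nrow(presence))
    rownames(presence) <- paste0("S", seq_len(nrow(presence)))
  if (is.null(colnames(presence)) && ncol(presence))
    colnames(presence) <- paste0("te", seq_len(ncol(presence)))
  if (is.null(strainInfo))
    strainInfo <- data.frame(strain = rownames(presence),
                             row.names = rownames(presence))
  if (is.null(lociInfo)) {
    parts <- strsplit(colnames(presence), "_")
    ok <- all(lengths(parts) >= 4)
    lociInfo <- data.frame(
      group_id = colnames(presence),
      chrom = if (ok) vapply(parts, `[`, "", 1L) else NA_character_,
      start = if (ok) as.numeric(vapply(parts, `[`, "", 2L)) else NA_real_,
      end = if (ok) as.numeric(vapply(parts, `[`, "", 3L)) else NA_real_,
      family = if (ok)
        vapply(parts, function(p) paste(p[-(1:3)], collapse = "_"), "")
      else NA_character_,
      row.names = colnames(presence))
  }
  new("PresenceMatrix", presence = presence,
      strainInfo = as.data.frame(strainInfo),
      lociInfo = as.data.frame(lociInfo))
}

#' @rdname PresenceMatrix
#' @param x,object a PresenceMatrix.
#' @export
setGeneric("presence", function(x) standardGeneric("presence"))
#' @rdname PresenceMatrix
#' @export
setMethod("presence", "PresenceMatrix", function(x) x@presence)

#' @rdname PresenceMatrix
#' @export
setGeneric("strainInfo", function(x) standardGeneric("strainInfo"))
#' @rdname PresenceMatrix
#' @export
setMethod("strainInfo", "PresenceMatrix", function(x) x@strainInfo)

#' @rdname PresenceMatrix
#' @export
setGeneric("lociInfo", function(x) standardGeneric("lociInfo"))
#' @rdname PresenceMatrix
#' @export
setMethod("lociInfo", "PresenceMatrix", function(x) x@lociInfo)

#' @rdname PresenceMatrix
#' @export
teFrequencies <- function(x) colMeans(x@presence)

#' @rdname PresenceMatrix
#' @export
setMethod("show", "PresenceMatrix", function(object) {
  f <- colMeans(object@presence)
  cat("PresenceMatrix:", nrow(object@presence), "strains x",
      ncol(object@presence), "TE insertion loci\n",
      " frequency range:", sprintf("%.3f-%.3f", min(f), max(f)), "\n")
})

#' SelectionScores: per-SNP haplotype-based selection statistics
#'
#' Table of unstandardized and frequency-bin standardized iHS, nSL and
#' iHH12 values per SNP site, plus the neutral-calibrated significance
#' thresholds once \code{\link{callSignificantScores}} has run.
#'
#' @slot scores data.frame with one row per scanned site.
#' @slot thresholds data.frame with one row per statistic (empty before
#'   significance calling).
#' @exportClass SelectionScores
setClass("SelectionScores",
  slots = c(scores = "data.frame", thresholds = "data.frame"))

#' @rdname SelectionScores-class
#' @param x,object a SelectionScores object.
#' @export
setGeneric("scoreTable", function(x) standardGeneric("scoreTable"))
#' @rdname SelectionScores-class
#' @export
setMethod("scoreTable", "SelectionScores", function(x) x@scores)

#' @rdname SelectionScores-class
#' @export
setGeneric("scoreThresholds", function(x) standardGeneric("scoreThresholds"))
#' @rdname SelectionScores-class
#' @export
setMethod("scoreThresholds", "SelectionScores", function(x) x@thresholds)

#' @rdname SelectionScores-class
#' @export
setMethod("show", "SelectionScores", function(object) {
  s <- object@scores
  cat("SelectionScores:", nrow(s), "sites\n")
  for (st in c("ihs", "nsl", "ihh12")) {
    col <- paste0("std_", st)
    if (col %in% names(s))
      cat(sprintf("  %s: %d standardized", st, sum(!is.na(s[[col]]))))
    fl <- paste0("sig_", st)
    if (fl %in% names(s))
      cat(sprintf(", %d significant", sum(s[[fl]], na.rm = TRUE)))
    cat("\n")
  }
  if (nrow(object@thresholds))
    cat("  neutral-calibrated thresholds attached\n")
})
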