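#' Pipeline parameters
#'
#' All thresholds used across the pipeline, each defaulting to the value
#' used in the original study design, overridable individually or from a
#' YAML configuration file. Units are given per field.
#'
#' @param ... named overrides of any default listed below.
#' @return A named list of parameters:
#' \describe{
#'   \item{rareBelow}{frequency below which an insertion is rare (0.10).}
#'   \item{fixedAbove}{frequency above which an insertion is fixed (0.95).}
#'   \item{minCopyLen}{annotation post-filter: copies shorter than this
#'     (bp) are removed (100).}
#'   \item{maxSatOverlap}{annotation post-filter: copies with more than
#'     this fraction of their length under satellite annotation are
#'     removed (0.8).}
#'   \item{groupMinLen}{ortholog-group filter: a group is kept only when
#'     more than half of its members exceed this length in bp (120).}
#'   \item{reciprocalCov}{minimum reciprocal breadth of coverage when two
#'     annotation sets are compared (0.95).}
#'   \item{flankBp}{flank length used for coordinate transfer (1000).}
#'   \item{positionTolerance}{bp tolerance for clustering transferred
#'     insertions into ortholog groups (100).}
#'   \item{gapTolerance}{bp tolerance on the reference gap between the two
#'     placed flanks of a reliable transfer (50).}
#'   \item{ehhCutoff}{EHH value at which outward integration stops (0.05).}
#'   \item{nBins}{derived-frequency bins used to standardize selection
#'     statistics per chromosome (10).}
#'   \item{mafFloor}{minimum derived-allele frequency at which selection
#'     statistics are computed (0.05).}
#'   \item{neutralPercentile}{percentile of the neutral-site distribution
#'     that defines significance (95).}
#'   \item{intronMaxLen}{maximum length (bp) of a "small" intron whose
#'     start supplies neutral calibration SNPs (65).}
#'   \item{intronOffsets}{1-based offset range inside qualifying introns
#'     whose SNPs are considered neutral (8-30).}
#'   \item{pairWindow}{maximum SNP-TE distance in bp for sweep pairing;
#'     strictly less than (1000).}
#'   \item{cisWindow}{bp window around a gene for cis-eQTL search (1000).}
#'   \item{excludedFamilies}{families removed from the adaptive-candidate
#'     pool because they are old enough to reach high frequency neutrally
#'     (INE-1, LARD).}
#'   \item{rarefactionReps}{random subsets drawn per genome count (30).}
#'   \item{rarefactionKmin}{smallest genome count in rarefaction (5).}
#'   \item{nPerm}{permutations in the eQTL permutation pass (100000).}
#'   \item{alpha}{adjusted-p cutoff for significant associations (0.05).}
#' }
#' @export
#' @examples
#' p <- teParams(flankBp = 500)
#' p$rareBelow
teParams <- function(...) {
  p <- list(
    rareBelow = 0.10,
    fixedAbove = 0.95,
    minCopyLen = 100,
    maxSatOverlap = 0.8,
    groupMinLen = 120,
    reciprocalCov = 0.95,
    flankBp = 1000,
    positionTolerance = 100,
    gapTolerance = 50,
    ehhCutoff = 0.05,
    nBins = 10,
    mafFloor = 0.05,
    neutralPercentile = 95,
    intronMaxLen = 65,
    intronOffsets = c(8, 30),
    pairWindow = 1000,
    cisWindow = 1000,
    excludedFamilies = c("INE-1", "LARD"),
    rarefactionReps = 30,
    rarefactionKmin = 5,
    nPerm = 100000,
    alpha = 0.05
  )
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    p[names(over)] <- over
  }
  p
}

#' Read pipeline parameters from a YAML file
#'
#' Keys absent from the file keep their \code{\link{teParams}} default.
#'
#' @param path path to a YAML file of parameter overrides.
#' @return A parameter list as from \code{\link{teParams}}.
#' @export
readParams <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read configuration files")
  over <- yaml::read_yaml(path)
  do.call(teParams, over)
}
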