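#' Reported candidate adaptive TE insertions
#'
#' The packaged table of the 18 high-frequency, high-recombination TE
#' insertions with haplotype-based evidence of selection reported for
#' out-of-Africa D. melanogaster cohorts (id format
#' \code{chrom_start_end_family}), with the triggering statistic,
#' population frequency, nearby gene(s) and gene-body location.
#'
#' @return data.frame with columns \code{te_id}, \code{statistic},
#'   \code{frequency}, \code{gene_symbol}, \code{te_location}.
#' @export
candidateAdaptiveTes <- function() {
  read.delim(system.file("extdata", "candidate_adaptive_tes.tsv",
                         package = "TEpopgen", mustWork = TRUE),
             stringsAsFactors = FALSE)
}

#' Merge a new candidate list with previously reported sets
#'
#' Bookkeeping for the cumulative species-wide candidate catalogue: the
#' new candidate ids are deduplicated, ids already present in earlier
#' catalogues are dropped, and the remaining earlier sets are added by
#' their counts (their full id lists are external).
#'
#' @param newIds character vector of candidate group ids.
#' @param priorCounts integer counts of previously reported candidate
#'   sets disjoint from \code{newIds}; defaults to the two published
#'   D. melanogaster screens (84 and 5 insertions).
#' @param knownPriorIds optional character vector of earlier ids, used
#'   to drop duplicates from \code{newIds}.
#' @return list with \code{nNew}, \code{nPrior}, \code{total}.
#' @export
mergeCandidateCatalogue <- function(newIds, priorCounts = c(84, 5),
                                    knownPriorIds = character(0)) {
  newIds <- setdiff(unique(newIds), knownPriorIds)
  list(nNew = length(newIds), nPrior = sum(priorCounts),
       total = length(newIds) + sum(priorCounts))
}
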