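#' GeneModels: protein-coding gene annotation restricted to the longest
#' transcript
#'
#' Gene context of a TE insertion (promoter, UTRs, CDS, intron) is resolved
#' on the longest transcript of each gene, so the class keeps the gene
#' spans plus the exon-level features of that single transcript.
#'
#' @slot genes GRanges of gene spans with metadata columns \code{gene_id}
#'   and \code{tss} (transcription start site, 1-based bp).
#' @slot features GRanges with metadata columns \code{gene_id} and
#'   \code{type} (five_prime_UTR, CDS, intron, three_prime_UTR), longest
#'   transcript only.
#' @exportClass GeneModels
setClass("GeneModels",
  slots = c(genes = "GRanges", features = "GRanges"))

setValidity("GeneModels", function(object) {
  msg <- character(0)
  if (!"gene_id" %in% names(S4Vectors::mcols(object@genes)))
    msg <- c(msg, "genes needs a gene_id column")
  if (length(object@features) &&
      !all(c("gene_id", "type") %in%
           names(S4Vectors::mcols(object@features))))
    msg <- c(msg, "features need gene_id and type columns")
  if (any(!as.character(GenomicRanges::strand(object@genes)) %in%
          c("+", "-")))
    msg <- c(msg, "gene strand must be + or -")
  if (length(msg)) msg else TRUE
})

#' @rdname GeneModels-class
#' @param x,object a GeneModels object.
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))
#' @rdname GeneModels-class
#' @export
setMethod("genes", "GeneModels", function(x) x@genes)

#' @rdname GeneModels-class
#' @export
setGeneric("geneFeatures", function(x) standardGeneric("geneFeatures"))
#' @rdname GeneModels-class
#' @export
setMethod("geneFeatures", "GeneModels", function(x) x@features)

#' @rdname GeneModels-class
#' @export
setMethod("show", "GeneModels", function(object) {
  cat("GeneModels:", length(object@genes), "genes,",
      length(object@features), "longest-transcript features\n")
})

#' Introns of the longest transcripts
#'
#' @param x a \linkS4class{GeneModels} object.
#' @return GRanges of intron intervals with strand and \code{gene_id}.
#' @export
intronsOf <- function(x) {
  f <- geneFeatures(x)
  f[f$type == "intron"]
}

#' Read gene models from a GFF3 file
#'
#' Parses gene, mRNA and exon-level features (exon, CDS, five_prime_UTR,
#' three_prime_UTR), selects the longest transcript of each gene (largest
#' summed exon length; transcript span breaks ties) and derives introns as
#' the gaps between its exons. Only protein-coding-style models (a gene
#' with at least one mRNA child) are retained.
#'
#' @param path path to the GFF3 file.
#' @return A \linkS4class{GeneModels} object.
#' @export
readGeneModels <- function(path) {
  gff <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gff$type)
  gid <- gff$ID
  g <- gff[typ == "gene"]
  tx <- gff[typ %in% c("mRNA", "transcript")]
  if (!length(g) || !length(tx)) stop("no gene/mRNA features in ", path)
  parentOf <- function(x) vapply(x$Parent, function(p)
    if (length(p)) p[[1L]] else NA_character_, "")
  tx_parent <- parentOf(tx)
  ex <- gff[typ %in% c("exon", "CDS", "five_prime_UTR", "three_prime_UTR")]
  ex_parent <- parentOf(ex)

  genes_gr <- GenomicRanges::GRanges()
  feats <- list()
  for (i in seq_along(g)) {
    gene_id <- g$ID[i]
    mine <- tx[tx_parent == gene_id]
    if (!length(mine)) next
    # longest transcript = largest summed exon width
    exlen <- vapply(mine$ID, function(tid) {
      e <- ex[ex_parent == tid]
      e <- e[as.character(e$type) == "exon"]
      if (length(e)) sum(GenomicRanges::width(e))
      else GenomicRanges::width(mine[mine$ID == tid])
    }, 0)
    best <- mine$ID[which.max(exlen)]
    keepf <- ex[ex_parent == best]
    strand_g <- as.character(GenomicRanges::strand(g[i]))
    exons <- keepf[as.character(keepf$type) == "exon"]
    introns <- GenomicRanges::GRanges()
    if (length(exons) > 1) {
      exon_r <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(exons)[1L],
        IRanges::ranges(exons))
      span <- range(exon_r)
      introns <- GenomicRanges::setdiff(span, exon_r)
    }
    tab <- function(gr, type) {
      if (!length(gr)) return(NULL)
      GenomicRanges::GRanges(
        GenomicRanges::seqnames(gr),
        IRanges::ranges(gr), strand = strand_g,
        gene_id = gene_id, type = type)
    }
    fl <- c(lapply(c("five_prime_UTR", "CDS", "three_prime_UTR"),
                   function(tp)
                     tab(keepf[as.character(keepf$type) == tp], tp)),
            list(tab(introns, "intron")))
    feats[[gene_id]] <- do.call(c, fl[!vapply(fl, is.null, TRUE)])
    tss <- if (strand_g == "+") GenomicRanges::start(g[i])
           else GenomicRanges::end(g[i])
    gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(g[i]),
                                 IRanges::ranges(g[i]),
                                 strand = strand_g,
                                 gene_id = gene_id, tss = tss)
    genes_gr <- c(genes_gr, gr)
  }
  feats <- feats[!vapply(feats, is.null, TRUE)]
  features <- if (length(feats)) do.call(c, unname(feats))
              else GenomicRanges::GRanges(gene_id = character(0),
                                          type = character(0))
  new("GeneModels", genes = genes_gr, features = features)
}

#' Build a GeneModels object in code
#'
#' Convenience constructor used by the synthetic-cohort generator and by
#' tests: one transcript per gene, exons given directly, introns derived.
#'
#' @param genes data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end} (1-based, closed, as in GFF), \code{strand}.
#' @param exons data.frame with columns \code{gene_id}, \code{start},
#'   \code{end}; when NULL each gene is a single exon.
#' @return A \linkS4class{GeneModels} object.
#' @export
makeGeneModels <- function(genes, exons = NULL) {
  gr <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start, genes$end),
                               strand = genes$strand,
                               gene_id = genes$gene_id,
                               tss = ifelse(genes$strand == "+",
                                            genes$start, genes$end))
  feats <- GenomicRanges::GRanges()
  if (!is.null(exons)) {
    for (gid in unique(exons$gene_id)) {
      e <- exons[exons$gene_id == gid, ]
      e <- e[order(e$start), ]
      gi <- genes[genes$gene_id == gid, ]
      if (nrow(e) > 1) {
        istart <- e$end[-nrow(e)] + 1
        iend <- e$start[-1] - 1
        ok <- iend >= istart
        if (any(ok))
          feats <- c(feats, GenomicRanges::GRanges(
            gi$chrom, IRanges::IRanges(istart[ok], iend[ok]),
            strand = gi$strand, gene_id = gid, type = "intron"))
      }
      feats <- c(feats, GenomicRanges::GRanges(
        gi$chrom, IRanges::IRanges(e$start, e$end),
        strand = gi$strand, gene_id = gid, type = "CDS"))
    }
  }
  new("GeneModels", genes = gr, features = feats)
}

#' Write gene models as GFF3
#'
#' One gene + one mRNA + exon/CDS features per gene, reconstructing exons
#' as the complement of the stored introns within the gene span.
#'
#' @param gm a \linkS4class{GeneModels} object.
#' @param path output path.
#' @export
writeGeneModels <- function(gm, path) {
  g <- genes(gm)
  f <- geneFeatures(gm)
  lines <- c("##gff-version 3")
  for (i in seq_along(g)) {
    gid <- g$gene_id[i]
    ch <- as.character(GenomicRanges::seqnames(g[i]))
    st <- as.character(GenomicRanges::strand(g[i]))
    s <- GenomicRanges::start(g[i]); e <- GenomicRanges::end(g[i])
    tid <- paste0(gid, ".t1")
    lines <- c(lines,
      paste(ch, "TEpopgen", "gene", s, e, ".", st, ".",
            paste0("ID=", gid), sep = "\t"),
      paste(ch, "TEpopgen", "mRNA", s, e, ".", st, ".",
            paste0("ID=", tid, ";Parent=", gid), sep = "\t"))
    intr <- f[f$gene_id == gid & f$type == "intron"]
    # exons = gene span minus introns
    span <- GenomicRanges::GRanges(ch, IRanges::IRanges(s, e))
    exons <- if (length(intr)) GenomicRanges::setdiff(span,
               GenomicRanges::GRanges(ch, IRanges::ranges(intr)))
             else span
    for (j in seq_along(exons)) {
      es <- GenomicRanges::start(exons[j])
      ee <- GenomicRanges::end(exons[j])
      lines <- c(lines,
        paste(ch, "TEpopgen", "exon", es, ee, ".", st, ".",
              paste0("Parent=", tid), sep = "\t"),
        paste(ch, "TEpopgen", "CDS", es, ee, ".", st, ".",
              paste0("Parent=", tid), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
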