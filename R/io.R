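#' Read per-strain TE annotations from a BED file
#'
#' Accepts BED3-BED6 (0-based, half-open). The name column (4) carries the
#' TE family, the score column (5) the percent identity of the copy to the
#' family consensus (use "." when unknown), and column 6 the strand.
#' Malformed lines are reported with their line numbers.
#'
#' @param path path to the BED file.
#' @param strainId strain identifier attached to every record; defaults to
#'   the file name without extension.
#' @param hierarchy optional family hierarchy table as returned by
#'   \code{\link{teHierarchy}}, used to resolve superfamily and order.
#' @return data.frame with columns \code{strain}, \code{chrom},
#'   \code{start}, \code{end}, \code{family}, \code{identity},
#'   \code{strand}, \code{length}, \code{superfamily}, \code{order}.
#' @export
readTeBed <- function(path, strainId = NULL, hierarchy = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(strainId))
    strainId <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(data.frame(strain = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      family = character(0), identity = numeric(0),
                      strand = character(0), length = numeric(0),
                      superfamily = character(0), order = character(0)))
  }
  fields <- strsplit(lines, "\t")
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("BED line ", lineno[which(nf < 3)[1]],
         ": fewer than 3 columns")
  get <- function(i, default = NA_character_)
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, "")
  start <- suppressWarnings(as.numeric(get(2)))
  end <- suppressWarnings(as.numeric(get(3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("BED line ", lineno[bad[1]], ": non-numeric coordinates")
  bad <- which(start < 0 | end < 0)
  if (length(bad))
    stop("BED line ", lineno[bad[1]], ": negative coordinates")
  bad <- which(end <= start)
  if (length(bad))
    stop("BED line ", lineno[bad[1]], ": end <= start")
  fam <- get(4)
  fam[is.na(fam) | fam == "."] <- "unknown"
  idn <- suppressWarnings(as.numeric(get(5)))
  strand <- get(6)
  strand[is.na(strand) | !strand %in% c("+", "-")] <- "."
  out <- data.frame(strain = strainId, chrom = get(1),
                    start = start, end = end, family = fam,
                    identity = idn, strand = strand,
                    length = end - start)
  if (is.null(hierarchy)) hierarchy <- teHierarchy()
  i <- match(out$family, hierarchy$family)
  out$superfamily <- ifelse(is.na(i), "unknown", hierarchy$superfamily[i])
  out$order <- ifelse(is.na(i), "other", hierarchy$order[i])
  out
}

#' Write TE annotation records as BED6
#'
#' @param records data.frame as returned by \code{\link{readTeBed}}.
#' @param path output path.
#' @export
writeTeBed <- function(records, path) {
  score <- ifelse(is.na(records$identity), ".",
                  as.character(records$identity))
  bed <- data.frame(records$chrom, format(records$start, scientific = FALSE,
                                          trim = TRUE),
                    format(records$end, scientific = FALSE, trim = TRUE),
                    records$family, score, records$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Family to superfamily to order lookup table
#'
#' Loads the packaged TE hierarchy (an editable TSV under
#' \code{inst/extdata}). Orders follow the five main groups observed in
#' Drosophila euchromatin (Helitron, LARD, LINE, LTR, TIR) plus "other".
#'
#' @param path optional path to a custom three-column TSV
#'   (family, superfamily, order).
#' @return data.frame with columns \code{family}, \code{superfamily},
#'   \code{order}.
#' @export
teHierarchy <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "te_hierarchy.tsv",
                        package = "TEpopgen", mustWork = TRUE)
  read.delim(path, header = TRUE, stringsAsFactors = FALSE)
}

#' Read phased haplotypes from a VCF file
#'
#' Keeps only biallelic SNP records and drops any record with missing
#' genotypes in at least one sample, mirroring the variant filtering a
#' haplotype scan requires (no multiallelic sites, no missing data).
#' Diploid genotypes must be phased ("|"); an unphased separator is an
#' error. Haploid genotypes ("0"/"1") yield one haplotype per sample, the
#' default interpretation for inbred or isofemale consensus genomes. The
#' REF allele maps to allele 0 (ancestral by default).
#'
#' @param path path to a VCF (plain or bgzipped).
#' @return A \linkS4class{HaplotypePanel}, or a named list of panels when
#'   the file covers several chromosomes.
#' @export
readPhasedVcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref1 <- nchar(as.character(rr$REF)) == 1L
  alt <- rr$ALT
  nalt <- lengths(alt)
  alt1 <- nalt == 1L &
    nchar(vapply(seq_along(alt), function(i)
      as.character(alt[[i]][1L]), "")) == 1L
  keep <- ref1 & alt1
  gt <- VariantAnnotation::geno(vcf)$GT
  gt <- gt[keep, , drop = FALSE]
  rr <- rr[keep]
  if (!nrow(gt)) stop("no biallelic SNP records in ", path)
  miss <- apply(gt, 1L, function(g) any(grepl("\\.", g)))
  gt <- gt[!miss, , drop = FALSE]
  rr <- rr[!miss]
  if (!nrow(gt)) stop("all sites have missing genotypes in ", path)
  if (any(grepl("/", gt)))
    stop("unphased diploid genotypes ('/') found; phase the VCF first")
  samples <- colnames(gt)
  diploid <- grepl("\\|", gt[1L])
  parse1 <- function(col) {
    if (diploid) {
      parts <- strsplit(col, "|", fixed = TRUE)
      rbind(as.integer(vapply(parts, `[`, "", 1L)),
            as.integer(vapply(parts, `[`, "", 2L)))
    } else {
      matrix(as.integer(col), nrow = 1L)
    }
  }
  chroms <- as.character(GenomicRanges::seqnames(rr))
  # haplotype rows arrive site-major: transpose sample columns into rows
  split_idx <- split(seq_along(chroms), chroms)
  panels <- lapply(split_idx, function(idx) {
    sub <- gt[idx, , drop = FALSE]
    mats <- lapply(seq_along(samples), function(j) parse1(sub[, j]))
    hap <- do.call(rbind, mats)
    strains <- rep(samples, each = if (diploid) 2L else 1L)
    o <- order(GenomicRanges::start(rr)[idx])
    HaplotypePanel(hap[, o, drop = FALSE],
                   positions = sort(GenomicRanges::start(rr)[idx]),
                   chrom = chroms[idx][1L], strains = strains)
  })
  if (length(panels) == 1L) panels[[1L]] else panels
}

#' Write a HaplotypePanel as a minimal phased VCF
#'
#' Strains with one haplotype are written as haploid GT ("0"/"1"); strains
#' with two haplotypes as phased diploid ("a|b"). Alleles are written as
#' placeholder A (REF, ancestral) / T (ALT, derived).
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param path output path.
#' @export
writePhasedVcf <- function(panel, path) {
  strains <- unique(panel@strains)
  hap <- panel@haplotypes
  gt_cols <- vapply(strains, function(s) {
    rows <- which(panel@strains == s)
    if (length(rows) == 1L) {
      as.character(hap[rows, ])
    } else if (length(rows) == 2L) {
      paste(hap[rows[1L], ], hap[rows[2L], ], sep = "|")
    } else stop("strain ", s, " has ", length(rows), " haplotypes")
  }, character(ncol(hap)))
  if (ncol(hap) == 1L) gt_cols <- matrix(gt_cols, nrow = 1L)
  header <- c("##fileformat=VCFv4.2",
              "##source=TEpopgen",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                      "FILTER", "INFO", "FORMAT", strains),
                    collapse = "\t"))
  body <- vapply(seq_len(ncol(hap)), function(i) {
    paste(c(panel@chrom, format(panel@positions[i], scientific = FALSE),
            paste0("snp", i), "A", "T", ".", "PASS", ".", "GT",
            gt_cols[i, ]), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a recombination map
#'
#' Expects a tab-delimited file with columns \code{chrom}, \code{start},
#' \code{end} (bp, 0-based half-open windows) and \code{rate} (cM/Mb).
#' Windows must be sorted and non-overlapping per chromosome.
#'
#' @param path path to the TSV file.
#' @return data.frame with the four columns, validated.
#' @export
readRecombMap <- function(path) {
  m <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "rate")
  if (!all(need %in% names(m)))
    stop("recombination map needs columns: ", paste(need, collapse = ", "))
  validateRecombMap(m)
}

validateRecombMap <- function(m) {
  if (any(m$rate < 0)) stop("negative recombination rate")
  for (ch in unique(m$chrom)) {
    w <- m[m$chrom == ch, ]
    w <- w[order(w$start), ]
    if (any(w$end <= w$start)) stop("empty map window on ", ch)
    if (nrow(w) > 1 && any(w$start[-1] < w$end[-nrow(w)]))
      stop("overlapping map windows on ", ch)
  }
  m[order(m$chrom, m$start), ]
}

#' Genetic position from a recombination map
#'
#' Cumulative integral of the local rate (cM/Mb) over physical distance
#' from the start of the mapped span of the chromosome; monotone
#' non-decreasing in position.
#'
#' @param map recombination map data.frame
#'   (\code{chrom,start,end,rate}).
#' @param chrom chromosome name.
#' @param pos physical position(s) in bp; must fall within the mapped span.
#' @return numeric vector of genetic positions in cM.
#' @export
#' @examples
#' m <- data.frame(chrom = "2L", start = c(0, 1e6), end = c(1e6, 2e6),
#'                 rate = c(1, 3))
#' geneticPosition(m, "2L", 1.5e6)  # 2.5 cM
geneticPosition <- function(map, chrom, pos) {
  w <- map[map$chrom == chrom, ]
  if (!nrow(w)) stop("chromosome ", chrom, " not in map")
  w <- w[order(w$start), ]
  if (any(pos < min(w$start) | pos > max(w$end)))
    stop("position outside mapped span on ", chrom)
  cum <- c(0, cumsum(w$rate * (w$end - w$start) / 1e6))
  idx <- findInterval(pos, w$start)
  cum[idx] + w$rate[idx] * (pos - w$start[idx]) / 1e6
}

#' Recombination rate at positions
#'
#' Rate (cM/Mb) of the map window containing each position; NA outside the
#' mapped span.
#'
#' @inheritParams geneticPosition
#' @return numeric vector of rates.
#' @export
recombRateAt <- function(map, chrom, pos) {
  w <- map[map$chrom == chrom, ]
  if (!nrow(w)) return(rep(NA_real_, length(pos)))
  w <- w[order(w$start), ]
  idx <- findInterval(pos, w$start)
  out <- rep(NA_real_, length(pos))
  ok <- idx >= 1 & idx <= nrow(w)
  ok[ok] <- pos[ok] < w$end[idx[ok]] | pos[ok] == w$end[nrow(w)]
  out[ok] <- w$rate[idx[ok]]
  out
}

#' Read a normalized expression matrix
#'
#' Tab-delimited, genes in rows (first column = gene id), strains in
#' columns.
#'
#' @param path path to the TSV file.
#' @return numeric matrix, genes x strains.
#' @export
readExpressionMatrix <- function(path) {
  df <- read.delim(path, header = TRUE, row.names = 1,
                   check.names = FALSE)
  as.matrix(df)
}

#' Write an expression matrix as TSV
#'
#' @param mat numeric matrix, genes x strains.
#' @param path output path.
#' @export
writeExpressionMatrix <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read minimap2-style PAF alignments
#'
#' Parses the 12 mandatory PAF columns; extra tags are ignored.
#'
#' @param path path to the PAF file.
#' @return data.frame with columns \code{qname,qlen,qstart,qend,strand,
#'   tname,tlen,tstart,tend,nmatch,alnlen,mapq}.
#' @export
readPaf <- function(path) {
  cols <- c("qname", "qlen", "qstart", "qend", "strand", "tname",
            "tlen", "tstart", "tend", "nmatch", "alnlen", "mapq")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(as.data.frame(setNames(rep(list(character(0)), 12), cols)))
  fields <- strsplit(lines, "\t")
  if (any(lengths(fields) < 12)) stop("PAF line with fewer than 12 columns")
  df <- as.data.frame(do.call(rbind, lapply(fields, `[`, 1:12)),
                      stringsAsFactors = FALSE)
  names(df) <- cols
  for (nm in c("qlen", "qstart", "qend", "tlen", "tstart", "tend",
               "nmatch", "alnlen", "mapq"))
    df[[nm]] <- as.numeric(df[[nm]])
  df
}

#' Write a presence matrix as TSV
#'
#' One row per ortholog group (id, coordinates, family, frequency) followed
#' by one 0/1 column per strain.
#'
#' @param pm a \linkS4class{PresenceMatrix}.
#' @param path output path.
#' @export
writePresenceMatrix <- function(pm, path) {
  li <- lociInfo(pm)
  p <- presence(pm)
  df <- data.frame(li[, c("group_id", "chrom", "start", "end", "family")],
                   frequency = colMeans(p),
                   t(p) * 1L, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a presence matrix written by \code{writePresenceMatrix}
#'
#' @param path path to the TSV file.
#' @param strainInfo optional strain metadata data.frame.
#' @return A \linkS4class{PresenceMatrix}.
#' @export
readPresenceMatrix <- function(path, strainInfo = NULL) {
  df <- read.delim(path, header = TRUE, check.names = FALSE)
  meta <- c("group_id", "chrom", "start", "end", "family", "frequency")
  strains <- setdiff(names(df), meta)
  p <- t(as.matrix(df[, strains, drop = FALSE])) == 1
  colnames(p) <- df$group_id
  rownames(p) <- strains
  PresenceMatrix(p, strainInfo = strainInfo,
                 lociInfo = data.frame(df[, meta[1:5]],
                                       row.names = df$group_id))
}
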