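#' Candidate cis TE-gene pairs
#'
#' Pairs each gene with the TE insertions whose interval intersects the
#' window \code{[gene start - window, gene end + window]} (window
#' anchored on the gene span, since associations are sought "around" the
#' gene, introns included).
#'
#' @param gm a \linkS4class{GeneModels}.
#' @param loci data.frame of TE loci (\code{group_id,chrom,start,end},
#'   0-based half-open), e.g. \code{lociInfo(pm)}.
#' @param window cis window in bp.
#' @return named list: gene_id -> character vector of group ids.
#' @export
buildCisPairs <- function(gm, loci, window = 1000) {
  g <- genes(gm)
  teGr <- GenomicRanges::GRanges(loci$chrom,
                                 IRanges::IRanges(loci$start + 1,
                                                  pmax(loci$end,
                                                       loci$start + 1)))
  win <- GenomicRanges::resize(g, GenomicRanges::width(g) + 2 * window,
                               fix = "center")
  ov <- GenomicRanges::findOverlaps(win, teGr, ignore.strand = TRUE)
  out <- split(loci$group_id[S4Vectors::subjectHits(ov)],
               g$gene_id[S4Vectors::queryHits(ov)])
  lapply(out, unique)
}

residualize <- function(y, covariates) {
  if (is.null(covariates)) return(y - mean(y))
  X <- cbind(1, as.matrix(covariates))
  qr.resid(qr(X), y)
}

#' Nominal association of TE presence with gene expression
#'
#' Expression and genotype are residualized on the covariates, then
#' Pearson-correlated; the p-value uses the exact t transform with the
#' degrees of freedom reduced by the covariate count.
#'
#' @param genotype numeric/logical per-strain TE presence (not constant).
#' @param expression numeric per-strain expression.
#' @param covariates optional matrix/data.frame of per-strain covariates
#'   (e.g. population-structure axes).
#' @return list with \code{r}, \code{slope}, \code{df}, \code{p}.
#' @export
nominalAssociation <- function(genotype, expression, covariates = NULL) {
  g <- as.numeric(genotype)
  e <- as.numeric(expression)
  n <- length(g)
  if (n < 6) stop("need at least 6 strains")
  if (length(e) != n) stop("genotype/expression length mismatch")
  if (sd(g) == 0) stop("constant genotype")
  if (sd(e) == 0) stop("constant expression")
  k <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  gr <- residualize(g, covariates)
  er <- residualize(e, covariates)
  if (sd(gr) == 0 || sd(er) == 0)
    stop("genotype or expression constant after covariate adjustment")
  r <- sum(gr * er) / sqrt(sum(gr^2) * sum(er^2))
  df <- n - 2L - k
  r2 <- min(r^2, 1 - 1e-15)
  tstat <- r * sqrt(df / (1 - r2))
  p <- 2 * stats::pt(-abs(tstat), df)
  list(r = r, slope = sum(gr * er) / sum(gr^2), df = df,
       p = max(p, .Machine$double.xmin))
}

# ML fit of a Beta(a, b) to permutation minima, method-of-moments init
fitBetaML <- function(x) {
  eps <- 1e-12
  x <- pmin(pmax(x, eps), 1 - eps)
  m <- mean(x); v <- var(x)
  if (v <= 0) return(NULL)
  common <- m * (1 - m) / v - 1
  init <- c(max(m * common, 1e-2), max((1 - m) * common, 1e-2))
  nll <- function(par) {
    if (any(par <= 0)) return(Inf)
    -sum(stats::dbeta(x, par[1L], par[2L], log = TRUE))
  }
  fit <- tryCatch(
    stats::optim(init, nll, method = "L-BFGS-B",
                 lower = c(1e-4, 1e-4), upper = c(1e6, 1e6)),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$value)) {
    # fall back to the moments estimate
    if (all(is.finite(init)) && all(init > 0))
      return(list(a = init[1L], b = init[2L], method = "moments"))
    return(NULL)
  }
  list(a = fit$par[1L], b = fit$par[2L], method = "mle")
}

#' Permutation pass with beta approximation for one gene
#'
#' For each permutation the expression values are shuffled across strains
#' and the smallest nominal p over the gene's cis TEs is recorded; a
#' Beta(a, b) is fitted to these permutation minima by maximum
#' likelihood (method-of-moments start) and the adjusted p is the fitted
#' Beta CDF evaluated at the observed best nominal p. All TEs tied at
#' the best nominal p are reported as top variants.
#'
#' @param expression numeric per-strain expression for the gene.
#' @param genotypes matrix strains x cis TEs of presence (column names =
#'   group ids).
#' @param covariates optional per-strain covariates.
#' @param nPerm number of permutations (>= 100; the beta fit is unstable
#'   below that).
#' @param seed RNG seed.
#' @return list: \code{topTes}, \code{nominalP}, \code{direction},
#'   \code{betaA}, \code{betaB}, \code{adjustedP}, \code{empiricalP},
#'   \code{nPerm}, \code{fit} ("mle", "moments" or "empirical").
#' @export
permutationPass <- function(expression, genotypes, covariates = NULL,
                            nPerm = 1000, seed = 1L) {
  if (nPerm < 100)
    stop("nPerm must be >= 100: the beta approximation is unstable ",
         "below that")
  genotypes <- as.matrix(genotypes) * 1
  n <- length(expression)
  keep <- apply(genotypes, 2L, sd) > 0
  if (!any(keep)) stop("all cis genotypes constant")
  genotypes <- genotypes[, keep, drop = FALSE]
  k <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  df <- n - 2L - k
  G <- apply(genotypes, 2L, residualize, covariates = covariates)
  Gn <- sweep(G, 2L, sqrt(colSums(G^2)), "/")
  er <- residualize(expression, covariates)
  en <- er / sqrt(sum(er^2))
  pFromR <- function(r) {
    r2 <- pmin(r^2, 1 - 1e-15)
    t <- abs(r) * sqrt(df / (1 - r2))
    pmax(2 * stats::pt(-t, df), .Machine$double.xmin)
  }
  obsP <- pFromR(drop(crossprod(Gn, en)))
  best <- min(obsP)
  topTes <- colnames(genotypes)[obsP <= best * (1 + 1e-9)]
  set.seed(seed)
  permP <- numeric(nPerm)
  for (b in seq_len(nPerm)) {
    ep <- en[sample.int(n)]
    # re-centre: permutation can break orthogonality to the covariates
    epr <- residualize(ep, covariates)
    epr <- epr / sqrt(sum(epr^2))
    permP[b] <- min(pFromR(drop(crossprod(Gn, epr))))
  }
  empiricalP <- (1 + sum(permP <= best)) / (nPerm + 1)
  fit <- fitBetaML(permP)
  if (is.null(fit)) {
    warning("degenerate beta fit; reporting empirical rank p")
    adj <- empiricalP
    a <- b <- NA_real_
    method <- "empirical"
  } else {
    adj <- stats::pbeta(best, fit$a, fit$b)
    a <- fit$a; b <- fit$b
    method <- fit$method
  }
  carrier <- genotypes[, topTes[1L]] > 0
  direction <- if (mean(expression[carrier]) >=
                   mean(expression[!carrier])) "up" else "down"
  list(topTes = topTes, nominalP = best, direction = direction,
       betaA = a, betaB = b, adjustedP = adj,
       empiricalP = empiricalP, nPerm = nPerm, fit = method)
}

#' Population-structure covariates from the presence matrix
#'
#' First principal components of the (centred) TE presence matrix, the
#' default stand-in for population structure when no external covariates
#' are supplied.
#'
#' @param pm a \linkS4class{PresenceMatrix}.
#' @param nPCs number of components.
#' @return matrix strains x nPCs.
#' @export
presencePCs <- function(pm, nPCs = 2) {
  p <- presence(pm) * 1
  p <- p[, apply(p, 2L, sd) > 0, drop = FALSE]
  pc <- stats::prcomp(p, center = TRUE, scale. = FALSE)
  pc$x[, seq_len(min(nPCs, ncol(pc$x))), drop = FALSE]
}

#' Full cis-eQTL pass over an expression matrix
#'
#' Runs the nominal and permutation passes for every gene with at least
#' one cis TE and returns one row per (gene, top TE), with ties at the
#' best nominal p all reported.
#'
#' @param expr numeric matrix genes x strains (normalized expression).
#' @param pm a \linkS4class{PresenceMatrix} (same strains).
#' @param gm a \linkS4class{GeneModels} for the genes of \code{expr}.
#' @param window cis window (bp).
#' @param covariates per-strain covariate matrix, or "auto" for the
#'   first two presence-matrix PCs, or NULL for none.
#' @param nPerm permutations per gene.
#' @param seed RNG seed (a per-gene seed is derived from it).
#' @return data.frame: gene_id, group_id, n_cis, r, nominal_p, direction,
#'   beta_a, beta_b, adjusted_p, empirical_p, tied.
#' @export
teEqtl <- function(expr, pm, gm, window = 1000, covariates = "auto",
                   nPerm = 1000, seed = 1L) {
  p <- presence(pm)
  strains <- colnames(expr)
  if (!all(strains %in% rownames(p)))
    stop("expression strains missing from presence matrix")
  p <- p[strains, , drop = FALSE]
  if (identical(covariates, "auto"))
    covariates <- presencePCs(PresenceMatrix(p), 2)
  pairs <- buildCisPairs(gm, lociInfo(pm), window)
  out <- list()
  gene_ids <- intersect(rownames(expr), names(pairs))
  for (gi in seq_along(gene_ids)) {
    gid <- gene_ids[gi]
    tes <- pairs[[gid]]
    G <- p[, tes, drop = FALSE]
    G <- G[, apply(G, 2L, function(x) sd(as.numeric(x)) > 0),
           drop = FALSE]
    if (!ncol(G)) next
    pp <- permutationPass(expr[gid, ], G, covariates, nPerm,
                          seed = seed + gi)
    nom <- nominalAssociation(p[, pp$topTes[1L]], expr[gid, ],
                              covariates)
    out[[gid]] <- data.frame(
      gene_id = gid, group_id = pp$topTes, n_cis = ncol(G),
      r = nom$r, nominal_p = pp$nominalP, direction = pp$direction,
      beta_a = pp$betaA, beta_b = pp$betaB, adjusted_p = pp$adjustedP,
      empirical_p = pp$empiricalP, tied = length(pp$topTes) > 1)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Significant cis-eQTL associations
#'
#' Keeps associations with adjusted p strictly below \code{alpha} whose
#' TE lies in a region of strictly positive recombination (insertions in
#' non-recombining regions are more likely hitchhikers than causal).
#'
#' @param results data.frame from \code{\link{teEqtl}}.
#' @param pm the \linkS4class{PresenceMatrix} used (for TE coordinates).
#' @param recombMap recombination map; NULL skips the recombination
#'   filter.
#' @param alpha adjusted-p cutoff (strict).
#' @return the filtered data.frame, with a \code{recomb_rate} column.
#' @export
callSignificantEqtl <- function(results, pm, recombMap = NULL,
                                alpha = 0.05) {
  if (!nrow(results)) return(results)
  keep <- results$adjusted_p < alpha
  li <- lociInfo(pm)
  i <- match(results$group_id, li$group_id)
  if (!is.null(recombMap)) {
    rate <- vapply(seq_along(i), function(j) {
      if (is.na(i[j])) return(NA_real_)
      recombRateAt(recombMap, li$chrom[i[j]],
                   (li$start[i[j]] + li$end[i[j]]) / 2)
    }, 0)
    results$recomb_rate <- rate
    keep <- keep & !is.na(rate) & rate > 0
  }
  results[keep, , drop = FALSE]
}
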