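# Independent brute-force oracles for the extended-haplotype statistics.
# Everything here recomputes identity from scratch with string keys and
# explicit pair enumeration (O(n^2 * m)); nothing is shared with the
# package's partition-refinement implementation.

# fraction of carrier pairs identical over the sites from the core out to
# column j (inclusive)
bruteEhhAt <- function(hap, rows, core, j) {
  cols <- if (j >= core) core:j else j:core
  keys <- apply(hap[rows, cols, drop = FALSE], 1L, paste, collapse = "")
  sz <- table(keys)
  n <- length(rows)
  sum(choose(sz, 2)) / choose(n, 2)
}

# EHH12 over all haplotypes, two largest classes pooled, at column j
bruteEhh12At <- function(hap, core, j) {
  cols <- if (j >= core) core:j else j:core
  keys <- apply(hap[, cols, drop = FALSE], 1L, paste, collapse = "")
  sz <- sort(as.integer(table(keys)), decreasing = TRUE)
  n <- nrow(hap)
  top <- sum(sz[seq_len(min(2, length(sz)))])
  rest <- if (length(sz) > 2) sz[-(1:2)] else integer(0)
  (choose(top, 2) + sum(choose(rest, 2))) / choose(n, 2)
}

# trapezoid with the truncation rule: include up to and including the
# first point with EHH < cutoff; flag truncation at the chromosome end
bruteIntegrate <- function(dists, ehhs, cutoff) {
  x <- c(0, dists)
  y <- c(1, ehhs)
  below <- which(y < cutoff)
  truncated <- FALSE
  if (length(below)) {
    x <- x[seq_len(below[1L])]
    y <- y[seq_len(below[1L])]
  } else truncated <- TRUE
  v <- 0
  if (length(x) > 1)
    for (i in seq_len(length(x) - 1L))
      v <- v + (x[i + 1L] - x[i]) * (y[i] + y[i + 1L]) / 2
  list(value = v, truncated = truncated)
}

bruteIhhAllele <- function(hap, pos, core, allele, cutoff) {
  rows <- which(hap[, core] == allele)
  m <- ncol(hap)
  side <- function(js) {
    if (!length(js)) return(list(value = 0, truncated = TRUE))
    ehhs <- vapply(js, function(j) bruteEhhAt(hap, rows, core, j), 0)
    dists <- abs(pos[js] - pos[core])
    keep <- seq_along(js)
    # stop the curve where the walk would have stopped (first < cutoff)
    firstBelow <- which(ehhs < cutoff)
    if (length(firstBelow))
      keep <- seq_len(firstBelow[1L])
    bruteIntegrate(dists[keep], ehhs[keep], cutoff)
  }
  L <- side(if (core > 1) (core - 1):1 else integer(0))
  R <- side(if (core < m) (core + 1):m else integer(0))
  list(value = L$value + R$value, truncated = L$truncated || R$truncated)
}

bruteIHS <- function(hap, pos, core, cutoff = 0.05, mafFloor = 0.05) {
  f <- mean(hap[, core])
  if (f < mafFloor || f > 1 - mafFloor) return(NA_real_)
  if (sum(hap[, core] == 1) < 2 || sum(hap[, core] == 0) < 2)
    return(NA_real_)
  A <- bruteIhhAllele(hap, pos, core, 0L, cutoff)
  D <- bruteIhhAllele(hap, pos, core, 1L, cutoff)
  if (A$truncated || D$truncated) return(NA_real_)
  if (A$value == 0 || D$value == 0) return(NA_real_)
  log(A$value / D$value)
}

# pairwise maximal identity interval in site units (core counts as 1)
bruteNSL <- function(hap, core, mafFloor = 0.05) {
  f <- mean(hap[, core])
  if (f < mafFloor || f > 1 - mafFloor) return(NA_real_)
  if (sum(hap[, core] == 1) < 2 || sum(hap[, core] == 0) < 2)
    return(NA_real_)
  m <- ncol(hap)
  slOf <- function(allele) {
    rows <- which(hap[, core] == allele)
    tot <- 0; np <- 0
    for (a in seq_along(rows)) for (b in seq_len(a - 1L)) {
      h1 <- hap[rows[a], ]; h2 <- hap[rows[b], ]
      L <- 1L
      j <- core - 1L
      while (j >= 1L && h1[j] == h2[j]) { L <- L + 1L; j <- j - 1L }
      j <- core + 1L
      while (j <= m && h1[j] == h2[j]) { L <- L + 1L; j <- j + 1L }
      tot <- tot + L; np <- np + 1L
    }
    tot / np
  }
  log(slOf(0L) / slOf(1L))
}

bruteIHH12 <- function(hap, pos, core, cutoff = 0.05, mafFloor = 0.05) {
  f <- mean(hap[, core])
  if (f < mafFloor || f > 1 - mafFloor) return(NA_real_)
  m <- ncol(hap)
  side <- function(js) {
    if (!length(js)) return(list(value = 0, truncated = TRUE))
    ehhs <- vapply(js, function(j) bruteEhh12At(hap, core, j), 0)
    dists <- abs(pos[js] - pos[core])
    firstBelow <- which(ehhs < cutoff)
    keep <- if (length(firstBelow)) seq_len(firstBelow[1L])
            else seq_along(js)
    bruteIntegrate(dists[keep], ehhs[keep], cutoff)
  }
  L <- side(if (core > 1) (core - 1):1 else integer(0))
  R <- side(if (core < m) (core + 1):m else integer(0))
  if (L$truncated || R$truncated) return(NA_real_)
  L$value + R$value
}

# small random panel with sorted positions; ensures the core column is
# polymorphic with at least 2 carriers of each allele when possible
randomPanel <- function(n, m, seed) {
  set.seed(seed)
  hap <- matrix(rbinom(n * m, 1, runif(1, 0.2, 0.8)), n, m)
  for (j in seq_len(m)) {          # keep every site polymorphic
    if (all(hap[, j] == hap[1, j]))
      hap[sample(n, 1), j] <- 1L - hap[1, j]
  }
  pos <- sort(sample(10 * m * 50, m))
  HaplotypePanel(hap, pos)
}
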