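suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

## Brute-force Poisson upper tail by direct series summation (independent of
## ppois/qpois): P(X >= k) = 1 - sum_{i<k} exp(-l) l^i / i!
bruteTail <- function(k, lambda) {
  if (k <= 0) return(1)
  i <- 0:(k - 1)
  1 - sum(exp(-lambda) * lambda^i / factorial(i))
}

bruteMinCount <- function(lambda, p) {
  k <- 1L
  while (bruteTail(k, lambda) >= p) k <- k + 1L
  k
}

## All-pairs oracle for TSS-window gene assignment: plain double loop.
bruteAssign <- function(regions, genes, window) {
  summit <- mcols(regions)$summit
  if (is.null(summit)) summit <- floor((start(regions) + end(regions)) / 2)
  n <- length(genes)
  nSites <- integer(n)
  minD <- rep(NA_real_, n)
  for (gi in seq_len(n)) {
    tss <- start(genes)[gi]
    sgn <- if (as.character(strand(genes))[gi] == "-") -1 else 1
    best <- Inf
    for (ri in seq_along(regions)) {
      if (as.character(seqnames(regions))[ri] !=
          as.character(seqnames(genes))[gi]) next
      d <- summit[ri] - tss
      if (abs(d) <= window) {
        nSites[gi] <- nSites[gi] + 1L
        if (abs(d) < abs(best)) best <- d * sgn
      }
    }
    if (nSites[gi] > 0L) minD[gi] <- best
  }
  data.frame(gene_id = mcols(genes)$gene_id, n_sites = nSites,
             min_tss_distance = minD, stringsAsFactors = FALSE)
}

## All-pairs oracle for summit-to-edge proximity distances.
bruteFractionWithin <- function(query, target, d) {
  qs <- mcols(query)$summit
  if (is.null(qs)) qs <- floor((start(query) + end(query)) / 2)
  nW <- 0L
  for (i in seq_along(query)) {
    best <- Inf
    for (j in seq_along(target)) {
      if (as.character(seqnames(query))[i] !=
          as.character(seqnames(target))[j]) next
      dd <- max(0, start(target)[j] - qs[i], qs[i] - end(target)[j])
      best <- min(best, dd)
    }
    if (best <= d) nW <- nW + 1L
  }
  nW / length(query)
}

## Exhaustive hypergeometric upper tail: enumerate every size-n subset of a
## size-N universe and count those holding >= k of the K category members.
bruteHyper <- function(N, K, n, k) {
  subsets <- combn(N, n)
  inCat <- colSums(subsets <= K)   # first K elements are the category
  mean(inCat >= k)
}

## Random enriched-region set on one chromosome, with summit mcol.
randomRegions <- function(n, chromLen, chrom = "chr1", width = 400L) {
  s <- sample.int(chromLen - width, n, replace = TRUE)
  gr <- GRanges(chrom, IRanges(s, s + width - 1L))
  mcols(gr)$summit <- s + sample.int(width, n, replace = TRUE) - 1L
  gr
}

## Random gene table on one chromosome.
randomGenes <- function(n, chromLen, chrom = "chr1") {
  geneRecords(sprintf("g%04d", seq_len(n)), rep(chrom, n),
              sample(c("+", "-"), n, replace = TRUE),
              sample.int(chromLen, n))
}
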