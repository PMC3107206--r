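#' Extract binned, per-million signal in windows around anchor points
#'
#' For each anchor, a window of \code{window} bp centered on the anchor is
#' split into \code{window / bin} consecutive bins; each bin counts the
#' extended fragments overlapping it, scaled to reads per million mapped
#' fragments. Anchors closer than \code{window/2} to a chromosome end are
#' dropped with a warning.
#'
#' @param anchorPoints width-1 \link[GenomicRanges]{GRanges} of anchor
#'   positions (e.g. summits from \code{\link{colocalizationAnchors}}), or
#'   regions whose \code{summit} column is used.
#' @param reads strand-aware read \link[GenomicRanges]{GRanges}.
#' @param genome a \link[GenomeInfoDb]{Seqinfo}.
#' @param window full window width in bp (default 1500).
#' @param bin bin width in bp (default 100).
#' @param extension strand-specific fragment extension (default 200).
#' @param label sample label stored in the matrix.
#' @return a \linkS4class{WindowSignalMatrix}.
#' @export
extractWindowSignal <- function(anchorPoints, reads, genome, window = 1500L,
                                bin = 100L, extension = 200L, label = "") {
  if (window %% bin != 0L) stop("bin must divide window")
  if (!length(reads)) stop("read set is empty; cannot normalize")
  ctr <- .summitPos(anchorPoints)
  half <- window %/% 2L
  sl <- seqlengths(genome)
  ch <- as.character(seqnames(anchorPoints))
  ok <- ctr - half >= 0 & ctr + half <= sl[ch]
  if (any(!ok))
    warning(sum(!ok), " anchor(s) within ", half,
            " bp of a chromosome end dropped")
  ctr <- ctr[ok]; ch <- ch[ok]
  nb <- window %/% bin
  frags <- extendReads(reads, genome, extension)
  if (!length(ctr)) {
    vals <- matrix(numeric(0), nrow = 0L, ncol = nb)
  } else {
    ## one GRanges of all anchor x bin cells, counted in a single overlap
    binStart <- rep(ctr - half, each = nb) + rep((seq_len(nb) - 1L) * bin, length(ctr))
    cells <- GRanges(rep(ch, each = nb), IRanges(binStart + 1L, binStart + bin))
    cnt <- countOverlaps(cells, frags, ignore.strand = TRUE)
    vals <- matrix(cnt, nrow = length(ctr), ncol = nb, byrow = TRUE)
    vals <- vals * 1e6 / length(frags)
  }
  apts <- GRanges(ch, IRanges(as.integer(ctr), width = 1L))
  new("WindowSignalMatrix", anchors = apts, values = vals,
      windowSize = as.integer(window), binSize = as.integer(bin),
      sample = label, totalReads = as.numeric(length(frags)))
}

#' Select anchor loci where several peak sets colocalize
#'
#' Takes the anchor peak set (e.g. the transcription factor whose peaks
#' center the windows), keeps the strongest peak per locus (greedy by
#' \code{ipReads}, enforcing at least \code{span} bp between chosen
#' summits), and retains only loci where every other peak set has a summit
#' within \code{span} bp.
#'
#' @param anchorPeaks enriched-region \link[GenomicRanges]{GRanges}.
#' @param otherSets list of enriched-region \link[GenomicRanges]{GRanges}.
#' @param span colocalization span in bp (default 1500).
#' @return width-1 \link[GenomicRanges]{GRanges} of anchor summits.
#' @export
colocalizationAnchors <- function(anchorPeaks, otherSets, span = 1500L) {
  if (!length(anchorPeaks)) return(GRanges())
  s <- .summitPos(anchorPeaks)
  strength <- mcols(anchorPeaks)$ipReads
  if (is.null(strength)) strength <- width(anchorPeaks)
  ch <- as.character(seqnames(anchorPeaks))
  o <- order(-strength)
  chosen <- integer(0)
  for (i in o) {
    if (!length(chosen) ||
        all(ch[chosen] != ch[i] | abs(s[chosen] - s[i]) >= span))
      chosen <- c(chosen, i)
  }
  keep <- vapply(chosen, function(i) {
    all(vapply(otherSets, function(gr) {
      if (!length(gr)) return(FALSE)
      ts <- .summitPos(gr)
      any(as.character(seqnames(gr)) == ch[i] & abs(ts - s[i]) <= span)
    }, logical(1)))
  }, logical(1))
  chosen <- sort(chosen[keep])
  GRanges(ch[chosen], IRanges(as.integer(s[chosen]), width = 1L))
}

#' Per-anchor correlation of binned signal between two samples
#'
#' Pearson correlation between the two samples' bin vectors at each anchor.
#' An anchor where either vector has zero variance yields an invalid record
#' (r = NA, valid = FALSE); invalid records are excluded from histograms.
#'
#' @param m1,m2 \linkS4class{WindowSignalMatrix} objects over identical
#'   anchors.
#' @return data.frame with \code{chrom}, \code{center}, \code{r},
#'   \code{valid}.
#' @export
pairwiseLocationCorrelation <- function(m1, m2) {
  a1 <- anchors(m1); a2 <- anchors(m2)
  if (length(a1) != length(a2) ||
      !all(as.character(seqnames(a1)) == as.character(seqnames(a2))) ||
      !all(start(a1) == start(a2)))
    stop("anchor sets differ between the two matrices")
  v1 <- signalValues(m1); v2 <- signalValues(m2)
  n <- nrow(v1)
  r <- rep(NA_real_, n)
  valid <- logical(n)
  for (i in seq_len(n)) {
    if (sd(v1[i, ]) > 0 && sd(v2[i, ]) > 0) {
      r[i] <- cor(v1[i, ], v2[i, ])
      valid[i] <- TRUE
    }
  }
  data.frame(chrom = as.character(seqnames(a1)), center = start(a1),
             r = r, valid = valid, stringsAsFactors = FALSE)
}

#' Histogram of per-anchor correlation coefficients
#'
#' @param records output of \code{\link{pairwiseLocationCorrelation}};
#'   invalid records are excluded.
#' @param breaks histogram breaks over [-1, 1].
#' @return data.frame \code{lower}, \code{upper}, \code{count}.
#' @export
correlationHistogram <- function(records, breaks = seq(-1, 1, by = 0.1)) {
  r <- records$r[records$valid]
  h <- hist(r, breaks = breaks, plot = FALSE)
  data.frame(lower = h$breaks[-length(h$breaks)], upper = h$breaks[-1L],
             count = h$counts)
}

#' Row-wise Z-score standardization of a signal matrix
#'
#' Each row is centered and scaled by its population standard deviation
#' (denominator n, so a one-hot row of b bins reaches the closed-form
#' maximum Z of sqrt(b - 1)); constant rows become all-zero and are flagged
#' in the \code{constantRows} attribute. Suitable for heatmap display of
#' binned window signal.
#'
#' @param m a \linkS4class{WindowSignalMatrix} or numeric matrix.
#' @return numeric matrix of Z scores with attribute \code{constantRows}.
#' @export
zscoreMatrix <- function(m) {
  v <- if (is(m, "WindowSignalMatrix")) signalValues(m) else m
  if (ncol(v) < 2L) stop("at least two bins per row are required")
  mu <- rowMeans(v)
  sdv <- sqrt(rowMeans((v - mu)^2))   # population sd
  constant <- sdv == 0
  z <- (v - mu) / ifelse(constant, 1, sdv)
  z[constant, ] <- 0
  attr(z, "constantRows") <- which(constant)
  z
}

#' Order heatmap rows by strength or hierarchical clustering
#'
#' @param m a \linkS4class{WindowSignalMatrix}.
#' @param method "strength" (descending row sum, default) or "hclust"
#'   (complete linkage on Euclidean distances of Z-scored rows).
#' @return integer row permutation.
#' @export
heatmapRowOrder <- function(m, method = c("strength", "hclust")) {
  method <- match.arg(method)
  v <- signalValues(m)
  if (method == "strength") return(order(-rowSums(v)))
  z <- zscoreMatrix(m)
  stats::hclust(stats::dist(z), method = "complete")$order
}

#' Write a window signal (or Z-score) matrix as TSV
#'
#' @param m a \linkS4class{WindowSignalMatrix}.
#' @param path output path.
#' @param zscore write Z scores instead of per-million values.
#' @export
writeSignalMatrix <- function(m, path, zscore = FALSE) {
  v <- if (zscore) zscoreMatrix(m) else signalValues(m)
  a <- anchors(m)
  df <- data.frame(anchor = sprintf("%s:%d", as.character(seqnames(a)),
                                    start(a) - 1L))
  colnames(v) <- sprintf("bin%02d", seq_len(ncol(v)))
  con <- .openWrite(path)
  on.exit(close(con))
  write.table(cbind(df, as.data.frame(v)), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
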