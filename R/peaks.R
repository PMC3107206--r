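#' Extend reads strand-specifically into fixed-length fragments
#'
#' Each read is replaced by a fragment of \code{extension} bp anchored at
#' its 5' end in the direction of transcription of the strand it mapped to:
#' a + read starting at s (0-based) becomes [s, s + extension); a - read
#' ending at e becomes [e - extension, e). Fragments are clipped at
#' chromosome bounds.
#'
#' @param reads strand-aware \link[GenomicRanges]{GRanges} of aligned reads.
#' @param genome a \link[GenomeInfoDb]{Seqinfo}.
#' @param extension fragment length in bp (default 200).
#' @return \link[GenomicRanges]{GRanges} of fragments (strand preserved).
#' @export
extendReads <- function(reads, genome, extension = 200L) {
  if (!length(reads))
    return(GRanges(seqinfo = genome))
  sl <- seqlengths(genome)
  ch <- as.character(seqnames(reads))
  bad <- !(ch %in% names(sl))
  if (any(bad))
    stop("read on chromosome absent from genome: ", ch[which(bad)[1L]])
  plus <- as.character(strand(reads)) == "+"
  s <- ifelse(plus, start(reads), end(reads) - extension + 1L)
  e <- s + extension - 1L
  s <- pmax(s, 1L)
  e <- pmin(e, sl[ch])
  if (any(s > e))
    stop("read entirely outside chromosome bounds after extension")
  GRanges(ch, IRanges(s, e), strand = strand(reads), seqinfo = genome)
}

## count fragments overlapping each fixed-width bin via a difference array
.binFragments <- function(fragments, genome, binSize) {
  sl <- seqlengths(genome)
  nb <- ceiling(sl / binSize)
  counts <- lapply(names(sl), function(ch) integer(nb[[ch]]))
  names(counts) <- names(sl)
  if (length(fragments)) {
    ch <- as.character(seqnames(fragments))
    b0 <- (start(fragments) - 1L) %/% binSize + 1L   # first bin, 1-based
    b1 <- (end(fragments) - 1L) %/% binSize + 1L     # last bin, 1-based
    for (c2 in unique(ch)) {
      i <- ch == c2
      n <- nb[[c2]]
      delta <- tabulate(b0[i], nbins = n) -
        tabulate(pmin(b1[i] + 1L, n + 1L), nbins = n + 1L)[seq_len(n)]
      ## fragments whose last bin is the final bin never get the -1 inside
      ## [1, n]; cumsum of the truncated delta handles them correctly
      counts[[c2]] <- cumsum(delta)
    }
  }
  new("BinTrack", counts = counts, binSize = as.integer(binSize),
      totalReads = as.numeric(length(fragments)), seqinfo = genome)
}

#' Extend reads and allocate them to genome bins
#'
#' Applies the strand-specific extension of \code{\link{extendReads}} and
#' increments every bin the fragment overlaps, yielding the binned coverage
#' track the Poisson significance test operates on.
#'
#' @param reads strand-aware \link[GenomicRanges]{GRanges}.
#' @param genome a \link[GenomeInfoDb]{Seqinfo}.
#' @param params a \linkS4class{PeakParams}.
#' @return a \linkS4class{BinTrack}.
#' @examples
#' g <- simGenome(c(chr1 = 1000))
#' r <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 136), strand = "+")
#' tr <- extendAndBin(r, g, peakParams())
#' which(binCounts(tr, "chr1") > 0)  # bins 5..12 (1-based): [100, 300)
#' @export
extendAndBin <- function(reads, genome, params = peakParams()) {
  frags <- extendReads(reads, genome, params@extension)
  .binFragments(frags, genome, params@binSize)
}

#' Minimum bin count reaching a Poisson tail threshold
#'
#' Returns the smallest integer k such that P(X >= k) < pThreshold for
#' X ~ Poisson(lambda): the minimum number of fragment counts a genomic bin
#' must hold to be called significantly enriched over a Poisson background
#' with mean \code{lambda} per bin.
#'
#' @param lambda expected fragments per bin under the background model, > 0.
#' @param pThreshold upper-tail probability threshold (default 1e-9).
#' @return integer minimum count.
#' @examples
#' poissonMinCount(0.1, 1e-9)  # 7
#' @export
poissonMinCount <- function(lambda, pThreshold = 1e-9) {
  if (lambda <= 0) stop("lambda must be > 0")
  if (pThreshold <= 0 || pThreshold >= 1)
    stop("pThreshold must lie in (0, 1)")
  k <- max(1L, qpois(1 - pThreshold, lambda))
  while (ppois(k - 1, lambda, lower.tail = FALSE) >= pThreshold)
    k <- k + 1L
  as.integer(k)
}

#' Merge significant bins into enriched regions
#'
#' Bins with count >= \code{minCount} are significant; maximal groups of
#' significant bins whose edge-to-edge gap is at most \code{mergeGap} bp
#' form one region spanning the first bin's start to the last bin's end.
#' The summit is the midpoint of the maximum-count bin (leftmost on ties).
#' When \code{fragments} is supplied, \code{ipReads} counts the extended
#' fragments overlapping each region (fragment-density units, so a fragment
#' spanning several bins is counted once).
#'
#' @param track a \linkS4class{BinTrack}.
#' @param minCount integer significance threshold, >= 1.
#' @param params a \linkS4class{PeakParams} (supplies \code{mergeGap}).
#' @param fragments optional extended-fragment \link[GenomicRanges]{GRanges}.
#' @return \link[GenomicRanges]{GRanges} of regions with metadata columns
#'   \code{summit}, \code{maxCount} and (if fragments given) \code{ipReads}.
#' @export
callEnrichedRegions <- function(track, minCount, params = peakParams(),
                                fragments = NULL) {
  if (minCount < 1) stop("minCount must be >= 1")
  bs <- binSize(track)
  maxGapBins <- params@mergeGap %/% bs   # gap of g empty bins = g*bs bp
  sl <- seqlengths(seqinfo(track))
  chs <- starts <- ends <- summits <- maxc <- NULL
  for (ch in names(binCounts(track))) {
    v <- binCounts(track)[[ch]]
    sig <- which(v >= minCount)
    if (!length(sig)) next
    ## split where the run of empty bins between neighbours exceeds the gap
    grp <- cumsum(c(1L, diff(sig) - 1L > maxGapBins))
    for (g in unique(grp)) {
      b <- sig[grp == g]
      first <- b[1L]; last <- b[length(b)]
      peakBin <- b[which.max(v[b])]       # leftmost maximal bin
      chs <- c(chs, ch)
      starts <- c(starts, (first - 1L) * bs + 1L)
      ends <- c(ends, min(last * bs, sl[[ch]]))
      summits <- c(summits, (peakBin - 1L) * bs + bs %/% 2L + 1L)
      maxc <- c(maxc, v[peakBin])
    }
  }
  if (is.null(chs))
    return(GRanges(seqinfo = seqinfo(track)))
  gr <- GRanges(chs, IRanges(starts, ends), seqinfo = seqinfo(track))
  mcols(gr)$summit <- as.integer(summits)
  mcols(gr)$maxCount <- as.integer(maxc)
  if (!is.null(fragments))
    mcols(gr)$ipReads <- countOverlaps(gr, fragments, ignore.strand = TRUE)
  gr
}

#' Filter regions by fold enrichment over an empirical control
#'
#' For each region the IP density is \code{ipReads / totalIp} and the
#' control density is \code{controlReads / totalControl}, both in fragment
#' counts per total mapped reads (per-million scaling cancels in the ratio).
#' A region is retained iff the density ratio strictly exceeds
#' \code{minFold}. Regions with zero control reads use the pseudocount so
#' the ratio stays finite.
#'
#' @param regions \link[GenomicRanges]{GRanges} from
#'   \code{\link{callEnrichedRegions}}.
#' @param ipFragments,controlFragments extended-fragment
#'   \link[GenomicRanges]{GRanges} for the IP and the IgG control sample.
#' @param params a \linkS4class{PeakParams}.
#' @return the retained regions, with \code{ipReads}, \code{controlReads}
#'   and \code{fold} metadata columns.
#' @export
applyControlFilter <- function(regions, ipFragments, controlFragments,
                               params = peakParams()) {
  totalIp <- length(ipFragments)
  totalCtrl <- length(controlFragments)
  if (totalIp == 0 || totalCtrl == 0)
    stop("both IP and control must contain reads")
  if (!length(regions)) return(regions)
  ip <- mcols(regions)$ipReads
  if (is.null(ip))
    ip <- countOverlaps(regions, ipFragments, ignore.strand = TRUE)
  ctrl <- countOverlaps(regions, controlFragments, ignore.strand = TRUE)
  ctrlEff <- ifelse(ctrl == 0, params@pseudocount, ctrl)
  fold <- (ip / totalIp) / (ctrlEff / totalCtrl)
  mcols(regions)$ipReads <- ip
  mcols(regions)$controlReads <- ctrl
  mcols(regions)$fold <- fold
  regions[fold > params@minFold]
}

#' Call enriched regions from IP and IgG-control reads
#'
#' The full caller: strand-specific 200-bp extension and 25-bp binning of
#' both samples; a single genome-wide Poisson background rate for the IP
#' (total bin increments / total bins) from which the per-sample minimum
#' significant bin count is derived at the 1e-9 threshold; merging of
#' significant bins within 200 bp into regions; and removal of regions
#' without more than three-fold greater read density in the IP than in the
#' control, normalized for total reads. All stage counts and the derived
#' minimum count are reported via \code{message}.
#'
#' @param ip,control strand-aware read \link[GenomicRanges]{GRanges}.
#' @param genome a \link[GenomeInfoDb]{Seqinfo}.
#' @param params a \linkS4class{PeakParams}.
#' @param verbose emit per-stage messages (default TRUE).
#' @return \link[GenomicRanges]{GRanges} of enriched regions with
#'   \code{summit}, \code{ipReads}, \code{controlReads}, \code{fold};
#'   the derived threshold is attached as \code{metadata} fields
#'   \code{minCount} and \code{lambda}.
#' @examples
#' g <- simGenome(c(chr1 = 2e5))
#' s <- plantedSites("chr1", 1e5, 1.01e5, fold = 15, genome = g)
#' rs <- simulateReads(g, s, nReadsTarget = 2e4, seed = 7)
#' pk <- callPeaks(rs$ip, rs$control, g, verbose = FALSE)
#' @export
callPeaks <- function(ip, control, genome, params = peakParams(),
                      verbose = TRUE) {
  say <- if (verbose) message else function(...) invisible(NULL)
  ipFrag <- extendReads(ip, genome, params@extension)
  ctrlFrag <- extendReads(control, genome, params@extension)
  ipTrack <- .binFragments(ipFrag, genome, params@binSize)
  increments <- sum(vapply(binCounts(ipTrack), sum, numeric(1)))
  nBins <- sum(lengths(binCounts(ipTrack)))
  lambda <- increments / nBins
  if (lambda <= 0) stop("IP sample contains no reads")
  minCount <- poissonMinCount(lambda, params@pThreshold)
  say("IP: ", length(ipFrag), " fragments; control: ", length(ctrlFrag),
      " fragments")
  say("background lambda = ", signif(lambda, 4), " per ", params@binSize,
      "-bp bin; minimum significant count = ", minCount)
  regions <- callEnrichedRegions(ipTrack, minCount, params, ipFrag)
  say(length(regions), " candidate region(s) before control filter")
  kept <- applyControlFilter(regions, ipFrag, ctrlFrag, params)
  say(length(kept), " region(s) pass the >", params@minFold,
      "-fold control filter")
  S4Vectors::metadata(kept) <- list(minCount = minCount, lambda = lambda,
                                    params = params)
  kept
}
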