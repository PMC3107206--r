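#' @import methods
#' @importFrom stats ppois qpois phyper p.adjust wilcox.test quantile median sd cor rpois runif rnorm rbinom
#' @importFrom utils read.table write.table
#' @importFrom GenomicRanges GRanges countOverlaps findOverlaps seqnames start end strand width mcols mcols<- sort nearest granges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits DataFrame
#' @importFrom GenomeInfoDb Seqinfo seqlengths seqinfo seqinfo<- seqlevels
#' @importFrom graphics hist
NULL

#' Parameters of the enrichment-region caller
#'
#' Holds the tunable parameters of the peak caller: strand-specific read
#' extension length, genome bin width, the Poisson tail-probability
#' threshold used to derive the per-sample minimum bin count, the maximum
#' edge-to-edge gap (bp) across which significant bins are merged into one
#' region, the minimum IP/control per-million density ratio a region must
#' strictly exceed, and the control pseudocount used when a region contains
#' no control reads.
#'
#' @slot extension integer, fragment extension from the read 5' end (bp).
#' @slot binSize integer, genome bin width (bp).
#' @slot pThreshold numeric in (0,1), Poisson upper-tail threshold.
#' @slot mergeGap integer, maximum gap (bp) merged between significant bins.
#' @slot minFold numeric, strict lower bound on the IP/control density ratio.
#' @slot pseudocount numeric, control reads substituted for zero-control
#'   regions so the fold ratio stays finite.
#' @export
setClass("PeakParams", representation(
  extension = "integer", binSize = "integer", pThreshold = "numeric",
  mergeGap = "integer", minFold = "numeric", pseudocount = "numeric"
))

setValidity("PeakParams", function(object) {
  msg <- character()
  if (object@extension <= 0L) msg <- c(msg, "extension must be positive")
  if (object@binSize <= 0L) msg <- c(msg, "binSize must be positive")
  if (!(object@pThreshold > 0 && object@pThreshold < 1))
    msg <- c(msg, "pThreshold must lie in (0, 1)")
  if (object@mergeGap < 0L) msg <- c(msg, "mergeGap must be non-negative")
  if (object@minFold <= 0) msg <- c(msg, "minFold must be positive")
  if (object@pseudocount <= 0) msg <- c(msg, "pseudocount must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct peak-calling parameters
#'
#' Defaults follow the pipeline's reference analysis: 200-bp strand-specific
#' extension, 25-bp bins, Poisson threshold 1e-9, 200-bp merge gap, and a
#' strict three-fold IP/IgG density filter.
#'
#' @param extension fragment extension in bp (default 200).
#' @param binSize bin width in bp (default 25).
#' @param pThreshold Poisson upper-tail probability threshold (default 1e-9).
#' @param mergeGap maximum bp gap merged between significant bins (default 200).
#' @param minFold strict minimum IP/control density ratio (default 3).
#' @param pseudocount control-read pseudocount for zero-control regions
#'   (default 1).
#' @return a \linkS4class{PeakParams} object.
#' @examples
#' peakParams(pThreshold = 1e-6)
#' @export
peakParams <- function(extension = 200L, binSize = 25L, pThreshold = 1e-9,
                       mergeGap = 200L, minFold = 3, pseudocount = 1) {
  new("PeakParams", extension = as.integer(extension),
      binSize = as.integer(binSize), pThreshold = as.numeric(pThreshold),
      mergeGap = as.integer(mergeGap), minFold = as.numeric(minFold),
      pseudocount = as.numeric(pseudocount))
}

setMethod("show", "PeakParams", function(object) {
  cat("PeakParams: extension=", object@extension, "bp, bin=", object@binSize,
      "bp, p<", format(object@pThreshold), ", mergeGap=", object@mergeGap,
      "bp, fold>", object@minFold, ", pseudocount=", object@pseudocount,
      "\n", sep = "")
})

#' Per-chromosome counts of extended fragments in fixed-width bins
#'
#' One integer vector per chromosome, each of length
#' \code{ceiling(chromLength / binSize)}; entry b is the number of extended
#' fragments overlapping genomic bin \code{[(b-1)*binSize, b*binSize)}
#' (0-based half-open). \code{totalReads} is the number of fragments that
#' produced the track and is the denominator for per-million normalization.
#'
#' @slot counts named list of integer vectors, one per chromosome.
#' @slot binSize integer bin width (bp).
#' @slot totalReads numeric, fragments counted into the track.
#' @slot seqinfo the \link[GenomeInfoDb]{Seqinfo} of the genome binned.
#' @export
setClass("BinTrack", representation(
  counts = "list", binSize = "integer", totalReads = "numeric",
  seqinfo = "Seqinfo"
))

setValidity("BinTrack", function(object) {
  msg <- character()
  sl <- seqlengths(object@seqinfo)
  if (!identical(names(object@counts), names(sl)))
    msg <- c(msg, "counts must be named by the genome's chromosomes, in order")
  expect <- ceiling(sl / object@binSize)
  for (ch in names(object@counts)) {
    v <- object@counts[[ch]]
    if (!is.numeric(v) || any(v < 0))
      msg <- c(msg, sprintf("counts for %s must be non-negative", ch))
    if (length(v) != expect[[ch]])
      msg <- c(msg, sprintf("counts for %s must have %d bins", ch, expect[[ch]]))
  }
  if (object@binSize <= 0L) msg <- c(msg, "binSize must be positive")
  if (object@totalReads < 0) msg <- c(msg, "totalReads must be non-negative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BinTrack", function(object) {
  cat("BinTrack: ", length(object@counts), " chromosome(s), bin=",
      object@binSize, "bp, ", sum(lengths(object@counts)), " bins, ",
      object@totalReads, " fragments\n", sep = "")
})

#' @describeIn BinTrack-accessors bin width in bp.
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @describeIn BinTrack-accessors number of fragments in the track.
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))

#' @describeIn BinTrack-accessors per-chromosome count vectors.
#' @export
setGeneric("binCounts", function(x, chrom) standardGeneric("binCounts"))

#' Accessors for BinTrack and WindowSignalMatrix objects
#'
#' @param x a \linkS4class{BinTrack} or \linkS4class{WindowSignalMatrix}.
#' @param chrom optional chromosome name; omitted returns the full list.
#' @name BinTrack-accessors
NULL

#' @rdname BinTrack-accessors
#' @export
setMethod("binSize", "BinTrack", function(x) x@binSize)

#' @rdname BinTrack-accessors
#' @export
setMethod("totalReads", "BinTrack", function(x) x@totalReads)

#' @rdname BinTrack-accessors
#' @export
setMethod("binCounts", "BinTrack", function(x, chrom) {
  if (missing(chrom)) return(x@counts)
  if (!chrom %in% names(x@counts))
    stop("unknown chromosome: ", chrom)
  x@counts[[chrom]]
})

#' @importMethodsFrom GenomeInfoDb seqinfo
#' @export
setMethod("seqinfo", "BinTrack", function(x) x@seqinfo)

#' Binned, depth-normalized signal in fixed windows around anchor points
#'
#' Each row is one anchor locus; columns are consecutive fixed-width bins
#' spanning a window centered on the anchor. Values are extended-fragment
#' counts scaled to reads per million mapped reads.
#'
#' @slot anchors width-1 \link[GenomicRanges]{GRanges} of anchor points.
#' @slot values numeric matrix, anchors x bins, reads per million.
#' @slot windowSize integer, full window width in bp.
#' @slot binSize integer, bin width in bp.
#' @slot sample character label of the read sample.
#' @slot totalReads numeric, mapped fragments behind the normalization.
#' @export
setClass("WindowSignalMatrix", representation(
  anchors = "GRanges", values = "matrix", windowSize = "integer",
  binSize = "integer", sample = "character", totalReads = "numeric"
))

setValidity("WindowSignalMatrix", function(object) {
  msg <- character()
  if (object@windowSize %% object@binSize != 0L)
    msg <- c(msg, "binSize must divide windowSize")
  nb <- object@windowSize %/% object@binSize
  if (ncol(object@values) != nb)
    msg <- c(msg, sprintf("values must have %d columns", nb))
  if (nrow(object@values) != length(object@anchors))
    msg <- c(msg, "one row per anchor required")
  if (any(object@values < 0)) msg <- c(msg, "values must be non-negative")
  if (any(width(object@anchors) != 1L))
    msg <- c(msg, "anchors must be width-1 points")
  if (length(msg)) msg else TRUE
})

setMethod("show", "WindowSignalMatrix", function(object) {
  cat("WindowSignalMatrix '", object@sample, "': ", length(object@anchors),
      " anchors x ", ncol(object@values), " bins (", object@binSize,
      " bp), window ", object@windowSize, " bp, per-million over ",
      object@totalReads, " fragments\n", sep = "")
})

#' @rdname BinTrack-accessors
#' @export
setMethod("binSize", "WindowSignalMatrix", function(x) x@binSize)

#' @rdname BinTrack-accessors
#' @export
setMethod("totalReads", "WindowSignalMatrix", function(x) x@totalReads)

#' @describeIn BinTrack-accessors anchor points of a signal matrix.
#' @export
setGeneric("anchors", function(x) standardGeneric("anchors"))

#' @rdname BinTrack-accessors
#' @export
setMethod("anchors", "WindowSignalMatrix", function(x) x@anchors)

#' @describeIn BinTrack-accessors signal matrix values (reads per million).
#' @export
setGeneric("signalValues", function(x) standardGeneric("signalValues"))

#' @rdname BinTrack-accessors
#' @export
setMethod("signalValues", "WindowSignalMatrix", function(x) x@values)
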