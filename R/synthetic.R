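#' Define a simulation genome
#'
#' @param lengths named numeric vector of chromosome lengths in bp.
#' @return a \link[GenomeInfoDb]{Seqinfo} describing the genome.
#' @examples
#' simGenome(c(chr1 = 1e6, chr2 = 5e5))
#' @export
simGenome <- function(lengths) {
  if (is.null(names(lengths)) || any(!nzchar(names(lengths))))
    stop("chromosome lengths must be named")
  if (anyDuplicated(names(lengths)))
    stop("chromosome names must be unique")
  if (any(lengths <= 0)) stop("chromosome lengths must be positive")
  Seqinfo(seqnames = names(lengths), seqlengths = as.integer(lengths))
}

#' Construct planted enriched sites
#'
#' Planted sites are the simulation ground truth: inside each site the IP
#' read rate is multiplied by \code{fold}; the IgG control never carries
#' planted enrichment. Coordinates are 0-based half-open, matching the BED
#' files the simulator writes.
#'
#' @param chrom,start,end vectors of site coordinates (0-based half-open).
#' @param fold per-site enrichment multiplier, all >= 1.
#' @param label optional free-text labels.
#' @param genome optional \link[GenomeInfoDb]{Seqinfo}; sites outside it are
#'   rejected with the offending site named.
#' @return a \link[GenomicRanges]{GRanges} with \code{fold} and \code{label}
#'   metadata columns.
#' @export
plantedSites <- function(chrom, start, end, fold, label = NULL, genome = NULL) {
  if (any(start >= end)) stop("planted sites must satisfy start < end")
  if (any(fold < 1)) stop("planted fold must be >= 1")
  if (is.null(label)) label <- sprintf("site%03d", seq_along(chrom))
  gr <- GRanges(chrom, IRanges(start + 1L, end), fold = fold, label = label)
  if (!is.null(genome)) {
    sl <- seqlengths(genome)
    bad <- !(as.character(seqnames(gr)) %in% names(sl)) |
      end(gr) > sl[as.character(seqnames(gr))] | start(gr) < 1L
    if (any(bad))
      stop("planted site(s) outside genome: ",
           paste(mcols(gr)$label[bad], collapse = ", "))
    gr <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)),
                  fold = mcols(gr)$fold, label = mcols(gr)$label,
                  seqinfo = genome)
  }
  gr
}

## draw n read 5' positions uniformly on [lo, hi) (0-based), return a
## width-readLength GRanges clipped to the chromosome; strand ~ Bernoulli(1/2)
## and the 5' end sits at the drawn position for + reads and at the read end
## for - reads.
.drawReads <- function(chrom, lo, hi, n, readLength, chromLen) {
  if (n == 0L)
    return(GRanges())
  p <- lo + floor(runif(n) * (hi - lo))       # 0-based 5' positions
  str <- ifelse(runif(n) < 0.5, "+", "-")
  s <- ifelse(str == "+", p, p - readLength + 1L)
  e <- s + readLength
  s <- pmax(s, 0L)
  e <- pmin(e, chromLen)
  keep <- s < e
  GRanges(chrom, IRanges(s[keep] + 1L, e[keep]), strand = str[keep])
}

## sample one read set from a piecewise-constant Poisson rate: base rate
## everywhere, plus (fold-1)*rate superposed on each elevated patch.
.sampleReadSet <- function(genome, rate, readLength, patches) {
  sl <- seqlengths(genome)
  out <- vector("list", 0L)
  for (ch in names(sl)) {
    L <- sl[[ch]]
    nBg <- rpois(1L, rate * L)
    out[[length(out) + 1L]] <- .drawReads(ch, 0L, L, nBg, readLength, L)
    if (!is.null(patches) && length(patches)) {
      p <- patches[as.character(seqnames(patches)) == ch]
      if (length(p)) {
        for (i in seq_along(p)) {
          w <- width(p)[i]
          extra <- rpois(1L, (mcols(p)$fold[i] - 1) * rate * w)
          out[[length(out) + 1L]] <-
            .drawReads(ch, start(p)[i] - 1L, end(p)[i], extra, readLength, L)
        }
      }
    }
  }
  gr <- suppressWarnings(do.call(c, out))
  gr <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)),
                strand = strand(gr), seqinfo = genome)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

## uniformly placed hotspot patches (locally elevated background), fixed fold
.drawHotspots <- function(genome, n, width, fold) {
  if (n == 0L) return(GRanges())
  sl <- seqlengths(genome)
  ch <- sample(names(sl), n, replace = TRUE, prob = sl / sum(sl))
  s <- floor(runif(n) * (sl[ch] - width))
  GRanges(ch, IRanges(s + 1L, s + width), fold = rep(fold, n))
}

#' Simulate IP and IgG-control aligned reads with planted enriched sites
#'
#' Background read 5' positions are drawn as a homogeneous Poisson process
#' on both strands. A configurable number of background "hotspots" --
#' 500-bp patches at five-fold the background rate -- model the non-random
#' background that a mock-IP (IgG) control exists to capture; a fraction
#' \code{controlCorrelation} of hotspots is shared between IP and control,
#' the remainder being private to each sample. Planted sites multiply the
#' IP rate by their \code{fold}; the control never contains planted
#' enrichment. Runs are reproducible given \code{seed}.
#'
#' @param genome a \link[GenomeInfoDb]{Seqinfo} from \code{\link{simGenome}}.
#' @param sites planted sites from \code{\link{plantedSites}} (may be empty).
#' @param nReadsTarget target total read count per sample; sets the
#'   background rate as \code{nReadsTarget / genome length} unless
#'   \code{backgroundRate} is given. Realized counts are Poisson around it.
#' @param backgroundRate expected background reads per bp (overrides
#'   \code{nReadsTarget}).
#' @param readLength read length in bp.
#' @param controlCorrelation fraction in [0,1] of hotspots shared between
#'   IP and control (default 1: matched background, the premise under which
#'   an IgG filter is meaningful).
#' @param hotspotDensity hotspots per megabase (default 5).
#' @param hotspotWidth,hotspotFold hotspot patch geometry (500 bp, 5x).
#' @param hotspots optional \link[GenomicRanges]{GRanges} of hotspot patches
#'   (with a \code{fold} column, e.g. from
#'   \code{\link{backgroundHotspots}}) replacing the internal draw; pass the
#'   same set to several IP simulations sharing one control, the way one
#'   mock-IP background underlies all IPs of an experiment.
#' @param seed integer seed; same seed and arguments give identical output.
#' @return list with elements \code{ip} and \code{control}, each a strand-
#'   aware \link[GenomicRanges]{GRanges} of aligned reads.
#' @examples
#' g <- simGenome(c(chr1 = 2e5))
#' s <- plantedSites("chr1", 9e4, 9.1e4, fold = 10, genome = g)
#' rs <- simulateReads(g, s, nReadsTarget = 2e4, seed = 1)
#' length(rs$ip)
#' @export
simulateReads <- function(genome, sites = GRanges(), nReadsTarget = 1e6,
                          backgroundRate = NULL, readLength = 36L,
                          controlCorrelation = 1, hotspotDensity = 5,
                          hotspotWidth = 500L, hotspotFold = 5,
                          hotspots = NULL, seed = 1L) {
  stopifnot(is(genome, "Seqinfo"))
  if (controlCorrelation < 0 || controlCorrelation > 1)
    stop("controlCorrelation must lie in [0, 1]")
  sl <- seqlengths(genome)
  if (is.null(backgroundRate)) backgroundRate <- nReadsTarget / sum(sl)
  if (backgroundRate < 0) stop("backgroundRate must be >= 0")
  if (length(sites)) {
    bad <- !(as.character(seqnames(sites)) %in% names(sl)) |
      end(sites) > sl[as.character(seqnames(sites))]
    if (any(bad)) {
      lab <- if (!is.null(mcols(sites)$label)) mcols(sites)$label[bad]
             else which(bad)
      stop("planted site(s) outside genome: ", paste(lab, collapse = ", "))
    }
  }
  set.seed(seed)
  if (is.null(hotspots)) {
    nHot <- round(hotspotDensity * sum(as.numeric(sl)) / 1e6)
    hot <- .drawHotspots(genome, nHot, hotspotWidth, hotspotFold)
  } else {
    hot <- hotspots
    if (is.null(mcols(hot)$fold)) mcols(hot)$fold <- hotspotFold
    nHot <- length(hot)
  }
  nShared <- round(controlCorrelation * nHot)
  shared <- hot[seq_len(nShared)]
  ipPriv <- .drawHotspots(genome, nHot - nShared, hotspotWidth, hotspotFold)
  ctrlPriv <- .drawHotspots(genome, nHot - nShared, hotspotWidth, hotspotFold)
  ipPatch <- suppressWarnings(c(shared, ipPriv))
  if (length(sites))
    ipPatch <- suppressWarnings(c(
      ipPatch, GRanges(seqnames(sites), IRanges(start(sites), end(sites)),
                       fold = mcols(sites)$fold)))
  ctrlPatch <- suppressWarnings(c(shared, ctrlPriv))
  ip <- .sampleReadSet(genome, backgroundRate, readLength, ipPatch)
  control <- .sampleReadSet(genome, backgroundRate, readLength, ctrlPatch)
  list(ip = ip, control = control)
}

#' Draw a shared set of background hotspot patches
#'
#' Uniformly placed patches of locally elevated background rate, the
#' non-random background component a mock-IP control exists to capture.
#' Draw once and pass to every \code{\link{simulateReads}} call of an
#' experiment so all IPs and the control share one background structure.
#'
#' @param genome a \link[GenomeInfoDb]{Seqinfo}.
#' @param density hotspots per megabase (default 5).
#' @param width patch width in bp (default 500).
#' @param fold rate multiplier inside a patch (default 5).
#' @param seed integer seed.
#' @return \link[GenomicRanges]{GRanges} with a \code{fold} column.
#' @export
backgroundHotspots <- function(genome, density = 5, width = 500L, fold = 5,
                               seed = 1L) {
  set.seed(seed)
  n <- round(density * sum(as.numeric(seqlengths(genome))) / 1e6)
  .drawHotspots(genome, n, width, fold)
}

#' Construct a gene table as TSS-anchored ranges
#'
#' @param gene_id unique gene identifiers.
#' @param chrom chromosome names.
#' @param strand "+" or "-" per gene.
#' @param tss transcription start site, 0-based bp.
#' @param genome optional \link[GenomeInfoDb]{Seqinfo}.
#' @return width-1 \link[GenomicRanges]{GRanges} at each TSS with a
#'   \code{gene_id} column.
#' @export
geneRecords <- function(gene_id, chrom, strand, tss, genome = NULL) {
  if (anyDuplicated(gene_id)) stop("gene_id values must be unique")
  if (any(tss < 0)) stop("tss must be >= 0")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  args <- list(chrom, IRanges(tss + 1L, width = 1L), strand = strand,
               gene_id = as.character(gene_id))
  if (!is.null(genome)) args$seqinfo <- genome
  do.call(GRanges, args)
}

#' Generate an evenly spaced synthetic gene table
#'
#' TSSs are placed on a regular grid with alternating strand, leaving a
#' margin at chromosome ends so annotation windows fit.
#'
#' @param genome a \link[GenomeInfoDb]{Seqinfo}.
#' @param nGenes number of genes across the genome.
#' @param margin bp kept clear at each chromosome end.
#' @return a gene \link[GenomicRanges]{GRanges} (see \code{\link{geneRecords}}).
#' @export
syntheticGeneTable <- function(genome, nGenes, margin = 20000L) {
  sl <- as.numeric(seqlengths(genome))
  names(sl) <- seqlevels(genome)
  per <- round(as.numeric(nGenes) * sl / sum(sl))
  per[per < 1] <- 1
  ids <- chs <- strs <- tsss <- NULL
  k <- 0L
  for (ch in names(sl)) {
    usable <- sl[[ch]] - 2 * margin
    if (usable <= 0) stop("chromosome ", ch, " shorter than twice the margin")
    n <- per[[ch]]
    pos <- margin + round(seq(0, usable, length.out = n))
    ids <- c(ids, sprintf("G%05d", k + seq_len(n)))
    chs <- c(chs, rep(ch, n))
    strs <- c(strs, rep(c("+", "-"), length.out = n))
    tsss <- c(tsss, pos)
    k <- k + n
  }
  geneRecords(ids, chs, strs, tsss, genome = genome)
}

#' Plant enriched sites near a subset of gene TSSs
#'
#' Picks \code{nSites} genes at random and plants one site per gene at a
#' signed offset from its TSS, emulating promoter-proximal enrichment.
#'
#' @param genes gene \link[GenomicRanges]{GRanges} from
#'   \code{\link{geneRecords}}.
#' @param genome a \link[GenomeInfoDb]{Seqinfo}.
#' @param nSites number of genes to mark.
#' @param width site width in bp.
#' @param fold enrichment multiplier.
#' @param maxOffset maximum |offset| of the site center from the TSS (bp);
#'   offsets are drawn uniformly in [-maxOffset, maxOffset].
#' @param seed integer seed.
#' @return planted sites \link[GenomicRanges]{GRanges} with \code{fold},
#'   \code{label} and the source \code{gene_id}.
#' @export
plantSitesNearTSS <- function(genes, genome, nSites, width = 1000L,
                              fold = 10, maxOffset = 1000L, seed = 1L) {
  set.seed(seed)
  nSites <- min(nSites, length(genes))
  pick <- sample(seq_along(genes), nSites)
  tss <- start(genes)[pick] - 1L
  off <- round(runif(nSites, -maxOffset, maxOffset))
  ctr <- tss + off
  s <- pmax(0L, ctr - width %/% 2L)
  sl <- seqlengths(genome)
  chs <- as.character(seqnames(genes))[pick]
  e <- pmin(sl[chs], s + width)
  gr <- plantedSites(chs, s, e, fold = rep(fold, nSites),
                     label = sprintf("near_%s", mcols(genes)$gene_id[pick]),
                     genome = genome)
  mcols(gr)$gene_id <- mcols(genes)$gene_id[pick]
  gr
}

#' Recall and precision of called regions against planted truth
#'
#' A planted site is recovered when at least one called region overlaps it;
#' a called region is a true positive when it overlaps a planted site
#' padded by \code{pad} bp on each side (calls drifting up to \code{pad}
#' from the planted interval still count).
#'
#' @param peaks called enriched-region \link[GenomicRanges]{GRanges}.
#' @param sites planted-site \link[GenomicRanges]{GRanges}.
#' @param pad slack in bp for the precision direction (default 1000).
#' @return list with \code{recall}, \code{precision}, \code{nCalled},
#'   \code{nPlanted}.
#' @export
plantedRecovery <- function(peaks, sites, pad = 1000L) {
  padded <- GRanges(seqnames(sites),
                    IRanges(pmax(1L, start(sites) - pad), end(sites) + pad))
  recall <- if (length(sites))
    mean(countOverlaps(sites, peaks, ignore.strand = TRUE) > 0L) else NA_real_
  precision <- if (length(peaks))
    mean(countOverlaps(peaks, padded, ignore.strand = TRUE) > 0L) else NA_real_
  list(recall = recall, precision = precision,
       nCalled = length(peaks), nPlanted = length(sites))
}

#' Simulate per-gene expression with a shift for bound genes
#'
#' Unbound genes draw \code{baseline + N(0, noiseSd)}; bound genes draw
#' \code{baseline + shift + N(0, noiseSd)}, all on the log2 scale.
#'
#' @param genes gene \link[GenomicRanges]{GRanges} or character gene ids.
#' @param boundFlags logical vector, one per gene.
#' @param shift log2 expression shift for bound genes, >= 0.
#' @param noiseSd log2 noise standard deviation, >= 0.
#' @param baseline log2 baseline expression.
#' @param seed integer seed.
#' @return data.frame with columns \code{gene_id} and \code{log2_expr}.
#' @export
simulateExpression <- function(genes, boundFlags, shift = 1, noiseSd = 1,
                               baseline = 8, seed = 1L) {
  ids <- if (is.character(genes)) genes else mcols(genes)$gene_id
  if (length(boundFlags) != length(ids))
    stop("boundFlags must have one entry per gene")
  if (shift < 0) stop("shift must be >= 0")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  set.seed(seed)
  expr <- baseline + ifelse(boundFlags, shift, 0) +
    rnorm(length(ids), 0, noiseSd)
  data.frame(gene_id = ids, log2_expr = expr, stringsAsFactors = FALSE)
}
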