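## A region's location for gene assignment and distance statistics is its
## summit (midpoint of the maximum-count bin); summit falls back to the
## region midpoint when no summit column is present (e.g. hand-built ranges).
.summitPos <- function(regions) {
  s <- mcols(regions)$summit
  if (is.null(s)) s <- floor((start(regions) + end(regions)) / 2)
  as.numeric(s)
}

.strandSign <- function(strand) ifelse(as.character(strand) == "-", -1, 1)

#' Assign enriched regions to genes by TSS window
#'
#' A region counts for a gene iff its summit lies within \code{window} bp of
#' the gene's TSS (inclusive). The signed distance is (summit - TSS) in the
#' gene's direction of transcription, so negative values are upstream.
#' \code{min_tss_distance} is the signed distance of the closest assigned
#' region and is NA for genes with no region in the window.
#'
#' @param regions enriched-region \link[GenomicRanges]{GRanges}.
#' @param genes gene \link[GenomicRanges]{GRanges} from
#'   \code{\link{geneRecords}}.
#' @param window half-width of the assignment window in bp (default 10000).
#' @return data.frame with columns \code{gene_id}, \code{n_sites},
#'   \code{min_tss_distance}; one row per gene, gene order preserved.
#' @export
assignPeaksToGenes <- function(regions, genes, window = 10000L) {
  n <- length(genes)
  out <- data.frame(gene_id = mcols(genes)$gene_id,
                    n_sites = integer(n), min_tss_distance = NA_real_,
                    stringsAsFactors = FALSE)
  if (!length(regions)) return(out)
  summit <- .summitPos(regions)
  pts <- GRanges(seqnames(regions), IRanges(summit, width = 1L))
  win <- GRanges(seqnames(genes),
                 IRanges(pmax(1, start(genes) - window),
                         start(genes) + window))
  hits <- findOverlaps(pts, win, ignore.strand = TRUE)
  if (!length(hits)) return(out)
  gi <- subjectHits(hits)
  d <- summit[queryHits(hits)] - start(genes)[gi]
  keep <- abs(d) <= window          # exact inclusive window on distance
  gi <- gi[keep]; d <- d[keep]
  signed <- d * .strandSign(strand(genes)[gi])
  out$n_sites <- tabulate(gi, nbins = n)
  if (length(gi)) {
    o <- order(gi, abs(signed))
    first <- !duplicated(gi[o])
    out$min_tss_distance[gi[o][first]] <- signed[o][first]
  }
  out
}

#' Histogram of summit distances to the nearest TSS
#'
#' Each region summit is assigned to its nearest TSS (any gene); the signed
#' distance (negative upstream, in the gene's transcription direction) is
#' binned over [-range, range). With \code{normalize = TRUE}, counts are
#' divided by the maximum bin so the tallest bin is 1.
#'
#' @param regions enriched-region \link[GenomicRanges]{GRanges}.
#' @param genes gene \link[GenomicRanges]{GRanges}; must be non-empty.
#' @param range half-width of the histogram in bp.
#' @param bin bin width in bp; must divide \code{range}.
#' @param normalize divide counts by the maximum bin.
#' @return data.frame with \code{lower}, \code{upper} (bin edges, signed bp)
#'   and \code{count} (or normalized \code{value}).
#' @export
tssDistanceHistogram <- function(regions, genes, range = 10000L, bin = 100L,
                                 normalize = FALSE) {
  if (!length(genes)) stop("gene table is empty")
  if (range %% bin != 0L) stop("bin must divide range")
  edges <- seq(-range, range, by = bin)
  counts <- integer(length(edges) - 1L)
  if (length(regions)) {
    summit <- .summitPos(regions)
    pts <- GRanges(seqnames(regions), IRanges(summit, width = 1L))
    tss <- GRanges(seqnames(genes), IRanges(start(genes), width = 1L))
    nn <- nearest(pts, tss, ignore.strand = TRUE)
    ok <- !is.na(nn)
    d <- (summit[ok] - start(genes)[nn[ok]]) *
      .strandSign(strand(genes)[nn[ok]])
    d <- d[d >= -range & d < range]
    counts <- tabulate(findInterval(d, edges), nbins = length(counts))
  }
  df <- data.frame(lower = edges[-length(edges)], upper = edges[-1L],
                   count = counts)
  if (normalize) {
    if (max(counts) > 0) df$value <- counts / max(counts) else df$value <- 0
  }
  df
}

## distance from a summit point to a region set under the selected mode
.proximityDistances <- function(query, target,
                                mode = c("summit-to-edge", "summit-to-summit",
                                         "edge-to-edge")) {
  mode <- match.arg(mode)
  qs <- .summitPos(query)
  ts <- .summitPos(target)
  n <- length(query)
  d <- rep(Inf, n)
  qch <- as.character(seqnames(query))
  tch <- as.character(seqnames(target))
  for (ch in unique(qch)) {
    qi <- which(qch == ch)
    ti <- which(tch == ch)
    if (!length(ti)) next
    for (i in qi) {
      d[i] <- switch(mode,
        "summit-to-edge" = min(pmax(0, pmax(start(target)[ti] - qs[i],
                                            qs[i] - end(target)[ti]))),
        "summit-to-summit" = min(abs(qs[i] - ts[ti])),
        "edge-to-edge" = min(pmax(0, pmax(start(target)[ti] - end(query)[i] - 1,
                                          start(query)[i] - end(target)[ti] - 1))))
    }
  }
  d
}

#' Fraction of query peaks within a distance of a target peak set
#'
#' By default measures summit-to-edge: the distance is 0 when the query
#' summit lies inside a target region, otherwise the bp to the nearest
#' target edge. Summit-to-summit and edge-to-edge are selectable.
#'
#' @param query,target non-empty enriched-region
#'   \link[GenomicRanges]{GRanges}.
#' @param d distance threshold in bp (default 300).
#' @param mode distance definition (default "summit-to-edge").
#' @return list with \code{n_query_peaks}, \code{n_within}, \code{fraction},
#'   \code{d} and \code{mode}.
#' @export
fractionWithin <- function(query, target, d = 300L,
                           mode = c("summit-to-edge", "summit-to-summit",
                                    "edge-to-edge")) {
  mode <- match.arg(mode)
  if (!length(query)) stop("query region set is empty")
  if (!length(target)) stop("target region set is empty")
  dist <- .proximityDistances(query, target, mode)
  nWithin <- sum(dist <= d)
  list(n_query_peaks = length(query), n_within = nWithin,
       fraction = nWithin / length(query), d = d, mode = mode)
}

#' Rank genes by number of enriched sites
#'
#' Genes with at least one site, ordered by descending site count with ties
#' broken lexicographically by gene id. Genes with five or more sites carry
#' \code{high = TRUE}, marking the heavily modified tier.
#'
#' @param assignments output of \code{\link{assignPeaksToGenes}}.
#' @param highCutoff site count from which a gene is flagged (default 5).
#' @return data.frame \code{gene_id}, \code{n_sites}, \code{high}, ranked.
#' @export
rankGenesBySiteCount <- function(assignments, highCutoff = 5L) {
  x <- assignments[assignments$n_sites > 0L, , drop = FALSE]
  x <- x[order(-x$n_sites, x$gene_id), c("gene_id", "n_sites")]
  x$high <- x$n_sites >= highCutoff
  rownames(x) <- NULL
  x
}

#' Export a ranked gene list in RNK convention
#'
#' Two tab-separated columns (gene id, score = site count), descending, no
#' header, suitable for external ranked-list enrichment tools.
#'
#' @param ranked output of \code{\link{rankGenesBySiteCount}}.
#' @param path output path.
#' @export
exportRnk <- function(ranked, path) {
  con <- .openWrite(path)
  on.exit(close(con))
  if (nrow(ranked))
    writeLines(sprintf("%s\t%d", ranked$gene_id, ranked$n_sites), con)
  invisible(path)
}

#' Fraction of one peak set overlapping another
#'
#' The fraction of regions in \code{setA} having at least 1 bp of
#' intersection with any region in \code{setB}; asymmetric by design.
#'
#' @param setA non-empty \link[GenomicRanges]{GRanges}.
#' @param setB \link[GenomicRanges]{GRanges}.
#' @return numeric fraction in [0, 1].
#' @export
peaksetOverlapFraction <- function(setA, setB) {
  if (!length(setA)) stop("setA is empty")
  if (!length(setB)) return(0)
  mean(countOverlaps(setA, setB, ignore.strand = TRUE) > 0L)
}

#' Compare expression between bound and unbound genes
#'
#' Splits genes into an unbound group (no site in the window) and bound
#' groups categorized by |min_tss_distance| with breaks
#' \code{distanceBreaks}; reports n, median and quartiles per group, a
#' two-sided rank-sum (Mann-Whitney) test of all bound vs unbound, and one
#' test per distance category against the unbound group. Groups with fewer
#' than two members are summarized but not tested (with a warning).
#'
#' @param expr data.frame \code{gene_id}, \code{log2_expr}.
#' @param assignments output of \code{\link{assignPeaksToGenes}}.
#' @param distanceBreaks increasing bp breaks for |min_tss_distance|
#'   categories (default c(0, 2000, 10000)).
#' @return list with \code{summary} (per-group stats) and \code{tests}
#'   (comparison, W, p).
#' @export
expressionByBinding <- function(expr, assignments,
                                distanceBreaks = c(0, 2000, 10000)) {
  m <- merge(assignments, expr, by = "gene_id")
  m$group <- "unbound"
  bound <- m$n_sites > 0L
  if (any(bound)) {
    lab <- paste0("<=", distanceBreaks[-1L], "bp")
    cats <- cut(abs(m$min_tss_distance[bound]), breaks = distanceBreaks,
                labels = lab, include.lowest = TRUE)
    m$group[bound] <- as.character(cats)
    m$group[bound & is.na(m$group)] <- paste0(">",
                                       distanceBreaks[length(distanceBreaks)],
                                       "bp")
  }
  groups <- split(m$log2_expr, m$group)
  summary <- do.call(rbind, lapply(names(groups), function(g) {
    v <- groups[[g]]
    data.frame(group = g, n = length(v), median = median(v),
               q25 = unname(quantile(v, 0.25)),
               q75 = unname(quantile(v, 0.75)))
  }))
  tests <- data.frame(comparison = character(), W = numeric(), p = numeric())
  unb <- m$log2_expr[!bound]
  runTest <- function(label, v) {
    if (length(v) < 2L || length(unb) < 2L) {
      warning("group too small for test: ", label)
      return(NULL)
    }
    w <- wilcox.test(v, unb, alternative = "two.sided", exact = FALSE)
    data.frame(comparison = label, W = unname(w$statistic), p = w$p.value)
  }
  tests <- rbind(tests, runTest("bound_vs_unbound", m$log2_expr[bound]))
  for (g in setdiff(names(groups), "unbound"))
    tests <- rbind(tests, runTest(paste0(g, "_vs_unbound"), groups[[g]]))
  list(summary = summary, tests = tests)
}
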