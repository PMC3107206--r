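## All files use 0-based half-open coordinates (BED convention); in-memory
## GRanges use the usual 1-based closed convention, converted at the boundary.
## gzip is handled transparently: paths ending in .gz are (de)compressed.

.openRead <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

.openWrite <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
}

.readTsvLines <- function(path) {
  con <- .openRead(path)
  on.exit(close(con))
  readLines(con)
}

.num <- function(x) suppressWarnings(as.numeric(x))

#' Read aligned reads from a BED-like file
#'
#' Accepts standard BED6 (chrom, start, end, name, score, strand) or a
#' compact 4-column dialect (chrom, start, end, strand). Every record is
#' validated; malformed coordinates or strands are reported with their line
#' number. Coordinates in the file are 0-based half-open.
#'
#' @param path input path (.gz transparently decompressed).
#' @param dialect "bed6" (default) or "bed4".
#' @param genome optional \link[GenomeInfoDb]{Seqinfo}; reads beyond a
#'   declared chromosome length are rejected.
#' @param dedup collapse duplicate (chrom, start, strand) triples when TRUE;
#'   by default duplicates are retained.
#' @return a strand-aware \link[GenomicRanges]{GRanges}; a warning is given
#'   for an empty file.
#' @export
readReads <- function(path, dialect = c("bed6", "bed4"), genome = NULL,
                      dedup = FALSE) {
  dialect <- match.arg(dialect)
  lines <- .readTsvLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("no reads in ", path)
    return(GRanges())
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  need <- if (dialect == "bed6") 6L else 4L
  nf <- lengths(parts)
  if (any(nf < need))
    stop(path, " line ", which(nf < need)[1L], ": expected >= ", need,
         " tab-separated fields")
  m <- matrix(unlist(lapply(parts, `[`, seq_len(need))), ncol = need,
              byrow = TRUE)
  chrom <- m[, 1L]
  s <- .num(m[, 2L]); e <- .num(m[, 3L])
  str <- m[, need]
  bad <- is.na(s) | is.na(e)
  if (any(bad))
    stop(path, " line ", which(bad)[1L], ": non-numeric coordinates")
  bad <- s >= e | s < 0
  if (any(bad))
    stop(path, " line ", which(bad)[1L],
         ": invalid interval (requires 0 <= start < end)")
  bad <- !(str %in% c("+", "-"))
  if (any(bad))
    stop(path, " line ", which(bad)[1L], ": unknown strand '",
         str[which(bad)[1L]], "'")
  if (!is.null(genome)) {
    sl <- seqlengths(genome)
    bad <- !(chrom %in% names(sl))
    if (any(bad))
      stop(path, " line ", which(bad)[1L], ": unknown chromosome '",
           chrom[which(bad)[1L]], "'")
    bad <- e > sl[chrom]
    if (any(bad))
      stop(path, " line ", which(bad)[1L], ": read extends past chromosome end")
  }
  gr <- GRanges(chrom, IRanges(s + 1, e), strand = str)
  if (!is.null(genome)) seqinfo(gr) <- genome
  if (dedup) {
    key <- paste(chrom, s, str)
    gr <- gr[!duplicated(key)]
  }
  message(length(gr), " reads loaded from ", path)
  gr
}

#' Write aligned reads as BED6
#'
#' @param reads a strand-aware \link[GenomicRanges]{GRanges}.
#' @param path output path (.gz transparently compressed).
#' @export
writeReads <- function(reads, path) {
  con <- .openWrite(path)
  on.exit(close(con))
  if (length(reads)) {
    writeLines(sprintf("%s\t%d\t%d\tr%d\t0\t%s",
                       as.character(seqnames(reads)), start(reads) - 1L,
                       end(reads), seq_along(reads),
                       as.character(strand(reads))), con)
  }
  invisible(path)
}

#' Write and read enriched regions as BED
#'
#' Regions are written sorted by (chrom, start). The fold enrichment is
#' serialized in the BED score column as \code{round(fold * 100)}; summit
#' position and the IP/control read counts travel in columns 7-9 so that a
#' read-back restores the full record. Coordinates on disk are 0-based
#' half-open.
#'
#' @param regions a \link[GenomicRanges]{GRanges} of enriched regions with
#'   metadata columns \code{fold} and optionally \code{summit},
#'   \code{ipReads}, \code{controlReads}.
#' @param path file path.
#' @return \code{readRegionsBed} returns the regions \code{GRanges};
#'   overlapping regions produce a warning, not an error.
#' @export
writeRegionsBed <- function(regions, path) {
  con <- .openWrite(path)
  on.exit(close(con))
  if (length(regions)) {
    o <- order(as.character(seqnames(regions)), start(regions))
    regions <- regions[o]
    fold <- mcols(regions)$fold
    if (is.null(fold)) fold <- rep(0, length(regions))
    summit <- mcols(regions)$summit
    if (is.null(summit)) summit <- floor((start(regions) + end(regions)) / 2)
    ipReads <- mcols(regions)$ipReads
    if (is.null(ipReads)) ipReads <- rep(0L, length(regions))
    ctrl <- mcols(regions)$controlReads
    if (is.null(ctrl)) ctrl <- rep(0L, length(regions))
    writeLines(sprintf("%s\t%d\t%d\tregion_%d\t%d\t.\t%d\t%d\t%d",
                       as.character(seqnames(regions)), start(regions) - 1L,
                       end(regions), seq_along(regions), round(fold * 100),
                       as.integer(summit) - 1L, as.integer(ipReads),
                       as.integer(ctrl)), con)
  }
  invisible(path)
}

#' @rdname writeRegionsBed
#' @export
readRegionsBed <- function(path) {
  lines <- .readTsvLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(GRanges())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 6L))
    stop(path, " line ", which(nf < 6L)[1L], ": expected >= 6 fields")
  ncolUse <- min(min(nf), 9L)
  m <- matrix(unlist(lapply(parts, `[`, seq_len(ncolUse))),
              ncol = ncolUse, byrow = TRUE)
  s <- .num(m[, 2L]); e <- .num(m[, 3L])
  bad <- is.na(s) | is.na(e) | s >= e
  if (any(bad)) stop(path, " line ", which(bad)[1L], ": invalid interval")
  gr <- GRanges(m[, 1L], IRanges(s + 1, e))
  mcols(gr)$fold <- .num(m[, 5L]) / 100
  if (ncol(m) >= 9L) {
    mcols(gr)$summit <- as.integer(.num(m[, 7L])) + 1L
    mcols(gr)$ipReads <- as.integer(.num(m[, 8L]))
    mcols(gr)$controlReads <- as.integer(.num(m[, 9L]))
  }
  gr <- gr[order(as.character(seqnames(gr)), start(gr))]
  hits <- findOverlaps(gr, gr)
  if (length(hits) > length(gr))
    warning("overlapping regions in ", path)
  gr
}

#' Write a bin track as bedGraph
#'
#' Runs of bins with equal value are merged into one line; zero bins are
#' omitted. With \code{normalize = TRUE}, counts are scaled to reads per
#' million fragments before writing.
#'
#' @param track a \linkS4class{BinTrack}.
#' @param path output path.
#' @param normalize write per-million values instead of raw counts.
#' @export
writeBedGraph <- function(track, path, normalize = FALSE) {
  con <- .openWrite(path)
  on.exit(close(con))
  bs <- binSize(track)
  sl <- seqlengths(seqinfo(track))
  for (ch in names(binCounts(track))) {
    v <- binCounts(track)[[ch]]
    if (normalize) {
      if (totalReads(track) <= 0) stop("cannot normalize an empty track")
      v <- v * 1e6 / totalReads(track)
    }
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values != 0
    if (!any(keep)) next
    bpStart <- (starts[keep] - 1L) * bs
    bpEnd <- pmin(ends[keep] * bs, sl[[ch]])
    writeLines(sprintf("%s\t%d\t%d\t%s", ch, bpStart, bpEnd,
                       format(r$values[keep], trim = TRUE, scientific = FALSE)),
               con)
  }
  invisible(path)
}

#' Write and read gene tables
#'
#' Tab-separated with header: gene_id, chrom, strand, tss (0-based bp).
#'
#' @param genes gene \link[GenomicRanges]{GRanges} (see
#'   \code{\link{geneRecords}}).
#' @param path file path.
#' @param genome optional \link[GenomeInfoDb]{Seqinfo} attached on read.
#' @export
writeGeneTable <- function(genes, path) {
  df <- data.frame(gene_id = mcols(genes)$gene_id,
                   chrom = as.character(seqnames(genes)),
                   strand = as.character(strand(genes)),
                   tss = start(genes) - 1L)
  con <- .openWrite(path)
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGeneTable
#' @export
readGeneTable <- function(path, genome = NULL) {
  con <- .openRead(path)
  on.exit(close(con))
  df <- read.table(con, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "tss")
  if (!all(need %in% names(df)))
    stop(path, ": gene table must have columns ",
         paste(need, collapse = ", "))
  geneRecords(df$gene_id, df$chrom, df$strand, df$tss, genome = genome)
}

#' Write and read expression tables
#'
#' Tab-separated with header: gene_id, log2_expr.
#'
#' @param expr data.frame with columns \code{gene_id}, \code{log2_expr}.
#' @param path file path.
#' @export
writeExpressionTable <- function(expr, path) {
  con <- .openWrite(path)
  on.exit(close(con))
  write.table(expr[, c("gene_id", "log2_expr")], con, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeExpressionTable
#' @export
readExpressionTable <- function(path) {
  con <- .openRead(path)
  on.exit(close(con))
  df <- read.table(con, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("gene_id", "log2_expr") %in% names(df)))
    stop(path, ": expression table must have columns gene_id, log2_expr")
  df
}

#' Read aligned reads from a SAM/BAM file (thin adapter)
#'
#' Extracts only (chrom, start, end, strand) of mapped reads via Rsamtools;
#' no CIGAR or quality interpretation. SAM input is converted on the fly.
#'
#' @param path a SAM or BAM file.
#' @return a strand-aware \link[GenomicRanges]{GRanges}.
#' @export
readReadsSam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("readReadsSam requires the Rsamtools package")
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE))
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "qwidth", "strand"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  x <- Rsamtools::scanBam(bam, param = p)[[1L]]
  keep <- !is.na(x$pos) & x$strand %in% c("+", "-")
  GRanges(as.character(x$rname)[keep],
          IRanges(x$pos[keep], width = x$qwidth[keep]),
          strand = as.character(x$strand)[keep])
}
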