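#' Default end-to-end demonstration configuration
#'
#' A complete run configuration on a small synthetic genome: a histone-mark
#' IP, a transcription-factor IP whose sites sit adjacent to a subset of
#' the mark's sites, a shared IgG control, an expression table shifted for
#' mark-bound genes, and a gene-category map in which the planted genes
#' form an enriched category. All numbers are chosen for statistical power
#' at desk scale.
#'
#' @param outDir run directory to create.
#' @param seed master seed; every stage seed derives from it.
#' @return a nested list accepted by \code{\link{runAll}}.
#' @export
demoConfig <- function(outDir = tempfile("adipochip_run_"), seed = 1L) {
  list(
    out_dir = outDir,
    seed = as.integer(seed),
    genome = list(chr1 = 6e6, chr2 = 4e6),
    simulate = list(
      n_genes = 400L, n_sites_mark = 60L, n_sites_tf = 40L,
      site_width = 1000L, tf_site_width = 300L, tf_offset = 300L,
      fold = 10, n_reads = 5e5, read_length = 36L,
      expression_shift = 1, expression_sd = 1
    ),
    peaks = list(extension = 200L, bin_size = 25L, p_threshold = 1e-9,
                 merge_gap = 200L, min_fold = 3, pseudocount = 1),
    annotate = list(window = 10000L),
    proximity = list(distance = 300L),
    coloc = list(window = 1500L, bin = 100L)
  )
}

.cfgPeakParams <- function(p) {
  peakParams(extension = p$extension %||% 200L,
             binSize = p$bin_size %||% 25L,
             pThreshold = p$p_threshold %||% 1e-9,
             mergeGap = p$merge_gap %||% 200L,
             minFold = p$min_fold %||% 3,
             pseudocount = p$pseudocount %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.validateConfig <- function(config) {
  if (is.null(config$out_dir)) stop("config error: out_dir is required")
  if (is.null(config$genome)) stop("config error: genome is required")
  if (is.null(config$simulate)) {
    inp <- config$inputs
    need <- c("ip_mark", "ip_tf", "control", "genes", "expression",
              "categories")
    for (f in need) {
      if (is.null(inp[[f]]))
        stop("config error: inputs$", f, " required when not simulating")
      if (!file.exists(inp[[f]]))
        stop("config error: input file missing: ", inp[[f]])
    }
  }
  invisible(TRUE)
}

## place TF sites adjacent to a subset of mark sites at a fixed offset
.tfSitesNearMark <- function(markSites, genome, n, width, offset, seed) {
  set.seed(seed)
  n <- min(n, length(markSites))
  pick <- sort(sample(seq_along(markSites), n))
  base <- markSites[pick]
  ctr <- end(base) + offset            # just downstream of the mark site
  s <- pmax(0L, ctr - width %/% 2L)
  sl <- seqlengths(genome)
  chs <- as.character(seqnames(base))
  plantedSites(chs, s, pmin(sl[chs], s + width),
               fold = rep(mcols(base)$fold[1L], n),
               label = sprintf("tf_%s", mcols(base)$label[pick]),
               genome = genome)
}

#' Run the whole pipeline from a single configuration
#'
#' Stages run in order: simulate (when \code{config$simulate} is present)
#' -> peak calling per IP sample -> gene annotation -> proximity ->
#' colocalization -> category enrichment -> report. Every stage consumes
#' and produces files under \code{out_dir}; a machine-readable
#' \code{summary.json} (stage counts, parameters, the derived minimum
#' Poisson count per sample, planted-truth recall/precision when
#' simulated) and a human-readable \code{report.txt} are written last.
#' Reruns with the same configuration and seed are bit-identical.
#'
#' @param config nested list (see \code{\link{demoConfig}}) or path to a
#'   YAML file with the same structure.
#' @param verbose emit stage messages.
#' @return (invisibly) the summary list written to \code{summary.json}.
#' @export
runAll <- function(config, verbose = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  .validateConfig(config)
  say <- if (verbose) message else function(...) invisible(NULL)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  seed <- as.integer(config$seed %||% 1L)
  genome <- simGenome(unlist(config$genome))
  params <- .cfgPeakParams(config$peaks %||% list())
  window <- config$annotate$window %||% 10000L
  proxD <- config$proximity$distance %||% 300L
  summary <- list(seed = seed,
                  genome = as.list(seqlengths(genome)),
                  parameters = list(
                    extension = params@extension, bin_size = params@binSize,
                    p_threshold = params@pThreshold,
                    merge_gap = params@mergeGap, min_fold = params@minFold,
                    annotation_window = window, proximity_distance = proxD))

  ## ---- stage: simulate (optional) ----
  if (!is.null(config$simulate)) {
    sc <- config$simulate
    say("[simulate] generating synthetic inputs")
    genes <- syntheticGeneTable(genome, sc$n_genes %||% 400L)
    markSites <- plantSitesNearTSS(genes, genome, sc$n_sites_mark %||% 60L,
                                   width = sc$site_width %||% 1000L,
                                   fold = sc$fold %||% 10,
                                   seed = seed)
    tfSites <- .tfSitesNearMark(markSites, genome, sc$n_sites_tf %||% 40L,
                                width = sc$tf_site_width %||% 300L,
                                offset = sc$tf_offset %||% 300L,
                                seed = seed + 1L)
    ## one shared non-random background: both IPs and the single IgG control
    ## draw the same hotspot patches, as one mock IP underlies all samples
    hot <- backgroundHotspots(genome, seed = seed + 10L)
    rsMark <- simulateReads(genome, markSites,
                            nReadsTarget = sc$n_reads %||% 5e5,
                            readLength = sc$read_length %||% 36L,
                            hotspots = hot, seed = seed + 2L)
    rsTf <- simulateReads(genome, tfSites,
                          nReadsTarget = sc$n_reads %||% 5e5,
                          readLength = sc$read_length %||% 36L,
                          hotspots = hot, seed = seed + 3L)
    writeReads(rsMark$ip, out("mark_ip.bed"))
    writeReads(rsTf$ip, out("tf_ip.bed"))
    writeReads(rsMark$control, out("igg_control.bed"))
    writeGeneTable(genes, out("genes.tsv"))
    bound <- mcols(genes)$gene_id %in% mcols(markSites)$gene_id
    expr <- simulateExpression(genes, bound,
                               shift = sc$expression_shift %||% 1,
                               noiseSd = sc$expression_sd %||% 1,
                               seed = seed + 4L)
    writeExpressionTable(expr, out("expression.tsv"))
    catMap <- data.frame(gene_id = mcols(markSites)$gene_id,
                         category = "planted_mark")
    writeEnrichmentTable(catMap, out("categories.tsv"))
    writeRegionsBed(markSites, out("truth_mark_sites.bed"))
    writeRegionsBed(tfSites, out("truth_tf_sites.bed"))
    inputs <- list(ip_mark = out("mark_ip.bed"), ip_tf = out("tf_ip.bed"),
                   control = out("igg_control.bed"), genes = out("genes.tsv"),
                   expression = out("expression.tsv"),
                   categories = out("categories.tsv"))
    summary$simulate <- list(n_genes = length(genes),
                             n_sites_mark = length(markSites),
                             n_sites_tf = length(tfSites),
                             n_reads_mark_ip = length(rsMark$ip),
                             n_reads_tf_ip = length(rsTf$ip),
                             n_reads_control = length(rsMark$control))
  } else {
    inputs <- config$inputs
    markSites <- tfSites <- NULL
  }

  ## ---- stage: peak calling per sample ----
  genes <- readGeneTable(inputs$genes, genome = genome)
  control <- readReads(inputs$control, genome = genome)
  peaks <- list()
  for (sample in c("mark", "tf")) {
    say("[callpeaks] sample: ", sample)
    ip <- readReads(inputs[[paste0("ip_", sample)]], genome = genome)
    pk <- callPeaks(ip, control, genome, params, verbose = verbose)
    writeRegionsBed(pk, out(sprintf("%s_peaks.bed", sample)))
    writeBedGraph(extendAndBin(ip, genome, params),
                  out(sprintf("%s_coverage.bedgraph", sample)))
    md <- S4Vectors::metadata(pk)
    summary[[paste0("peaks_", sample)]] <-
      list(n_reads = length(ip), lambda = md$lambda,
           min_count = md$minCount, n_regions = length(pk))
    peaks[[sample]] <- pk
  }
  if (!is.null(markSites)) {
    rec <- plantedRecovery(peaks$mark, markSites)
    summary$recovery_mark <- rec
    say(sprintf("[callpeaks] mark recall %.3f precision %.3f",
                rec$recall, rec$precision))
  }

  ## ---- stage: annotate ----
  say("[annotate] assigning mark peaks to genes (window ", window, " bp)")
  assign <- assignPeaksToGenes(peaks$mark, genes, window)
  write.table(assign, out("assignments.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  ranked <- rankGenesBySiteCount(assign)
  exportRnk(ranked, out("ranked_genes.rnk"))
  hist10 <- tssDistanceHistogram(peaks$mark, genes)
  write.table(hist10, out("tss_distance_histogram.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  summary$annotate <- list(n_genes = nrow(assign),
                           n_bound = sum(assign$n_sites > 0),
                           n_high = sum(ranked$high))

  ## ---- stage: proximity ----
  if (length(peaks$tf) && length(peaks$mark)) {
    prox <- fractionWithin(peaks$tf, peaks$mark, proxD)
    write.table(as.data.frame(prox), out("proximity.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    summary$proximity <- prox
    ovl <- peaksetOverlapFraction(peaks$tf, peaks$mark)
    summary$overlap_fraction_tf_in_mark <- ovl
  }

  ## ---- stage: colocalize ----
  ancs <- colocalizationAnchors(peaks$tf, list(peaks$mark),
                                span = config$coloc$window %||% 1500L)
  summary$coloc <- list(n_anchors = length(ancs))
  if (length(ancs) >= 2L) {
    ipTf <- readReads(inputs$ip_tf, genome = genome)
    ipMark <- readReads(inputs$ip_mark, genome = genome)
    mTf <- extractWindowSignal(ancs, ipTf, genome,
                               window = config$coloc$window %||% 1500L,
                               bin = config$coloc$bin %||% 100L,
                               label = "tf")
    mMark <- extractWindowSignal(anchors(mTf), ipMark, genome,
                                 window = config$coloc$window %||% 1500L,
                                 bin = config$coloc$bin %||% 100L,
                                 label = "mark")
    writeSignalMatrix(mTf, out("signal_tf.tsv"))
    writeSignalMatrix(mMark, out("signal_mark.tsv"))
    writeSignalMatrix(mMark, out("signal_mark_zscore.tsv"), zscore = TRUE)
    recs <- pairwiseLocationCorrelation(mTf, mMark)
    write.table(recs, out("correlations.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    ch <- correlationHistogram(recs)
    write.table(ch, out("correlation_histogram.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    summary$coloc$n_valid <- sum(recs$valid)
    summary$coloc$median_r <- median(recs$r[recs$valid])
  }

  ## ---- stage: expression association ----
  expr <- readExpressionTable(inputs$expression)
  eb <- expressionByBinding(expr, assign)
  write.table(eb$summary, out("expression_groups.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(eb$tests, out("expression_tests.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  bt <- eb$tests[eb$tests$comparison == "bound_vs_unbound", ]
  summary$expression <- list(
    p_bound_vs_unbound = if (nrow(bt)) bt$p else NA_real_)

  ## ---- stage: enrich ----
  catMap <- readCategoryMap(inputs$categories)
  boundGenes <- assign$gene_id[assign$n_sites > 0]
  enr <- hypergeometricEnrichment(boundGenes, catMap, assign$gene_id)
  writeEnrichmentTable(enr, out("enrichment.tsv"))
  summary$enrichment <- list(top_category = enr$category[1L],
                             top_p = enr$p[1L])

  ## ---- stage: report ----
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  yaml::write_yaml(config, out("config_used.yaml"))
  rpt <- c(
    "adipoChIP pipeline run",
    sprintf("seed: %d", seed),
    sprintf("mark sample: %d regions (min count %d)",
            summary$peaks_mark$n_regions, summary$peaks_mark$min_count),
    sprintf("tf sample: %d regions (min count %d)",
            summary$peaks_tf$n_regions, summary$peaks_tf$min_count),
    sprintf("genes with >=1 mark site within %d bp of TSS: %d of %d",
            window, summary$annotate$n_bound, summary$annotate$n_genes))
  if (!is.null(summary$proximity))
    rpt <- c(rpt, sprintf(
      "tf peaks within %d bp of a mark site: %d of %d (%.1f%%)",
      proxD, summary$proximity$n_within, summary$proximity$n_query_peaks,
      100 * summary$proximity$fraction))
  if (!is.null(summary$recovery_mark))
    rpt <- c(rpt, sprintf("planted recovery (mark): recall %.3f precision %.3f",
                          summary$recovery_mark$recall,
                          summary$recovery_mark$precision))
  writeLines(rpt, out("report.txt"))
  say("[report] run complete: ", config$out_dir)
  invisible(summary)
}
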