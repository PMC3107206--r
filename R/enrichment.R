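#' Exact hypergeometric category enrichment of a gene set
#'
#' For each category with K genes in the universe (size N), a query set of
#' n genes containing k category members gets the exact upper-tail
#' probability p = sum_{i >= k} C(K,i) C(N-K, n-i) / C(N,n) of drawing at
#' least k category genes without replacement. Both Bonferroni and
#' Benjamini-Hochberg adjustments across categories are reported.
#'
#' @param setGenes character vector, the query gene set (subset of
#'   \code{universe}).
#' @param categoryMap data.frame with columns \code{gene_id} and
#'   \code{category}; genes outside the universe are rejected.
#' @param universe character vector of all genes considered.
#' @return data.frame, one row per category, with k, n, K, N, \code{p},
#'   \code{p_bonferroni}, \code{p_bh}, sorted by p ascending.
#' @examples
#' u <- sprintf("g%02d", 1:10)
#' cm <- data.frame(gene_id = u[1:5], category = "tf")
#' hypergeometricEnrichment(u[c(1, 2, 3, 4)], cm, u)  # p = 5/210
#' @export
hypergeometricEnrichment <- function(setGenes, categoryMap, universe) {
  setGenes <- unique(as.character(setGenes))
  universe <- unique(as.character(universe))
  offenders <- setdiff(setGenes, universe)
  if (length(offenders))
    stop("set genes not in universe: ", paste(offenders, collapse = ", "))
  offenders <- setdiff(unique(categoryMap$gene_id), universe)
  if (length(offenders))
    stop("category genes not in universe: ",
         paste(offenders, collapse = ", "))
  N <- length(universe)
  n <- length(setGenes)
  cats <- split(as.character(categoryMap$gene_id), categoryMap$category)
  rows <- lapply(names(cats), function(cc) {
    members <- unique(cats[[cc]])
    K <- length(members)
    k <- length(intersect(members, setGenes))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(category = cc, k = k, n = n, K = K, N = N, p = p)
  })
  res <- do.call(rbind, rows)
  res$p_bonferroni <- p.adjust(res$p, "bonferroni")
  res$p_bh <- p.adjust(res$p, "BH")
  res <- res[order(res$p, res$category), ]
  rownames(res) <- NULL
  res
}

#' Write enrichment results as TSV
#'
#' @param results output of \code{\link{hypergeometricEnrichment}}.
#' @param path output path.
#' @export
writeEnrichmentTable <- function(results, path) {
  con <- .openWrite(path)
  on.exit(close(con))
  write.table(results, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column gene-to-category map
#'
#' Tab-separated, columns \code{gene_id} and \code{category}, with header.
#'
#' @param path input path.
#' @return data.frame with those two columns.
#' @export
readCategoryMap <- function(path) {
  con <- .openRead(path)
  on.exit(close(con))
  df <- read.table(con, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("gene_id", "category") %in% names(df)))
    stop(path, ": category map must have columns gene_id, category")
  df
}
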