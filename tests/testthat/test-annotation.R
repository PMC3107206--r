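test_that("peaks assign to genes by summit-TSS distance within the window", {
  genes <- geneRecords("g1", "chr1", "+", 5000)
  mkRegion <- function(summit) {
    gr <- GRanges("chr1", IRanges(summit - 199, summit + 200))
    mcols(gr)$summit <- summit
    gr
  }
  ## summit 12000, TSS 5000 (0-based): distance 7000 <= 10000 -> assigned
  a <- assignPeaksToGenes(mkRegion(12001), genes, 10000)
  expect_equal(a$n_sites, 1L)
  expect_equal(a$min_tss_distance, 7000)
  ## summit 16000: distance 11000 -> not assigned
  a <- assignPeaksToGenes(mkRegion(16001), genes, 10000)
  expect_equal(a$n_sites, 0L)
  expect_true(is.na(a$min_tss_distance))
  ## empty region list -> all genes zero
  a <- assignPeaksToGenes(GRanges(), genes)
  expect_equal(a$n_sites, 0L)
  ## minus-strand gene: downstream summit gives negative upstream distance
  gm <- geneRecords("g2", "chr1", "-", 5000)
  a <- assignPeaksToGenes(mkRegion(8001), gm, 10000)
  expect_equal(a$min_tss_distance, -3000)
})

test_that("gene assignment agrees exactly with the all-pairs oracle", {
  set.seed(101)
  for (rep in 1:20) {
    nR <- sample(0:60, 1)
    nG <- sample(1:60, 1)
    regions <- if (nR > 0) randomRegions(nR, 5e4) else GRanges()
    genes <- randomGenes(nG, 5e4)
    w <- sample(c(2000, 5000, 10000), 1)
    got <- assignPeaksToGenes(regions, genes, w)
    want <- bruteAssign(regions, genes, w)
    expect_identical(got$n_sites, want$n_sites)
    expect_equal(got$min_tss_distance, want$min_tss_distance)
  }
})

test_that("TSS distance histogram puts mass where summits fall", {
  genes <- geneRecords("g1", "chr1", "+", 50000)
  r <- GRanges("chr1", IRanges(50001, 50001))
  mcols(r)$summit <- 50001L
  h <- tssDistanceHistogram(r, genes, range = 1000, bin = 100)
  expect_equal(sum(h$count), 1)
  expect_equal(h$count[h$lower == 0], 1)
  ## normalization scales the tallest bin to exactly 1
  hn <- tssDistanceHistogram(r, genes, range = 1000, bin = 100,
                             normalize = TRUE)
  expect_equal(max(hn$value), 1)
  expect_error(tssDistanceHistogram(r, GRanges()[0], range = 1000, bin = 100),
               "empty")
  expect_error(tssDistanceHistogram(r, genes, range = 1000, bin = 300),
               "divide")
})

test_that("histogram counts sum to the summits inside the range", {
  set.seed(7)
  genes <- randomGenes(30, 1e5)
  regions <- randomRegions(200, 1e5)
  h <- tssDistanceHistogram(regions, genes, range = 10000, bin = 100)
  ## every summit within +/- range of its nearest TSS lands in one bin
  summit <- mcols(regions)$summit
  tss <- start(genes)
  nin <- sum(vapply(summit, function(s) {
    i <- which.min(abs(tss - s))
    d <- (s - tss[i]) * (if (as.character(strand(genes))[i] == "-") -1 else 1)
    d >= -10000 && d < 10000
  }, logical(1)))
  expect_equal(sum(h$count), nin)
})

test_that("fractionWithin matches enumeration and the all-pairs oracle", {
  target <- GRanges("chr1", IRanges(1001, 2000))
  mcols(target)$summit <- 1500L
  mkQ <- function(summits) {
    gr <- GRanges("chr1", IRanges(summits, summits))
    mcols(gr)$summit <- summits
    gr
  }
  ## distances {0 (inside), 100, 500} with d = 300 -> fraction 2/3
  q <- mkQ(c(1500L, 2100L, 2500L))
  fw <- fractionWithin(q, target, 300)
  expect_equal(fw$fraction, 2 / 3)
  expect_equal(fw$n_within, 2L)
  ## monotone in d
  expect_lte(fractionWithin(q, target, 100)$fraction,
             fractionWithin(q, target, 300)$fraction)
  expect_lte(fractionWithin(q, target, 300)$fraction,
             fractionWithin(q, target, 1000)$fraction)
  ## summit inside target counts as distance zero
  expect_equal(fractionWithin(mkQ(1500L), target, 0)$fraction, 1)
  expect_error(fractionWithin(q, GRanges()), "empty")
  expect_error(fractionWithin(GRanges(), target), "empty")
  ## oracle equivalence on random instances
  set.seed(55)
  for (rep in 1:20) {
    q <- randomRegions(sample(1:50, 1), 5e4)
    t2 <- randomRegions(sample(1:50, 1), 5e4)
    d <- sample(c(0, 100, 300, 1000), 1)
    expect_equal(fractionWithin(q, t2, d)$fraction,
                 bruteFractionWithin(q, t2, d))
  }
})

test_that("alternative proximity modes are selectable", {
  target <- GRanges("chr1", IRanges(1001, 2000))
  mcols(target)$summit <- 1500L
  q <- GRanges("chr1", IRanges(2101, 2300))
  mcols(q)$summit <- 2200L
  ## summit-to-edge: 2200 - 2000 = 200; summit-to-summit: 700
  expect_equal(fractionWithin(q, target, 300)$fraction, 1)
  expect_equal(fractionWithin(q, target, 300,
                              mode = "summit-to-summit")$fraction, 0)
  ## edge-to-edge: gap 2101 - 2000 - 1 = 100
  expect_equal(fractionWithin(q, target, 100,
                              mode = "edge-to-edge")$fraction, 1)
})

test_that("genes rank by site count with lexicographic tie-break", {
  a <- data.frame(gene_id = c("A", "B", "C", "D"),
                  n_sites = c(5L, 2L, 5L, 0L),
                  min_tss_distance = c(0, 0, 0, NA))
  r <- rankGenesBySiteCount(a)
  expect_equal(r$gene_id, c("A", "C", "B"))   # D (0 sites) dropped
  expect_equal(r$high, c(TRUE, TRUE, FALSE))
  expect_equal(nrow(rankGenesBySiteCount(
    data.frame(gene_id = "X", n_sites = 0L, min_tss_distance = NA))), 0)
  f <- tempfile(fileext = ".rnk")
  exportRnk(r, f)
  expect_equal(readLines(f), c("A\t5", "C\t5", "B\t2"))
})

test_that("peak-set overlap fraction follows half-open intersection", {
  a <- GRanges("chr1", IRanges(101, 200))   # [100,200) 0-based
  b <- GRanges("chr1", IRanges(200, 300))   # [199,300) -> 1 bp overlap
  expect_equal(peaksetOverlapFraction(a, b), 1)
  expect_equal(peaksetOverlapFraction(a, a), 1)
  expect_equal(suppressWarnings(peaksetOverlapFraction(
    a, GRanges("chr2", IRanges(101, 200)))), 0)
  ## order invariance and asymmetry
  many <- GRanges("chr1", IRanges(c(101, 5001, 9001), width = 100))
  expect_equal(peaksetOverlapFraction(many, a), 1 / 3)
  set.seed(1)
  expect_equal(peaksetOverlapFraction(many[sample(3)], a), 1 / 3)
  expect_error(peaksetOverlapFraction(GRanges(), a), "empty")
})

test_that("expression comparison detects the planted shift and the null", {
  ids <- sprintf("g%03d", 1:400)
  assigns <- data.frame(gene_id = ids,
                        n_sites = rep(c(1L, 0L), each = 200),
                        min_tss_distance = c(rep(500, 200), rep(NA, 200)))
  ## clear shift: medians differ by ~2, p tiny
  expr <- simulateExpression(ids, assigns$n_sites > 0, shift = 2,
                             noiseSd = 0.5, seed = 4)
  out <- expressionByBinding(expr, assigns)
  su <- out$summary
  expect_equal(su$median[su$group == "<=2000bp"] -
                 su$median[su$group == "unbound"], 2, tolerance = 0.2)
  expect_lt(out$tests$p[out$tests$comparison == "bound_vs_unbound"], 1e-15)
  ## null: identical distributions give an unremarkable p
  expr0 <- simulateExpression(ids, rep(FALSE, 400), shift = 0, noiseSd = 1,
                              seed = 5)
  out0 <- expressionByBinding(expr0, assigns)
  expect_gt(out0$tests$p[out0$tests$comparison == "bound_vs_unbound"], 0.001)
  ## a single bound gene is summarized but not tested
  a1 <- data.frame(gene_id = ids, n_sites = c(1L, rep(0L, 399)),
                   min_tss_distance = c(100, rep(NA, 399)))
  w <- capture_warnings(out1 <- expressionByBinding(expr, a1))
  expect_true(length(w) >= 1 && all(grepl("too small", w)))
  expect_true("<=2000bp" %in% out1$summary$group)
  expect_false("bound_vs_unbound" %in% out1$tests$comparison)
})
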