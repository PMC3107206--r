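mkWsm <- function(values, centers = NULL, chrom = "chr1", label = "s") {
  values <- rbind(values)
  if (is.null(centers)) centers <- 10000L + 5000L * seq_len(nrow(values))
  new("WindowSignalMatrix",
      anchors = GRanges(chrom, IRanges(as.integer(centers), width = 1L)),
      values = values, windowSize = 100L * ncol(values), binSize = 100L,
      sample = label, totalReads = 1e6)
}

test_that("window signal is per-million normalized fragment counts", {
  g <- simGenome(c(chr1 = 1e5))
  anchor <- GRanges("chr1", IRanges(50001, width = 1))
  ## one long read whose 1500-bp span covers the whole window, plus distant
  ## reads to set the depth; extension beyond read length is irrelevant here
  covering <- GRanges("chr1", IRanges(49000, 52000), strand = "+")
  distant <- GRanges("chr1", IRanges(rep(5000, 9), width = 36),
                     strand = "+")
  reads <- c(covering, distant)
  m <- extractWindowSignal(anchor, reads, g, window = 1500, bin = 100,
                           extension = 3001)
  ## 10 fragments total: every covered bin = 1 * 1e6 / 10
  expect_true(all(signalValues(m) == 1e6 / 10))
  ## doubling every read leaves per-million values unchanged
  m2 <- extractWindowSignal(anchor, c(reads, reads), g, window = 1500,
                            bin = 100, extension = 3001)
  expect_equal(signalValues(m2), signalValues(m))
  ## no reads in the window -> zero vector
  m0 <- extractWindowSignal(anchor, distant, g, window = 1500, bin = 100)
  expect_true(all(signalValues(m0) == 0))
  expect_error(extractWindowSignal(anchor, GRanges(), g), "empty")
})

test_that("anchors too close to a chromosome end are dropped with warning", {
  g <- simGenome(c(chr1 = 2000))
  anchors2 <- GRanges("chr1", IRanges(c(300L, 1000L), width = 1))
  reads <- GRanges("chr1", IRanges(900, 935), strand = "+")
  expect_warning(m <- extractWindowSignal(anchors2, reads, g, window = 1500),
                 "dropped")
  expect_length(anchors(m), 1)
})

test_that("per-anchor correlation identities hold exactly", {
  ramp <- matrix(as.numeric(1:15), nrow = 1)
  m1 <- mkWsm(rbind(ramp, ramp, c(rep(0, 14), 15)))
  m2 <- mkWsm(rbind(ramp, ramp[, 15:1, drop = FALSE], rep(2, 15)))
  rec <- pairwiseLocationCorrelation(m1, m2)
  expect_equal(rec$r[1], 1)      # identical nonconstant vectors
  expect_equal(rec$r[2], -1)     # reversed ramp
  expect_false(rec$valid[3])     # constant vector in one sample
  expect_true(is.na(rec$r[3]))
  ## symmetry
  rec2 <- pairwiseLocationCorrelation(m2, m1)
  expect_equal(rec$r, rec2$r)
  ## mismatched anchors are rejected
  m3 <- mkWsm(ramp, centers = 999L)
  expect_error(pairwiseLocationCorrelation(m1, m3), "anchor")
})

test_that("histogram of correlations excludes invalid records", {
  rec <- data.frame(chrom = "chr1", center = 1:3,
                    r = c(0.95, -0.85, NA), valid = c(TRUE, TRUE, FALSE))
  h <- correlationHistogram(rec)
  expect_equal(sum(h$count), 2)
  expect_equal(h$count[which(abs(h$lower - 0.9) < 1e-9)], 1)
})

test_that("Z-scoring standardizes rows and flags constants", {
  v <- rbind(as.numeric(1:15), rep(3, 15), c(rep(0, 14), 15 * 7))
  z <- zscoreMatrix(v)
  expect_equal(rowMeans(z)[1], 0)
  expect_equal(sqrt(mean((z[1, ] - mean(z[1, ]))^2)), 1)  # population sd 1
  expect_true(all(z[2, ] == 0))
  expect_equal(attr(z, "constantRows"), 2L)
  ## one-hot row: max Z = sqrt(14) regardless of scale
  expect_equal(max(z[3, ]), sqrt(14))
  z2 <- zscoreMatrix(rbind(c(rep(0, 14), 15 * 1000)))
  expect_equal(max(z2[1, ]), sqrt(14))
})

test_that("correlation is invariant under per-row affine transforms", {
  set.seed(77)
  v1 <- matrix(rpois(10 * 15, 5), nrow = 10) * 1.0
  v2 <- matrix(rpois(10 * 15, 5), nrow = 10) * 1.0
  m1 <- mkWsm(v1); m2 <- mkWsm(v2)
  raw <- pairwiseLocationCorrelation(m1, m2)
  ## z-score then correlate equals correlating raw vectors (shifted to stay
  ## non-negative; correlation is affine-invariant per row)
  zm1 <- mkWsm(zscoreMatrix(v1) - min(zscoreMatrix(v1)))
  zm2 <- mkWsm(zscoreMatrix(v2) - min(zscoreMatrix(v2)))
  zr <- pairwiseLocationCorrelation(zm1, zm2)
  expect_equal(zr$r, raw$r, tolerance = 1e-12)
})

test_that("coincident planted sites correlate; offset sites anticorrelate", {
  g <- simGenome(c(chr1 = 2e6))
  centers <- seq(1e5, 1.9e6, by = 6e4)
  w <- 300
  sitesA <- plantedSites("chr1", centers - w / 2, centers + w / 2,
                         fold = 20, genome = g)
  ## offset each partner site by 500 bp (within the 300-700 bp band)
  sitesB <- plantedSites("chr1", centers + 500 - w / 2, centers + 500 + w / 2,
                         fold = 20, genome = g)
  rsA <- simulateReads(g, sitesA, nReadsTarget = 4e5, hotspotDensity = 0,
                       seed = 61)
  rsAsame <- simulateReads(g, sitesA, nReadsTarget = 4e5, hotspotDensity = 0,
                           seed = 62)
  rsB <- simulateReads(g, sitesB, nReadsTarget = 4e5, hotspotDensity = 0,
                       seed = 63)
  anchorPts <- GRanges("chr1", IRanges(as.integer(centers + 1), width = 1))
  mA <- extractWindowSignal(anchorPts, rsA$ip, g, label = "A")
  mSame <- extractWindowSignal(anchorPts, rsAsame$ip, g, label = "A2")
  mOff <- extractWindowSignal(anchorPts, rsB$ip, g, label = "B")
  same <- pairwiseLocationCorrelation(mA, mSame)
  off <- pairwiseLocationCorrelation(mA, mOff)
  fracHighSame <- mean(same$r[same$valid] > 0.5)
  fracHighOff <- mean(off$r[off$valid] > 0.5)
  expect_gt(fracHighSame, fracHighOff)
  expect_lt(median(off$r[off$valid]), 0)   # predominantly negative
  expect_gt(fracHighSame, 0.5)
})

test_that("anchor selection keeps strong colocalized summits apart", {
  mkPeaks <- function(summits, strength) {
    gr <- GRanges("chr1", IRanges(summits - 100L, summits + 100L))
    mcols(gr)$summit <- summits
    mcols(gr)$ipReads <- strength
    gr
  }
  anchorsP <- mkPeaks(c(10000L, 10400L, 50000L, 90000L), c(50L, 80L, 60L, 70L))
  other <- mkPeaks(c(10500L, 50100L), c(10L, 10L))
  sel <- colocalizationAnchors(anchorsP, list(other), span = 1500L)
  ## 10400 beats 10000 (stronger, within span); 90000 has no partner
  expect_equal(start(sel), c(10400L, 50000L))
})

test_that("heatmap row ordering supports strength and clustering", {
  set.seed(12)
  v <- matrix(rpois(8 * 15, 4), nrow = 8) * 1.0
  m <- mkWsm(v)
  expect_equal(heatmapRowOrder(m), order(-rowSums(v)))
  o <- heatmapRowOrder(m, "hclust")
  expect_setequal(o, 1:8)
})
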