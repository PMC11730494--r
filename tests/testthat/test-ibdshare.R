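test_that("Beagle-style IBD files parse with pair normalisation", {
  f <- withr::local_tempfile(lines = "A\t1\tB\t1\t17\t100\t200\t3.0")
  segs <- readIbd(f)
  expect_equal(length(segs), 1L)
  expect_equal(segs$sample1, "A")
  expect_equal(segs$sample2, "B")
  expect_equal(GenomicRanges::start(segs), 100L)
  expect_equal(GenomicRanges::end(segs), 200L)
  expect_equal(segs$score, 3.0)

  # (A,B) and (B,A) normalise to the same pair key
  f2 <- withr::local_tempfile(lines = c(
    "A\t1\tB\t1\t17\t100\t200\t3.0",
    "B\t2\tA\t1\t17\t300\t400\t2.0"))
  segs2 <- readIbd(f2)
  expect_equal(segs2$sample1, c("A", "A"))
  expect_equal(segs2$sample2, c("B", "B"))

  f3 <- withr::local_tempfile(lines = "A\t1\tB\t1\t17\t500\t400\t3.0")
  expect_error(readIbd(f3), "line")
})

test_that("IBD segments round-trip through write and read", {
  gr <- GenomicRanges::GRanges(c("1", "17"),
                               IRanges::IRanges(c(10, 100), c(500, 9000)))
  gr$sample1 <- c("A", "B"); gr$sample2 <- c("C", "C")
  gr$score <- c(4.2, NA)
  f <- withr::local_tempfile()
  writeIbd(gr, f)
  back <- readIbd(f)
  expect_equal(as.character(GenomicRanges::seqnames(back)),
               as.character(GenomicRanges::seqnames(gr)))
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(gr))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(gr))
  expect_equal(back$sample1, gr$sample1)
  expect_equal(back$score, gr$score)
})

test_that("three pairwise segments intersect to the common core", {
  segs <- GenomicRanges::GRanges("7", IRanges::IRanges(
    c(100, 200, 250), c(300, 400, 350)))
  segs$sample1 <- c("A", "A", "B")
  segs$sample2 <- c("B", "C", "C")
  sr <- sharedRegions(segs, c("A", "B", "C"))
  expect_equal(GenomicRanges::start(sr), 250L)
  expect_equal(GenomicRanges::end(sr), 300L)
  expect_setequal(sr$supportingPairs[[1]], c("A|B", "A|C", "B|C"))
  # agreement with the per-base membership oracle
  brute <- sharedRegionsBrute(segs, c("A", "B", "C"), maxPos = 500)
  expect_equal(GenomicRanges::start(sr), GenomicRanges::start(brute))
  expect_equal(GenomicRanges::end(sr), GenomicRanges::end(brute))
  # a pair with no segment on the chromosome empties the result
  expect_equal(length(sharedRegions(segs[1:2], c("A", "B", "C"))), 0L)
  # two-sample identity case
  sr2 <- sharedRegions(segs[1], c("A", "B"))
  expect_equal(GenomicRanges::start(sr2), 100L)
  expect_equal(GenomicRanges::end(sr2), 300L)
  expect_error(sharedRegions(segs, "A"), "at least 2")
})

test_that("shared regions equal the per-base oracle on random instances", {
  set.seed(303)
  for (rep in 1:15) {
    samples <- LETTERS[1:sample(3:4, 1)]
    prs <- combn(samples, 2)
    segs <- list()
    for (j in seq_len(ncol(prs))) {
      nSeg <- sample(0:4, 1)
      if (nSeg == 0) next
      lo <- sample(1:9000, nSeg)
      hi <- pmin(lo + sample(50:3000, nSeg, replace = TRUE), 10000L)
      gr <- GenomicRanges::GRanges(sample(c("1", "2"), 1),
                                   IRanges::IRanges(lo, hi))
      gr$sample1 <- rep(prs[1, j], nSeg)
      gr$sample2 <- rep(prs[2, j], nSeg)
      segs[[length(segs) + 1L]] <- gr
    }
    if (length(segs) == 0) next
    segs <- suppressWarnings(do.call(c, segs))
    for (mp in c(NA, 2)) {
      minPairs <- if (is.na(mp)) NULL else mp
      sr <- sharedRegions(segs, samples, minPairs = minPairs)
      brute <- sharedRegionsBrute(segs, samples, maxPos = 10000L,
                                  minPairs = minPairs)
      expect_equal(as.character(GenomicRanges::seqnames(sr)),
                   as.character(GenomicRanges::seqnames(brute)))
      expect_equal(GenomicRanges::start(sr), GenomicRanges::start(brute))
      expect_equal(GenomicRanges::end(sr), GenomicRanges::end(brute))
      # output intervals disjoint and sorted
      if (length(sr) > 1) {
        expect_false(any(duplicated(as.character(GenomicRanges::seqnames(sr))) &
          GenomicRanges::start(sr) <= c(0, GenomicRanges::end(sr)[-length(sr)])))
      }
    }
  }
})

test_that("pairwise sharing of a pair's own segments is the merged identity", {
  segs <- GenomicRanges::GRanges("3", IRanges::IRanges(c(100, 250, 800),
                                                       c(300, 400, 900)))
  segs$sample1 <- rep("A", 3); segs$sample2 <- rep("B", 3)
  sr <- sharedRegions(segs, c("A", "B"))
  merged <- GenomicRanges::reduce(segs)
  expect_equal(GenomicRanges::start(sr), GenomicRanges::start(merged))
  expect_equal(GenomicRanges::end(sr), GenomicRanges::end(merged))
})

test_that("variant and gene overlap respects inclusive boundaries", {
  region <- GenomicRanges::GRanges("17", IRanges::IRanges(250, 300))
  av <- makeVariants(list(rep("het", 2), rep("het", 2), rep("het", 2)),
                     samples = c("X", "Y"), chrom = "17",
                     pos = c(275L, 300L, 301L),
                     gene = c("G1", "G2", "G3"))
  expect_equal(overlapsRegion(region, av, mode = "position"),
               c(TRUE, TRUE, FALSE))
  spans <- GenomicRanges::GRanges("17", IRanges::IRanges(
    c(240, 500, 100), c(260, 600, 200)))
  names(spans) <- c("G1", "G2", "G3")
  expect_equal(overlapsRegion(region, av, geneSpans = spans, mode = "gene"),
               c(TRUE, FALSE, FALSE))
  # gene missing from the span table is non-overlapping, with a message
  expect_message(
    res <- overlapsRegion(region, av, geneSpans = spans[1:2], mode = "gene"),
    "without a span")
  expect_equal(res, c(TRUE, FALSE, FALSE))
})

test_that("gene spans round-trip through TSV and BED", {
  spans <- GenomicRanges::GRanges(c("1", "17"),
                                  IRanges::IRanges(c(1000, 5000), c(2000, 9000)))
  names(spans) <- c("GA", "GB")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeGeneSpans(spans, f)
  back <- readGeneSpans(f)
  expect_equal(names(back), names(spans))
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(spans))
  # BED input converts 0-based half-open to 1-based inclusive
  bed <- withr::local_tempfile(lines = "17\t999\t2000\tGC")
  b <- readGeneSpans(bed)
  expect_equal(GenomicRanges::start(b), 1000L)
  expect_equal(GenomicRanges::end(b), 2000L)
})

# -- naive exclusion scan ------------------------------------------------

simulateSibPair <- function(nMark, af, tract = NULL, errRate = 0.001) {
  shared <- rbinom(nMark, 1, af)
  g <- matrix(NA_real_, nMark, 2)
  for (s in 1:2) {
    own <- rbinom(nMark, 1, af)
    other <- rbinom(nMark, 1, af)
    hap1 <- other
    if (!is.null(tract)) hap1[tract] <- shared[tract]
    g[, s] <- hap1 + own
  }
  err <- matrix(runif(nMark * 2) < errRate, nMark, 2)
  g[err] <- sample(0:2, sum(err), replace = TRUE)
  g
}

test_that("the naive scan recovers a planted shared tract", {
  set.seed(404)
  nMark <- 2000L
  positions <- seq(10000L, by = 10000L, length.out = nMark)
  tract <- 501:1500 # 10 Mb of the 20 Mb chromosome
  hits <- 0L
  for (rep in 1:30) {
    g <- simulateSibPair(nMark, af = 0.25, tract = tract)
    segs <- naiveIbdScan(g, positions, chrom = "17", window = 300L,
                         maxOppositeHom = 2L)
    truthRange <- IRanges::IRanges(positions[min(tract)], positions[max(tract)])
    if (length(segs)) {
      ov <- IRanges::intersect(IRanges::ranges(segs), truthRange)
      frac <- sum(IRanges::width(ov)) / IRanges::width(truthRange)
      if (frac >= 0.8) hits <- hits + 1L
    }
  }
  expect_gte(hits, 27L) # >= 90% of simulations recover >= 80% of the tract
})

test_that("the naive scan stays quiet on unrelated pairs", {
  set.seed(505)
  nMark <- 2000L
  positions <- seq(10000L, by = 10000L, length.out = nMark)
  quiet <- 0L
  for (rep in 1:30) {
    g <- simulateSibPair(nMark, af = 0.25, tract = NULL)
    segs <- naiveIbdScan(g, positions, window = 300L, maxOppositeHom = 2L)
    if (length(segs) == 0L) quiet <- quiet + 1L
  }
  expect_gte(quiet, 28L) # >= 95% of runs emit nothing at this stringency
})

test_that("an all-missing pair yields no segments", {
  g <- matrix(NA_real_, 100, 2)
  expect_equal(length(naiveIbdScan(g, seq_len(100))), 0L)
})
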