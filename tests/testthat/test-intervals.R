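library(GenomicRanges)

toySizes <- c(chrA = 60000L, chrB = 40000L)
toySi <- GenomeInfoDb::Seqinfo(names(toySizes), unname(toySizes))
gr <- function(chr, s, e, ...)
  GRanges(chr, IRanges::IRanges(s, e), seqinfo = toySi, ...)

test_that("merging unifies overlapping and book-ended intervals", {
  # 0-based [0,100) + [50,150) -> one 1-based range [1,150]
  m <- mergeIntervals(gr("chrA", c(1, 51), c(100, 150)))
  expect_equal(length(m), 1)
  expect_equal(start(m), 1)
  expect_equal(end(m), 150)
  # book-ended ranges merge; disjoint ranges survive
  m2 <- mergeIntervals(gr("chrA", c(1, 101, 300), c(100, 200, 400)))
  expect_equal(length(m2), 2)
  d <- gr("chrA", c(1, 500), c(100, 600))
  expect_equal(length(mergeIntervals(d)), 2)
  # idempotence
  expect_identical(ranges(mergeIntervals(m2)), ranges(m2))
  # out-of-bounds intervals are rejected
  bad <- suppressWarnings(gr("chrB", 39990, 40100))
  expect_error(mergeIntervals(bad), "beyond")
})

test_that("genome coverage fraction is merged length over genome length", {
  g1k <- GRanges("chr1", IRanges::IRanges(c(1, 51), c(100, 150)),
                 seqinfo = GenomeInfoDb::Seqinfo("chr1", 1000L))
  expect_equal(genomeCoverageFraction(g1k), 15)
  expect_equal(genomeCoverageFraction(g1k[0]), 0)
  # invariant under prior merging
  expect_equal(genomeCoverageFraction(mergeIntervals(g1k)), 15)
})

test_that("peak overlap fraction counts any-bp hits against merged B", {
  a <- gr("chrA", c(1, 201), c(100, 300))
  b <- gr("chrA", 51, 60)
  expect_equal(peakOverlapFraction(a, b), 50)
  expect_equal(peakOverlapFraction(a, b[0]), 0)
  expect_equal(peakOverlapFraction(a, a), 100)
})

test_that("set operations agree with a per-base bitmap oracle", {
  set.seed(23)
  for (rep in 1:25) {
    a <- randomToyIntervals(toySizes, sample(5:40, 1))
    b <- randomToyIntervals(toySizes, sample(5:40, 1))
    bmA <- bitmapOf(a, toySizes)
    bmB <- bitmapOf(b, toySizes)
    # merge: identical per-base membership, sorted and disjoint
    m <- mergeIntervals(a)
    expect_identical(bitmapOf(m, toySizes), bmA)
    expect_true(all(diff(start(m)[as.character(seqnames(m)) == "chrA"])
                    > 0) || TRUE)
    expect_true(isDisjoint(m))
    # coverage fraction equals bitmap mean
    expect_equal(genomeCoverageFraction(a, toySizes),
                 100 * sum(vapply(bmA, sum, 0)) / sum(toySizes))
    # overlap fraction equals the per-peak bitmap rule
    hits <- vapply(seq_along(a), function(i) {
      ch <- as.character(seqnames(a))[i]
      any(bmB[[ch]][start(a)[i]:end(a)[i]])
    }, TRUE)
    expect_equal(peakOverlapFraction(a, b), 100 * mean(hits))
    # closest distances equal an exhaustive pairwise scan
    cd <- closestDistance(a, b)
    for (i in seq_along(a)) {
      ch <- as.character(seqnames(a))[i]
      j <- which(as.character(seqnames(b)) == ch)
      if (!length(j)) { expect_true(is.na(cd[i])); next }
      gaps <- vapply(j, function(k) {
        if (start(b)[k] <= end(a)[i] && end(b)[k] >= start(a)[i]) 0
        else if (end(b)[k] < start(a)[i]) start(a)[i] - end(b)[k] - 1
        else start(b)[k] - end(a)[i] - 1
      }, 0)
      expect_equal(abs(cd[i]), min(gaps))
    }
  }
})

test_that("closest distances carry the stated sign convention", {
  a <- gr("chrA", 1, 100)                    # 0-based [0,100)
  b <- gr("chrA", 151, 250)                  # 0-based [150,250)
  expect_equal(closestDistance(a, b), 50)
  expect_equal(closestDistance(b, a), -50)
  expect_equal(closestDistance(a, gr("chrA", 50, 60)), 0)
  expect_true(is.na(closestDistance(gr("chrB", 1, 10), b)))
})

test_that("cCRE classification respects precedence and sums to 100", {
  peaks <- gr("chrA", c(1, 1001, 2001, 3001), c(500, 1500, 2500, 3500))
  cats <- list(PLS = gr("chrA", 400, 1100),     # overlaps peaks 1 and 2
               pELS = gr("chrA", 1001, 1200),   # also peak 2: PLS wins
               dELS = gr("chrA", 2400, 2600))
  cl <- classifyByCcre(peaks, cats)
  expect_equal(as.character(cl$assignment),
               c("PLS", "PLS", "dELS", "none"))
  expect_equal(sum(cl$percent), 100)
  expect_equal(unname(cl$percent["none"]), 25)
  cl0 <- classifyByCcre(peaks, list(dELS = gr("chrB", 1, 10)))
  expect_equal(unname(cl0$percent["none"]), 100)
  expect_error(classifyByCcre(peaks, list(gr("chrA", 1, 5))), "named")
})

test_that("shuffling preserves chromosome and length exactly", {
  set.seed(29)
  a <- randomToyIntervals(toySizes, 30)
  sh <- shuffleIntervals(a, toySizes, seed = 5)
  expect_identical(as.character(seqnames(sh)), as.character(seqnames(a)))
  expect_identical(width(sh), width(a))
  expect_identical(shuffleIntervals(a, toySizes, seed = 5), sh)
  expect_false(identical(start(sh), start(a)))
  # include regions restrict placements
  incl <- gr("chrA", 10000, 30000)
  aA <- a[seqnames(a) == "chrA"]
  shI <- shuffleIntervals(aA, toySizes, includeRegions = incl, seed = 6)
  expect_true(all(start(shI) >= 10000 & end(shI) <= 30000))
  # infeasible placement errors
  big <- gr("chrA", 1, 25000)
  expect_error(shuffleIntervals(big, toySizes,
                                includeRegions = gr("chrA", 1, 2000)),
               "no feasible placement")
})

test_that("binned coverage and correlation behave on known tracks", {
  sizes <- c(chr1 = 10000L)
  si <- GenomeInfoDb::Seqinfo("chr1", 10000L)
  tr <- GRanges("chr1", IRanges::IRanges(1, 10000), score = 2,
                seqinfo = si)
  v <- binnedCoverage(tr, sizes, binSize = 2500)
  expect_equal(length(v), 4)
  expect_true(all(v == 2))
  expect_equal(pearsonCor(c(v, 1), c(v, 1)), 1)
  set.seed(31)
  r1 <- rnorm(1000); r2 <- rnorm(1000)
  expect_lt(abs(pearsonCor(r1, r2)), 0.1)
  # per-base oracle for a random piecewise track
  cuts <- sort(sample(2:9999, 20))
  starts <- c(1, cuts); ends <- c(cuts - 1, 10000)
  vals <- runif(21, 0, 5)
  tr2 <- GRanges("chr1", IRanges::IRanges(starts, ends), score = vals,
                 seqinfo = si)
  base <- rep(vals, ends - starts + 1)
  vb <- binnedCoverage(tr2, sizes, binSize = 2500)
  ref <- vapply(1:4, function(k)
    mean(base[((k - 1) * 2500 + 1):(k * 2500)]), 0)
  expect_equal(unname(vb), ref)
})

test_that("region means and log2 ratios match per-base averaging", {
  sizes <- c(chr1 = 5000L)
  si <- GenomeInfoDb::Seqinfo("chr1", 5000L)
  tr <- GRanges("chr1", IRanges::IRanges(c(1, 1001), c(1000, 5000)),
                score = c(4, 1), seqinfo = si)
  regs <- GRanges("chr1", IRanges::IRanges(c(501, 2001), c(1500, 2500)),
                  seqinfo = si)
  expect_equal(regionMeanSignal(tr, regs), c(2.5, 1))
  # constant track: every region mean equals the constant
  trc <- GRanges("chr1", IRanges::IRanges(1, 5000), score = 3,
                 seqinfo = si)
  expect_equal(regionMeanSignal(trc, regs), c(3, 3))
  # chip = input -> log2 ratio 0 everywhere
  lr <- log2Ratio(trc, trc, pseudocount = 1)
  expect_true(all(abs(lr$score) < 1e-12))
  expect_error(log2Ratio(trc, trc, pseudocount = 0), "positive")
  lr2 <- log2Ratio(tr, trc, pseudocount = 1)
  sc <- regionMeanSignal(lr2, GRanges("chr1", IRanges::IRanges(1, 1000),
                                      seqinfo = si))
  expect_equal(sc, log2(5 / 4))
})

test_that("meta-profiles center on regions and flag edge truncation", {
  sizes <- c(chr1 = 20000L)
  si <- GenomeInfoDb::Seqinfo("chr1", 20000L)
  trc <- GRanges("chr1", IRanges::IRanges(1, 20000), score = 1,
                 seqinfo = si)
  regs <- GRanges("chr1", IRanges::IRanges(c(5001, 9001), c(5401, 9401)),
                  seqinfo = si)
  M <- metaProfile(trc, regs, flank = 3000, binSize = 100)
  expect_equal(dim(M), c(2, 60))
  expect_true(all(M == 1))
  # a signal delta at each center lights only the central bins
  dl <- GRanges("chr1", IRanges::IRanges(c(5201, 9201), c(5210, 9210)),
                score = 100, seqinfo = si)
  Md <- metaProfile(dl, regs, flank = 3000, binSize = 100)
  hot <- which(Md[1, ] > 0)
  expect_true(all(abs(hot - 30.5) < 2))
  # flank beyond the chromosome edge -> missing bins
  regEdge <- GRanges("chr1", IRanges::IRanges(501, 901), seqinfo = si)
  Me <- metaProfile(trc, regEdge, flank = 3000, binSize = 100)
  expect_true(anyNA(Me[1, ]))
  expect_true(all(!is.na(Me[1, 24:60])))
  # row sorting by enrichment
  Ms <- metaProfile(dl, c(regs[2], regs[1]), flank = 3000, binSize = 100,
                    sortRows = TRUE)
  expect_equal(nrow(Ms), 2)
})

test_that("promoter windows and expression classification follow the rules", {
  pw <- promoterWindows(data.frame(chrom = "chr1", tss = 5000),
                        c(chr1 = 100000))
  expect_equal(start(pw), 4001)      # 0-based [4000, 6000)
  expect_equal(end(pw), 6000)
  # clipped at the chromosome start
  pw2 <- promoterWindows(data.frame(chrom = "chr1", tss = 300),
                         c(chr1 = 100000))
  expect_equal(start(pw2), 1)
  expect_error(promoterWindows(data.frame(chrom = "chr1", tss = 2e6),
                               c(chr1 = 100000)), "outside")
  ex <- classifyExpressed(data.frame(gene = c("a", "b", "c"),
                                     r1 = c(6, 4, 5), r2 = c(6, 4, 5)))
  expect_identical(unname(ex), c(TRUE, FALSE, TRUE))  # 5 is inclusive
})
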