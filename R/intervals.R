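#' @importFrom GenomicRanges GRanges reduce findOverlaps countOverlaps
#'   coverage distanceToNearest tileGenome width start end seqnames strand
#' @importFrom IRanges IRanges Views viewMeans subsetByOverlaps
#' @importFrom GenomeInfoDb seqlengths seqlevels seqinfo Seqinfo
NULL

checkIntervals <- function(gr) {
  sl <- GenomeInfoDb::seqlengths(gr)
  if (any(is.na(sl)))
    stop("chromosome sizes (seqlengths) must be set on the interval set")
  bad <- which(GenomicRanges::end(gr) >
               sl[as.character(GenomicRanges::seqnames(gr))] |
               GenomicRanges::start(gr) < 1)
  if (length(bad))
    stop("interval beyond chromosome bounds at record ", bad[1])
  invisible(gr)
}

#' Merge overlapping or book-ended intervals
#'
#' Union of overlapping or directly adjacent (book-ended) intervals;
#' the result is sorted and disjoint (bedtools-merge semantics).
#'
#' @param gr A GRanges with seqlengths set.
#' @return A sorted, disjoint GRanges.
#' @export
mergeIntervals <- function(gr) {
  checkIntervals(gr)
  GenomicRanges::reduce(sort(gr), ignore.strand = TRUE)
}

#' Fraction of the genome covered by an interval set
#'
#' Merged length of the set divided by the total genome length, in percent.
#'
#' @param gr A GRanges.
#' @param chromSizes Named vector of chromosome lengths; defaults to the
#'   seqlengths of `gr`.
#' @return Percent of the genome covered.
#' @examples
#' si <- GenomeInfoDb::Seqinfo("chr1", 1000)
#' gr <- GenomicRanges::GRanges("chr1",
#'   IRanges::IRanges(c(1, 51), c(100, 150)), seqinfo = si)
#' genomeCoverageFraction(gr)  # 15
#' @export
genomeCoverageFraction <- function(gr, chromSizes = NULL) {
  if (is.null(chromSizes)) chromSizes <- GenomeInfoDb::seqlengths(gr)
  checkIntervals(gr)
  if (length(gr) == 0) return(0)
  100 * sum(GenomicRanges::width(mergeIntervals(gr))) /
    sum(as.numeric(chromSizes))
}

#' Percent of A intervals overlapping a B set
#'
#' Fraction of records in `a` having at least `minOverlapBp` bases of
#' intersection with the merged `b`.
#'
#' @param a,b GRanges.
#' @param minOverlapBp Minimum overlap in bp (default 1: any overlap).
#' @return Percent of `a` records overlapping.
#' @export
peakOverlapFraction <- function(a, b, minOverlapBp = 1L) {
  if (length(a) == 0) return(0)
  if (length(b) == 0) return(0)
  hit <- GenomicRanges::countOverlaps(a, mergeIntervals(b),
                                      minoverlap = minOverlapBp,
                                      ignore.strand = TRUE) > 0
  100 * mean(hit)
}

#' Classify peaks by candidate cis-regulatory element category
#'
#' Each peak is assigned the highest-precedence category it overlaps
#' (any intersection of at least 1 bp), else "none". Categories must be
#' given in precedence order (e.g. PLS before pELS before dELS).
#'
#' @param peaks GRanges of peaks.
#' @param categorySets Named list of GRanges, ordered by precedence.
#' @param minOverlapBp Minimum overlap in bp per category assignment.
#' @return List with `assignment` (per-peak category, factor) and
#'   `percent` (named percentages over categories plus "none"; sums to
#'   100).
#' @export
classifyByCcre <- function(peaks, categorySets, minOverlapBp = 1L) {
  if (is.null(names(categorySets)) || anyDuplicated(names(categorySets)))
    stop("categorySets must be a uniquely named list in precedence order")
  lev <- c(names(categorySets), "none")
  assig <- rep("none", length(peaks))
  for (cat in names(categorySets)) {
    hit <- GenomicRanges::countOverlaps(
      peaks, categorySets[[cat]], minoverlap = minOverlapBp,
      ignore.strand = TRUE) > 0
    assig[assig == "none" & hit] <- cat
  }
  assig <- factor(assig, levels = lev)
  pct <- 100 * table(assig) / max(1L, length(peaks))
  list(assignment = assig, percent = c(pct))
}

#' Randomize intervals preserving chromosome and length
#'
#' Each interval is re-placed uniformly at random on its own chromosome
#' with its own length (bedtools shuffle -chrom semantics). With
#' `includeRegions`, placements are restricted to lie wholly within the
#' given regions on the same chromosome (the -incl setting, e.g.
#' randomizing only within ciLADs).
#'
#' @param gr GRanges to shuffle.
#' @param chromSizes Named chromosome lengths; defaults to seqlengths.
#' @param includeRegions Optional GRanges restricting placements.
#' @param seed Optional RNG seed.
#' @return GRanges with the same per-chromosome multiset of lengths.
#' @export
shuffleIntervals <- function(gr, chromSizes = NULL, includeRegions = NULL,
                             seed = NULL) {
  if (is.null(chromSizes)) chromSizes <- GenomeInfoDb::seqlengths(gr)
  checkIntervals(gr)
  withSeed(seed, {
    chrom <- as.character(GenomicRanges::seqnames(gr))
    w <- GenomicRanges::width(gr)
    newStart <- integer(length(gr))
    if (is.null(includeRegions)) {
      for (i in seq_along(gr)) {
        room <- chromSizes[[chrom[i]]] - w[i] + 1L
        if (room < 1) stop("interval longer than its chromosome")
        newStart[i] <- sample.int(room, 1L)
      }
    } else {
      incl <- mergeIntervals(includeRegions)
      ichr <- as.character(GenomicRanges::seqnames(incl))
      for (i in seq_along(gr)) {
        cand <- which(ichr == chrom[i] &
                      GenomicRanges::width(incl) >= w[i])
        if (!length(cand))
          stop("no feasible placement within includeRegions for record ", i)
        room <- GenomicRanges::width(incl)[cand] - w[i] + 1L
        pick <- cand[sample.int(length(cand), 1L, prob = room)]
        off <- sample.int(GenomicRanges::width(incl)[pick] - w[i] + 1L, 1L)
        newStart[i] <- GenomicRanges::start(incl)[pick] + off - 1L
      }
    }
    out <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(newStart, width = w),
      seqinfo = GenomeInfoDb::seqinfo(gr))
    S4Vectors::mcols(out) <- S4Vectors::mcols(gr)
    out
  })
}

#' Signed distance from each A interval to its closest B interval
#'
#' 0 when overlapping (or book-ended); otherwise the gap in bp between the
#' nearest edges, negative when the closest B lies upstream (lower
#' coordinates). Chromosomes absent from B yield NA.
#'
#' @param a,b GRanges.
#' @return Numeric vector, one signed distance per record of `a`.
#' @export
closestDistance <- function(a, b) {
  out <- rep(NA_real_, length(a))
  if (length(b) == 0) return(out)
  hits <- GenomicRanges::distanceToNearest(a, b, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  d <- S4Vectors::mcols(hits)$distance
  upstream <- GenomicRanges::end(b)[si] <= GenomicRanges::start(a)[qi]
  sgn <- ifelse(d == 0, 0, ifelse(upstream, -1, 1))
  out[qi] <- sgn * d
  out
}

#' Mean signal (or interval coverage) in consecutive genomic bins
#'
#' Tiles the genome into consecutive bins of `binSize` bp and returns the
#' length-weighted mean of the piecewise-constant signal per bin (absent
#' positions count as 0). Plain interval sets are treated as coverage
#' (reads) tracks.
#'
#' @param x GRanges; if it has a numeric `score` column it is read as a
#'   bedGraph-style track, otherwise as intervals to be counted.
#' @param chromSizes Named chromosome lengths; defaults to seqlengths.
#' @param binSize Bin width in bp (default 2500).
#' @return Numeric vector of per-bin means, ordered by chromosome then
#'   position; names are "chrom:start-end" (1-based).
#' @export
binnedCoverage <- function(x, chromSizes = NULL, binSize = 2500L) {
  stopifnot(binSize > 0)
  if (is.null(chromSizes)) chromSizes <- GenomeInfoDb::seqlengths(x)
  if (any(is.na(chromSizes))) stop("chromosome sizes required")
  cov <- if (!is.null(S4Vectors::mcols(x)$score))
    GenomicRanges::coverage(x, weight = "score", width = as.list(chromSizes))
  else GenomicRanges::coverage(x, width = as.list(chromSizes))
  out <- numeric(0)
  for (chr in names(chromSizes)) {
    n <- chromSizes[[chr]]
    starts <- seq(1L, n, by = binSize)
    ends <- pmin(starts + binSize - 1L, n)
    vm <- IRanges::viewMeans(IRanges::Views(cov[[chr]],
                                            IRanges::IRanges(starts, ends)))
    names(vm) <- sprintf("%s:%d-%d", chr, starts, ends)
    out <- c(out, vm)
  }
  out
}

#' Pearson correlation between two binned-coverage vectors
#'
#' @param v1,v2 Equal-length numeric vectors (e.g. from [binnedCoverage()]).
#' @param removeOutliers Drop bins where either vector lies outside
#'   median +/- 1.5 IQR of its own distribution before correlating.
#' @return Pearson r.
#' @export
pearsonCor <- function(v1, v2, removeOutliers = FALSE) {
  stopifnot(length(v1) == length(v2))
  if (removeOutliers) {
    inR <- function(v) {
      q <- stats::quantile(v, c(0.25, 0.75))
      iqr <- q[2] - q[1]
      v >= q[1] - 1.5 * iqr & v <= q[2] + 1.5 * iqr
    }
    keep <- inR(v1) & inR(v2)
    v1 <- v1[keep]; v2 <- v2[keep]
  }
  stats::cor(v1, v2, method = "pearson")
}

#' Length-weighted mean signal per region
#'
#' @param track bedGraph-style GRanges with `score`.
#' @param regions GRanges of query regions.
#' @return Numeric vector of per-region means (absent signal counts as 0).
#' @export
regionMeanSignal <- function(track, regions) {
  sl <- GenomeInfoDb::seqlengths(regions)
  if (any(is.na(sl))) sl <- GenomeInfoDb::seqlengths(track)
  cov <- GenomicRanges::coverage(track, weight = "score",
                                 width = as.list(sl))
  vapply(seq_along(regions), function(i) {
    chr <- as.character(GenomicRanges::seqnames(regions))[i]
    IRanges::viewMeans(IRanges::Views(
      cov[[chr]], IRanges::IRanges(GenomicRanges::start(regions)[i],
                                   GenomicRanges::end(regions)[i])))
  }, 0)
}

#' Per-base log2 ratio of two signal tracks
#'
#' `log2((chip + pseudocount) / (input + pseudocount))` evaluated per base,
#' returned as a piecewise-constant track (run-length compressed).
#'
#' @param chip,input bedGraph-style GRanges with `score`.
#' @param pseudocount Positive stabilizer added to both tracks.
#' @param chromSizes Named chromosome lengths; defaults to seqlengths.
#' @return GRanges with `score = log2 ratio`.
#' @export
log2Ratio <- function(chip, input, pseudocount = 1, chromSizes = NULL) {
  if (pseudocount <= 0) stop("pseudocount must be positive")
  if (is.null(chromSizes)) chromSizes <- GenomeInfoDb::seqlengths(chip)
  cc <- GenomicRanges::coverage(chip, weight = "score",
                                width = as.list(chromSizes))
  ci <- GenomicRanges::coverage(input, weight = "score",
                                width = as.list(chromSizes))
  r <- log2((cc + pseudocount) / (ci + pseudocount))
  out <- methods::as(r, "GRanges")
  GenomeInfoDb::seqlengths(out) <- unlist(chromSizes)[
    GenomeInfoDb::seqlevels(out)]
  out
}

#' Meta-profile matrix of signal around region centers
#'
#' Mean signal in consecutive `binSize`-bp bins across `+/- flank` bp
#' around each region's center; bins truncated by a chromosome edge are
#' reported as NA. Rows follow the input region order and can be re-sorted
#' by mean enrichment (descending) for heatmap display.
#'
#' @param track bedGraph-style GRanges with `score`.
#' @param regions GRanges of regions (centers = midpoints).
#' @param flank Flank size in bp (default 3000).
#' @param binSize Bin width in bp (default 100).
#' @param sortRows Sort rows by decreasing row mean.
#' @return Numeric matrix regions x bins with attribute "binCenters" (bp
#'   offsets from the region center).
#' @export
metaProfile <- function(track, regions, flank = 3000L, binSize = 100L,
                        sortRows = FALSE) {
  stopifnot(binSize > 0, flank > 0, flank %% binSize == 0)
  sl <- GenomeInfoDb::seqlengths(regions)
  if (any(is.na(sl))) sl <- GenomeInfoDb::seqlengths(track)
  cov <- GenomicRanges::coverage(track, weight = "score",
                                 width = as.list(sl))
  nb <- as.integer(2 * flank / binSize)
  ctr <- floor((GenomicRanges::start(regions) +
                GenomicRanges::end(regions)) / 2)
  M <- matrix(NA_real_, length(regions), nb)
  offs <- seq(-flank, flank - binSize, by = binSize)
  for (i in seq_along(regions)) {
    chr <- as.character(GenomicRanges::seqnames(regions))[i]
    s <- ctr[i] + offs
    e <- s + binSize - 1L
    ok <- s >= 1 & e <= sl[[chr]]
    if (any(ok)) {
      vm <- IRanges::viewMeans(IRanges::Views(
        cov[[chr]], IRanges::IRanges(s[ok], e[ok])))
      M[i, ok] <- vm
    }
  }
  rownames(M) <- if (!is.null(names(regions))) names(regions) else
    as.character(seq_along(regions))
  if (sortRows) M <- M[order(-rowMeans(M, na.rm = TRUE)), , drop = FALSE]
  attr(M, "binCenters") <- offs + binSize / 2
  M
}

#' Promoter windows around transcription start sites
#'
#' Builds the promoter set as the region 1 kb up- and downstream of each
#' TSS (total 2 kb, strand-independent width), clipped to the chromosome.
#'
#' @param tss data.frame with columns `chrom`, `tss` (0-based position),
#'   optionally `strand` and `gene`.
#' @param chromSizes Named chromosome lengths.
#' @param flank Window half-width in bp (default 1000).
#' @return GRanges of promoter windows (0-based half-open input mapped to
#'   1-based closed GRanges).
#' @examples
#' promoterWindows(data.frame(chrom = "chr1", tss = 5000),
#'                 c(chr1 = 100000))  # spans [4000, 6000) in 0-based terms
#' @export
promoterWindows <- function(tss, chromSizes, flank = 1000L) {
  if (any(tss$tss < 0 | tss$tss > chromSizes[tss$chrom]))
    stop("TSS outside chromosome bounds")
  s0 <- pmax(tss$tss - flank, 0)
  e0 <- pmin(tss$tss + flank, chromSizes[tss$chrom])
  gr <- GenomicRanges::GRanges(
    tss$chrom, IRanges::IRanges(s0 + 1, e0),
    strand = if (!is.null(tss$strand)) tss$strand else "*",
    seqinfo = GenomeInfoDb::Seqinfo(names(chromSizes),
                                    as.integer(unname(chromSizes))))
  if (!is.null(tss$gene)) names(gr) <- tss$gene
  gr
}

#' Classify genes as expressed from replicate read counts
#'
#' A gene is "expressed" when the mean of its replicate counts reaches the
#' threshold (inclusive; default 5 average mapped reads over two
#' replicates).
#'
#' @param counts data.frame or matrix; if a data.frame with a `gene`
#'   column, the remaining numeric columns are the replicates.
#' @param threshold Minimum mean count (default 5).
#' @return Named logical vector (TRUE = expressed).
#' @examples
#' classifyExpressed(data.frame(gene = c("a", "b"), r1 = c(6, 4),
#'                              r2 = c(6, 4)))
#' @export
classifyExpressed <- function(counts, threshold = 5) {
  if (is.data.frame(counts) && "gene" %in% names(counts)) {
    genes <- counts$gene
    m <- as.matrix(counts[setdiff(names(counts), "gene")])
  } else {
    m <- as.matrix(counts)
    genes <- rownames(m)
  }
  if (any(m < 0)) stop("counts must be non-negative")
  out <- rowMeans(m) >= threshold
  names(out) <- genes
  out
}
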