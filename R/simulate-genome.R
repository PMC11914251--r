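#' Build a toy genome fixture with planted peaks and annotation categories
#'
#' Constructs, on a small user-defined genome, (i) disjoint annotation blocks
#' for cCRE-like categories (e.g. PLS, pELS, dELS) and LAD-like domains,
#' (ii) a peak set in which a configurable number of peaks is planted wholly
#' inside each category (the rest fall outside every category), and (iii) a
#' piecewise-constant signal track elevated over the peaks. Because planted
#' peaks lie entirely within their (disjoint) category blocks, the per-peak
#' category truth table is exact by construction.
#'
#' @param chromSizes Named integer vector of chromosome lengths (bp).
#' @param nPeaks Total number of peaks.
#' @param peakWidth Peak width in bp (single number) or a function
#'   `n -> widths`; default 478 bp, a typical ChIP-seq peak size.
#' @param categoryLayout Named list, one entry per category, each
#'   `c(n = <blocks>, width = <bp>)`.
#' @param enrichmentMap Named numeric: fraction of peaks planted on each
#'   category; the remainder (1 - sum) is placed outside all categories.
#' @param signalBaseline,signalPeak Track values off/on peaks.
#' @param maxTries Placement retries before declaring the request infeasible.
#' @param seed Optional RNG seed.
#' @return List with `chromSizes`, `peaks` (GRanges, `mcols()$category`),
#'   `categories` (GRanges with `category`), `signal` (GRanges with `score`,
#'   bedGraph semantics) and `truth` (per-peak category `DataFrame`).
#' @examples
#' fx <- makeGenomeFixture(c(chr1 = 1e6), nPeaks = 20, seed = 1)
#' table(fx$truth$category)
#' @export
makeGenomeFixture <- function(chromSizes = c(chr1 = 1000000L,
                                             chr2 = 800000L),
                              nPeaks = 100L,
                              peakWidth = 478L,
                              categoryLayout = list(
                                PLS  = c(n = 30, width = 800),
                                pELS = c(n = 60, width = 800),
                                dELS = c(n = 120, width = 1000),
                                LAD  = c(n = 3, width = 60000)),
                              enrichmentMap = c(dELS = 0.40, pELS = 0.15,
                                                PLS = 0.05, LAD = 0.05),
                              signalBaseline = 1, signalPeak = 10,
                              maxTries = 2000L, seed = NULL) {
  stopifnot(all(chromSizes > 0), nPeaks >= 0)
  if (any(enrichmentMap < 0) || sum(enrichmentMap) > 1 + 1e-9)
    stop("enrichmentMap fractions must be non-negative and sum to <= 1")
  if (!all(names(enrichmentMap) %in% names(categoryLayout)))
    stop("enrichmentMap names must be categories in categoryLayout")
  widthFun <- if (is.function(peakWidth)) peakWidth
              else function(n) rep(as.integer(peakWidth), n)
  si <- GenomeInfoDb::Seqinfo(names(chromSizes),
                              as.integer(unname(chromSizes)))
  withSeed(seed, {
    # -- category blocks: disjoint across all categories
    catChrom <- character(); catStart <- integer(); catEnd <- integer()
    catName <- character()
    overlapsAny <- function(chrom, s, e) {
      idx <- which(catChrom == chrom)
      any(catStart[idx] < e & catEnd[idx] > s)
    }
    # place wide blocks first so large domains still find room
    widths <- vapply(categoryLayout, function(x) x[["width"]], 0)
    for (cat in names(categoryLayout)[order(-widths)]) {
      nb <- categoryLayout[[cat]][["n"]]
      w <- categoryLayout[[cat]][["width"]]
      for (b in seq_len(nb)) {
        done <- FALSE
        for (try in seq_len(maxTries)) {
          chrom <- sample(names(chromSizes), 1,
                          prob = pmax(chromSizes - w + 1, 0))
          if (chromSizes[[chrom]] < w) next
          s <- sample.int(chromSizes[[chrom]] - w + 1, 1) - 1L  # 0-based
          if (!overlapsAny(chrom, s, s + w)) {
            catChrom <- c(catChrom, chrom); catStart <- c(catStart, s)
            catEnd <- c(catEnd, s + as.integer(w))
            catName <- c(catName, cat)
            done <- TRUE
            break
          }
        }
        if (!done) stop("cannot construct disjoint category layout")
      }
    }
    categories <- GenomicRanges::GRanges(
      catChrom, IRanges::IRanges(catStart + 1L, catEnd), seqinfo = si,
      category = catName)
    # -- peaks per category (planted wholly inside a block)
    nCat <- round(enrichmentMap * nPeaks)
    nNone <- nPeaks - sum(nCat)
    if (nNone < 0) stop("enrichmentMap requests more peaks than nPeaks")
    pkChrom <- character(); pkStart <- integer(); pkEnd <- integer()
    pkCat <- character()
    pkClash <- function(chrom, s, e) {
      idx <- which(pkChrom == chrom)
      any(pkStart[idx] < e & pkEnd[idx] > s)
    }
    addPeak <- function(chrom, s, w, cat) {
      pkChrom <<- c(pkChrom, chrom); pkStart <<- c(pkStart, s)
      pkEnd <<- c(pkEnd, s + as.integer(w)); pkCat <<- c(pkCat, cat)
    }
    for (cat in names(nCat)) {
      for (j in seq_len(nCat[[cat]])) {
        w <- widthFun(1)
        blocks <- which(catName == cat & (catEnd - catStart) >= w)
        if (!length(blocks))
          stop("requested enrichment infeasible: no '", cat,
               "' block can hold a ", w, " bp peak")
        done <- FALSE
        for (try in seq_len(maxTries)) {
          b <- if (length(blocks) == 1) blocks else sample(blocks, 1)
          room <- (catEnd[b] - catStart[b]) - w
          s <- catStart[b] + (if (room > 0) sample.int(room + 1, 1) - 1L
                              else 0L)
          if (!pkClash(catChrom[b], s, s + w)) {
            addPeak(catChrom[b], s, w, cat)
            done <- TRUE
            break
          }
        }
        if (!done) stop("requested enrichment infeasible: category '", cat,
                        "' area exhausted")
      }
    }
    for (j in seq_len(nNone)) {
      w <- widthFun(1)
      done <- FALSE
      for (try in seq_len(maxTries)) {
        chrom <- sample(names(chromSizes), 1,
                        prob = pmax(chromSizes - w + 1, 0))
        s <- sample.int(chromSizes[[chrom]] - w + 1, 1) - 1L
        if (!overlapsAny(chrom, s, s + w) && !pkClash(chrom, s, s + w)) {
          addPeak(chrom, s, w, "none")
          done <- TRUE
          break
        }
      }
      if (!done) stop("cannot place background peaks outside categories")
    }
    ord <- order(match(pkChrom, names(chromSizes)), pkStart)
    peaks <- GenomicRanges::GRanges(
      pkChrom[ord], IRanges::IRanges(pkStart[ord] + 1L, pkEnd[ord]),
      seqinfo = si, category = pkCat[ord])
    names(peaks) <- sprintf("peak%04d", seq_along(peaks))
    # -- signal track: baseline everywhere, elevated over peaks
    cov <- GenomicRanges::coverage(peaks, width = GenomeInfoDb::seqlengths(si))
    sig <- methods::as(cov, "GRanges")
    sig$score <- ifelse(sig$score > 0, signalPeak, signalBaseline)
    GenomeInfoDb::seqinfo(sig) <- si
    truth <- S4Vectors::DataFrame(peak = names(peaks),
                                  category = peaks$category)
    list(chromSizes = chromSizes, peaks = peaks, categories = categories,
         signal = sig, truth = truth)
  })
}
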