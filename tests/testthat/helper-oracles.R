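# Independent brute-force oracles. These deliberately re-derive quantities
# from first principles (dense search, enumeration, direct formulas) and
# never call the implementation paths they check.

# shortest distance from a point to an axis-aligned ellipsoid surface by
# dense surface sampling plus local optimization over spherical angles
oracleEllipsoidDist <- function(p, center, ax) {
  obj <- function(ang) {
    q <- center + ax * c(cos(ang[1]) * cos(ang[2]),
                         cos(ang[1]) * sin(ang[2]),
                         sin(ang[1]))
    sum((q - p)^2)
  }
  starts <- expand.grid(th = seq(-pi / 2, pi / 2, length.out = 13),
                        ph = seq(0, 2 * pi, length.out = 17))
  best <- Inf
  for (i in seq_len(nrow(starts))) {
    o <- stats::optim(as.numeric(starts[i, ]), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
    best <- min(best, o$value)
  }
  sqrt(best)
}

# minimum anisotropic distance from one foreground voxel to any background
# voxel, by exhaustive scan
oracleVoxelDist <- function(mask, vox, sp) {
  bg <- which(!mask, arr.ind = TRUE)
  if (!nrow(bg)) return(Inf)
  sqrt(min(((vox[1] - bg[, 1]) * sp[1])^2 +
           ((vox[2] - bg[, 2]) * sp[2])^2 +
           ((vox[3] - bg[, 3]) * sp[3])^2))
}

# Huang-Wang fuzzy entropy of a histogram split at threshold level t,
# naive per-level evaluation
oracleHuangEntropy <- function(counts, levels, t) {
  nz <- counts > 0
  lv <- levels[nz]; ct <- counts[nz]
  C <- max(lv) - min(lv)
  lo <- lv <= t
  if (!any(lo) || all(lo)) return(Inf)
  mu0 <- sum(ct[lo] * lv[lo]) / sum(ct[lo])
  mu1 <- sum(ct[!lo] * lv[!lo]) / sum(ct[!lo])
  S <- function(u) {
    v <- 1 - u
    -(u * log(u) + ifelse(v > 0, v * log(v), 0))
  }
  tot <- 0
  for (i in seq_along(lv)) {
    mu <- if (lo[i]) mu0 else mu1
    u <- 1 / (1 + abs(lv[i] - mu) / C)
    tot <- tot + ct[i] * S(u)
  }
  tot
}

oracleHuangMin <- function(counts, levels) {
  es <- vapply(levels, function(t) oracleHuangEntropy(counts, levels, t),
               0)
  min(es)
}

# exact two-sample KS p-value by full enumeration of label assignments
oracleKsPerm <- function(x, y) {
  n <- length(x); m <- length(y)
  ksD <- function(a, b) {
    pts <- sort(unique(c(a, b)))
    max(abs(ecdf(a)(pts) - ecdf(b)(pts)))
  }
  obs <- ksD(x, y)
  all <- c(x, y)
  combos <- utils::combn(n + m, n)
  cnt <- 0L
  for (j in seq_len(ncol(combos))) {
    a <- all[combos[, j]]
    b <- all[-combos[, j]]
    if (ksD(a, b) >= obs - 1e-12) cnt <- cnt + 1L
  }
  cnt / ncol(combos)
}

# Hochberg adjustment by direct evaluation of the step-up formula
oracleHochberg <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (k in seq_len(m))
    adj[k] <- min(1, min((m - k:m + 1) * ps[k:m]))
  out <- numeric(m)
  out[o] <- adj
  out
}

# per-base bitmap of an interval set on a toy genome (list of logical
# vectors, one per chromosome; 1-based positions)
bitmapOf <- function(gr, chromSizes) {
  bm <- lapply(chromSizes, function(n) logical(n))
  if (length(gr)) {
    ch <- as.character(GenomicRanges::seqnames(gr))
    s <- GenomicRanges::start(gr); e <- GenomicRanges::end(gr)
    for (i in seq_along(gr)) bm[[ch[i]]][s[i]:e[i]] <- TRUE
  }
  bm
}

randomToyIntervals <- function(chromSizes, n, maxLen = 500) {
  ch <- sample(names(chromSizes), n, replace = TRUE)
  w <- sample.int(maxLen, n, replace = TRUE)
  s <- vapply(seq_len(n), function(i)
    sample.int(chromSizes[[ch[i]]] - w[i] + 1, 1), 0L)
  GenomicRanges::GRanges(ch, IRanges::IRanges(s, width = w),
                         seqinfo = GenomeInfoDb::Seqinfo(
                           names(chromSizes),
                           as.integer(unname(chromSizes))))
}

# analytic expected fraction of shuffled peaks overlapping a region set:
# per peak, favorable uniform start positions / all start positions
oracleShuffleOverlapExpect <- function(peaks, regions, chromSizes) {
  merged <- GenomicRanges::reduce(regions, ignore.strand = TRUE)
  mc <- as.character(GenomicRanges::seqnames(merged))
  ms <- GenomicRanges::start(merged); me <- GenomicRanges::end(merged)
  pr <- vapply(seq_along(peaks), function(i) {
    chr <- as.character(GenomicRanges::seqnames(peaks))[i]
    L <- GenomicRanges::width(peaks)[i]
    total <- chromSizes[[chr]] - L + 1
    idx <- which(mc == chr)
    if (!length(idx)) return(0)
    lo <- pmax(ms[idx] - L + 1, 1)
    hi <- pmin(me[idx], chromSizes[[chr]] - L + 1)
    iv <- IRanges::reduce(IRanges::IRanges(lo[hi >= lo], hi[hi >= lo]))
    sum(IRanges::width(iv)) / total
  }, 0)
  mean(pr)
}
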