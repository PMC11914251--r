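#' Huang fuzzy-entropy threshold of an intensity histogram
#'
#' Implements Huang & Wang fuzzy thresholding (Shannon entropy form): for a
#' candidate threshold t, pixels at level g get fuzzy membership
#' `u(g) = 1 / (1 + |g - mu| / C)` to their class (mu = mean of the class
#' they fall in, C = level range), and the threshold minimizing the total
#' fuzzy entropy `-sum h(g) [u log u + (1-u) log(1-u)]` is returned. The
#' search is exhaustive over all candidate levels; ties are broken by the
#' lowest level.
#'
#' @param counts Histogram counts, one per gray level.
#' @param levels Gray-level values matching `counts`; defaults to
#'   `0:(length(counts)-1)`.
#' @return The selected threshold level (pixels with level <= threshold are
#'   background class 0).
#' @examples
#' h <- rep(0, 256); h[11] <- 100; h[201] <- 100
#' huangThreshold(h)  # 10 (levels are 0-based)
#' @export
huangThreshold <- function(counts, levels = NULL) {
  counts <- as.numeric(counts)
  if (is.null(levels)) levels <- seq_along(counts) - 1
  stopifnot(length(levels) == length(counts))
  nz <- which(counts > 0)
  if (length(nz) < 2) stop("degenerate histogram: fewer than 2 nonzero bins")
  lv <- levels[nz]; ct <- counts[nz]
  C <- lv[length(lv)] - lv[1]
  # cumulative moments for O(1) class means at each candidate
  cw <- cumsum(ct); cm <- cumsum(ct * lv)
  W <- cw[length(cw)]; M <- cm[length(cm)]
  sFun <- function(u) {
    # Shannon entropy of membership; u in [0.5, 1] so 1-u in [0, 0.5]
    v <- 1 - u
    -(u * log(u) + ifelse(v > 0, v * log(v), 0))
  }
  best <- Inf; bestT <- NA_real_
  for (k in seq_len(length(nz) - 1)) {      # threshold at level lv[k]
    mu0 <- cm[k] / cw[k]
    mu1 <- (M - cm[k]) / (W - cw[k])
    u0 <- 1 / (1 + abs(lv[seq_len(k)] - mu0) / C)
    u1 <- 1 / (1 + abs(lv[(k + 1):length(lv)] - mu1) / C)
    E <- sum(ct[seq_len(k)] * sFun(u0)) +
         sum(ct[(k + 1):length(lv)] * sFun(u1))
    if (E < best - 1e-12) { best <- E; bestT <- lv[k] }
  }
  bestT
}

#' Segmentation configuration
#'
#' @param thresholdMethod "huang" (default) or "fixed".
#' @param fixedThreshold Intensity threshold when `thresholdMethod="fixed"`.
#' @param minVolumeUm3 Minimum nucleus volume (um^3); converted to voxels
#'   via the stack spacing.
#' @param excludeXYBorder Flag nuclei touching the lateral image border
#'   (they are excluded from downstream distance analysis).
#' @param connectivity 3D connectivity for component labeling, 6 or 26.
#' @param nbins Histogram bins for automatic thresholding.
#' @param mode "3d" thresholds the full stack; "projection" thresholds the
#'   maximum z-projection to get 2D ROIs and infers each nucleus's z-extent
#'   from above-threshold planes within its footprint.
#' @return A validated list of class `segConfig`.
#' @export
segConfig <- function(thresholdMethod = c("huang", "fixed"),
                      fixedThreshold = NA_real_, minVolumeUm3 = 20,
                      excludeXYBorder = TRUE, connectivity = 26L,
                      nbins = 256L, mode = c("3d", "projection")) {
  thresholdMethod <- match.arg(thresholdMethod)
  mode <- match.arg(mode)
  if (thresholdMethod == "fixed" && !is.finite(fixedThreshold))
    stop("fixed threshold requested but fixedThreshold is not set")
  stopifnot(minVolumeUm3 >= 0, connectivity %in% c(6L, 26L))
  structure(list(thresholdMethod = thresholdMethod,
                 fixedThreshold = fixedThreshold,
                 minVolumeUm3 = minVolumeUm3,
                 excludeXYBorder = excludeXYBorder,
                 connectivity = as.integer(connectivity),
                 nbins = as.integer(nbins), mode = mode),
            class = "segConfig")
}

#' Segment nuclei in 3D from the DNA-stain channel
#'
#' A single global threshold (Huang fuzzy entropy on the pooled stack
#' histogram by default) binarizes the stain channel; connected components
#' at the configured connectivity become nuclei; components smaller than the
#' minimum volume are dropped and components touching the lateral (x/y)
#' image border are flagged. Each nucleus's height is
#' `Z = (zMax - zMin + 1) * dz`, the plane-count estimator.
#'
#' @param stack An [ImageStack-class].
#' @param channel DNA-stain channel name (default "hoechst").
#' @param config A [segConfig()].
#' @return A [SegmentationResult-class].
#' @examples
#' fld <- makeNucleusField(1, fieldShape = c(12, 96, 96), seed = 1)
#' seg <- segmentNuclei(fld$stack)
#' nuclei(seg)
#' @export
segmentNuclei <- function(stack, channel = "hoechst", config = segConfig()) {
  img <- stack[[channel]]
  sp <- stack@spacing
  d <- dim(img)
  tau <- if (config$thresholdMethod == "fixed") {
    config$fixedThreshold
  } else {
    rng <- range(img)
    if (diff(rng) <= 0) {
      # flat image: nothing segmentable
      rng[1]
    } else {
      # 256-bin pooled histogram; threshold mapped back to intensity units
      br <- seq(rng[1], rng[2], length.out = config$nbins + 1L)
      h <- tabulate(findInterval(img, br, rightmost.closed = TRUE),
                    nbins = config$nbins)
      mids <- (br[-1] + br[-length(br)]) / 2
      if (sum(h > 0) < 2) mids[which.max(h)]
      else huangThreshold(h, levels = mids)
    }
  }
  src <- img
  if (config$mode == "projection") {
    proj <- apply(img, c(2, 3), max)
    fg2d <- proj > tau
    mask <- array(FALSE, d)
    for (z in seq_len(d[1])) mask[z, , ] <- fg2d & (img[z, , ] > tau)
  } else {
    mask <- img > tau
  }
  minVox <- max(1L, ceiling(config$minVolumeUm3 / prod(sp)))
  labs <- label3d(mask, config$connectivity)
  sizes <- tabulate(labs[labs > 0L])
  keep <- which(sizes >= minVox)
  if (length(keep) == 0L) {
    return(new("SegmentationResult", labels = array(0L, d),
               nuclei = emptyNucleusTable(), spacing = sp,
               threshold = as.numeric(tau)))
  }
  # relabel compactly, ordered by first voxel occurrence
  lut <- integer(max(labs) + 1L)          # lut[old label + 1] -> new label
  lut[keep + 1L] <- seq_along(keep)
  labs <- array(lut[labs + 1L], d)
  recs <- lapply(seq_along(keep), function(k) {
    idx <- which(labs == k, arr.ind = TRUE)   # columns z, y, x
    zr <- range(idx[, 1]); yr <- range(idx[, 2]); xr <- range(idx[, 3])
    list(id = k, nVoxels = nrow(idx),
         zMin = zr[1], zMax = zr[2], yMin = yr[1], yMax = yr[2],
         xMin = xr[1], xMax = xr[2],
         centroidXUm = mean((idx[, 3] - 0.5) * sp[3]),
         centroidYUm = mean((idx[, 2] - 0.5) * sp[2]),
         centroidZUm = mean((idx[, 1] - 0.5) * sp[1]),
         heightUm = (zr[2] - zr[1] + 1) * sp[1],
         touchesBorder = yr[1] == 1L || yr[2] == d[2] ||
                         xr[1] == 1L || xr[2] == d[3])
  })
  nuc <- S4Vectors::DataFrame(do.call(rbind, lapply(recs, function(r)
    data.frame(r, stringsAsFactors = FALSE))))
  new("SegmentationResult", labels = labs, nuclei = nuc, spacing = sp,
      threshold = as.numeric(tau))
}

emptyNucleusTable <- function() {
  S4Vectors::DataFrame(id = integer(), nVoxels = integer(),
                       zMin = integer(), zMax = integer(),
                       yMin = integer(), yMax = integer(),
                       xMin = integer(), xMax = integer(),
                       centroidXUm = numeric(), centroidYUm = numeric(),
                       centroidZUm = numeric(), heightUm = numeric(),
                       touchesBorder = logical())
}

#' Nucleus height from its z-plane extent
#'
#' `Z = (zMax - zMin + 1) * dz`: the number of planes the nucleus occupies
#' times the plane spacing.
#'
#' @param record One row of a segmentation's nucleus table (needs `zMin`,
#'   `zMax`), or a list with those fields.
#' @param dz Plane spacing in um.
#' @return Height Z in um.
#' @examples
#' nucleusHeight(list(zMin = 3, zMax = 14), dz = 0.5)  # 6
#' @export
nucleusHeight <- function(record, dz) {
  stopifnot(dz > 0, record$zMin <= record$zMax)
  (record$zMax - record$zMin + 1) * dz
}
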