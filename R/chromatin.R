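# bilinear interpolation of a 2D image at continuous (y, x) pixel-center
# coordinates (1-based; pixel i covers [i-0.5, i+0.5])
bilinear <- function(img, y, x) {
  ny <- nrow(img); nx <- ncol(img)
  y <- pmin(pmax(y, 1), ny); x <- pmin(pmax(x, 1), nx)
  y0 <- pmin(pmax(floor(y), 1), ny - 1); x0 <- pmin(pmax(floor(x), 1),
                                                    nx - 1)
  fy <- y - y0; fx <- x - x0
  img[cbind(y0, x0)] * (1 - fy) * (1 - fx) +
    img[cbind(y0 + 1, x0)] * fy * (1 - fx) +
    img[cbind(y0, x0 + 1)] * (1 - fy) * fx +
    img[cbind(y0 + 1, x0 + 1)] * fy * fx
}

# mid-plane slice helpers
midPlane <- function(mask) {
  zs <- which(apply(mask, 1, any))
  round((min(zs) + max(zs)) / 2)
}

maskCentroid2d <- function(m2d) {
  idx <- which(m2d, arr.ind = TRUE)
  c(y = mean(idx[, 1]), x = mean(idx[, 2]))
}

#' Peripheral heterochromatin layer thickness by radial ray casting
#'
#' Casts `nRays` equally spaced radial rays from the nucleus centroid in the
#' mid z-plane. On each ray the layer's outer boundary is the mask border;
#' walking inward, the peripheral intensity peak is located and the inner
#' boundary is the first point where intensity falls to `boundaryFraction`
#' of that peak. The per-ray distances between the two boundaries are
#' averaged (the thickness estimate is the mean of `nRays` distance values).
#'
#' @param stain Numeric 3D array: the chromatin-mark channel.
#' @param mask Logical 3D array: the nucleus mask.
#' @param spacing `(dz, dy, dx)` in um.
#' @param nRays Number of rays (default 100).
#' @param boundaryFraction Half-max style inner-boundary rule (default 0.5).
#' @return List: `thicknessUm` (per-ray values), `nLocations`, `meanUm`,
#'   `semUm` (sd/sqrt(n)) and `normalizedPct` (mean / (Z/2) x 100, with Z
#'   the plane-count height of the mask).
#' @export
layerThickness <- function(stain, mask, spacing, nRays = 100L,
                           boundaryFraction = 0.5) {
  stopifnot(nRays >= 2, boundaryFraction > 0, boundaryFraction < 1)
  spacing <- unname(spacing)
  z <- midPlane(mask)
  m2d <- mask[z, , ]
  s2d <- stain[z, , ]
  ctr <- maskCentroid2d(m2d)
  ny <- nrow(m2d); nx <- ncol(m2d)
  step <- 0.5                                  # pixels
  Ts <- rep(NA_real_, nRays)
  for (k in seq_len(nRays)) {
    th <- 2 * pi * (k - 1) / nRays
    dy <- sin(th); dx <- cos(th)
    # march outward to the mask border
    smax <- 0
    s <- 0
    repeat {
      s <- s + step
      yy <- ctr[1] + s * dy; xx <- ctr[2] + s * dx
      if (yy < 1 || yy > ny || xx < 1 || xx > nx) break
      if (!m2d[round(yy), round(xx)]) break
      smax <- s
    }
    if (smax <= 2 * step) next
    u <- seq(0, smax, by = step)               # distance inward from border
    yy <- ctr[1] + (smax - u) * dy
    xx <- ctr[2] + (smax - u) * dx
    I <- bilinear(s2d, yy, xx)
    outer_n <- max(2, floor(length(u) / 2))    # peak must sit in outer half
    ip <- which.max(I[seq_len(outer_n)])
    peak <- I[ip]
    lim <- boundaryFraction * peak
    below <- which(I[(ip + 1):length(I)] <= lim)
    if (!length(below)) next                   # no detectable layer this ray
    j <- ip + below[1]
    # linear sub-sample interpolation of the crossing
    frac <- if (I[j - 1] > I[j]) (I[j - 1] - lim) / (I[j - 1] - I[j]) else 1
    Ts[k] <- (u[j - 1] + frac * step) * spacing[3]
  }
  ok <- !is.na(Ts)
  if (mean(ok) <= 0.5)
    stop("no layer: no detectable peripheral peak on more than 50% of rays")
  zs <- which(apply(mask, 1, any))
  Z <- (max(zs) - min(zs) + 1) * spacing[1]
  Tv <- Ts[ok]
  list(thicknessUm = Tv, nLocations = length(Tv), meanUm = mean(Tv),
       semUm = stats::sd(Tv) / sqrt(length(Tv)),
       normalizedPct = mean(Tv) / (Z / 2) * 100)
}

#' Nucleoplasmic over peripheral intensity ratio from a line profile
#'
#' Samples the chromatin-mark intensity along a chord through the nucleus
#' centroid (by default along the major axis of the mid-plane mask). The
#' peripheral value is the mean of the two maxima within the border zones
#' (outer `borderZone` fraction of the chord at each end); the nucleoplasmic
#' value is the mean over the central `centralFraction` of the chord.
#'
#' @inheritParams layerThickness
#' @param angle Chord angle in radians; NULL picks the mask's major axis.
#' @param centralFraction Central chord fraction for the nucleoplasmic mean.
#' @param borderZone Outer chord fraction defining each border zone.
#' @return List: `peripheral`, `nucleoplasmic`, `ratio`
#'   (nucleoplasmic / peripheral).
#' @export
profileRatio <- function(stain, mask, spacing, angle = NULL,
                         centralFraction = 0.5, borderZone = 0.15) {
  spacing <- unname(spacing)
  z <- midPlane(mask)
  m2d <- mask[z, , ]
  s2d <- stain[z, , ]
  ctr <- maskCentroid2d(m2d)
  if (is.null(angle)) {
    idx <- which(m2d, arr.ind = TRUE)
    cv <- stats::cov(idx)
    ev <- eigen(cv)$vectors[, 1]
    angle <- atan2(ev[1], ev[2])
  }
  dy <- sin(angle); dx <- cos(angle)
  ny <- nrow(m2d); nx <- ncol(m2d)
  step <- 0.5
  reach <- function(sgn) {
    s <- 0; last <- 0
    repeat {
      s <- s + step
      yy <- ctr[1] + sgn * s * dy; xx <- ctr[2] + sgn * s * dx
      if (yy < 1 || yy > ny || xx < 1 || xx > nx) break
      if (!m2d[round(yy), round(xx)]) break
      last <- s
    }
    last
  }
  sNeg <- reach(-1); sPos <- reach(1)
  t <- seq(-sNeg, sPos, by = step)
  if (length(t) < 10) stop("degenerate chord: fewer than 10 samples")
  I <- bilinear(s2d, ctr[1] + t * dy, ctr[2] + t * dx)
  n <- length(I)
  nb <- max(1, floor(borderZone * n))
  peri <- mean(c(max(I[seq_len(nb)]), max(I[(n - nb + 1):n])))
  half <- centralFraction / 2
  mid <- (abs(seq_len(n) - (which.min(abs(t))[1])) / n) <= half
  nucl <- mean(I[mid])
  list(peripheral = peri, nucleoplasmic = nucl, ratio = nucl / peri)
}

#' Quantify intranuclear chromatin foci
#'
#' Restricts to the nucleus footprint eroded by `rimExclusionUm` (excluding
#' the peripheral layer), thresholds the maximum z-projection of the
#' chromatin channel at mean + k sd of the intranuclear intensity, labels
#' connected components and reports their count and 2D areas (um^2).
#'
#' @inheritParams layerThickness
#' @param rimExclusionUm Width of the excluded peripheral rim (um).
#' @param intensityK Threshold = mean + `intensityK` * sd (default 2).
#' @param minAreaUm2 Minimum focus area kept (um^2).
#' @return List: `count`, `areasUm2`, `meanAreaUm2` (NA when no foci).
#' @export
quantifyFoci <- function(stain, mask, spacing, rimExclusionUm = 1,
                         intensityK = 2, minAreaUm2 = 0.2) {
  stopifnot(rimExclusionUm >= 0)
  spacing <- unname(spacing)
  foot <- apply(mask, c(2, 3), any)
  stM <- stain
  stM[!mask] <- -Inf
  proj <- apply(stM, c(2, 3), max)
  # 2D erosion of the footprint via an exact distance transform
  f3 <- array(foot, c(1, dim(foot)))
  # huge z-spacing so the padded z-faces never drive the 2D distances
  dtf <- edt3d(padMask(f3), c(1e9, spacing[2], spacing[3]))[2, , ]
  er <- dtf[2:(nrow(foot) + 1), 2:(ncol(foot) + 1)] > rimExclusionUm
  if (!any(er)) stop("empty eroded region: rim exclusion removes the nucleus")
  vals <- proj[er]
  thr <- mean(vals) + intensityK * stats::sd(vals)
  bin <- er & proj > thr
  labs <- label3d(array(bin, c(1, dim(bin))), 26L)[1, , ]
  if (!any(labs > 0))
    return(list(count = 0L, areasUm2 = numeric(0), meanAreaUm2 = NA_real_))
  areas <- tabulate(labs[labs > 0]) * spacing[2] * spacing[3]
  areas <- areas[areas >= minAreaUm2]
  list(count = length(areas), areasUm2 = areas,
       meanAreaUm2 = if (length(areas)) mean(areas) else NA_real_)
}
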