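#' Maximum-intensity z-projection
#'
#' @param stack An [ImageStack-class].
#' @param channel Channel to project (default "gfp").
#' @param roi Optional list with `y` and `x` index ranges (inclusive
#'   2-vectors) restricting the projection.
#' @return 2D matrix (y, x) of per-pixel maxima over z.
#' @export
maxProject <- function(stack, channel = "gfp", roi = NULL) {
  img <- stack[[channel]]
  d <- dim(img)
  if (!is.null(roi)) {
    if (roi$y[1] < 1 || roi$y[2] > d[2] || roi$x[1] < 1 || roi$x[2] > d[3] ||
        roi$y[1] > roi$y[2] || roi$x[1] > roi$x[2])
      stop("empty or out-of-bounds roi")
    img <- img[, roi$y[1]:roi$y[2], roi$x[1]:roi$x[2], drop = FALSE]
  }
  apply(img, c(2, 3), max)
}

#' Detect spots as prominence-filtered local maxima (Fiji find-maxima style)
#'
#' Local maxima are retained when their prominence — the height above the
#' highest saddle connecting them to a stronger maximum (or above the image
#' minimum for the global maximum) — exceeds `noiseTolerance`. Candidates are
#' processed in decreasing intensity; equal-valued plateau duplicates are
#' suppressed. Results are ranked by intensity and truncated to
#' `maxSpots` (default 3: the reporter shows 1-3 dots per nucleus).
#'
#' @param projection 2D numeric matrix (y, x), typically a maximum
#'   z-projection.
#' @param noiseTolerance Positive prominence threshold.
#' @param maxSpots Maximum number of maxima to return.
#' @return Matrix with columns `y`, `x`, `value` (possibly 0 rows).
#' @examples
#' m <- matrix(10, 21, 21); m[11, 11] <- 100
#' detectSpots(m, noiseTolerance = 20)
#' @export
detectSpots <- function(projection, noiseTolerance, maxSpots = 3L) {
  stopifnot(noiseTolerance > 0)
  P <- projection
  ny <- nrow(P); nx <- ncol(P)
  pad <- matrix(-Inf, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- P
  isMax <- matrix(TRUE, ny, nx)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    isMax <- isMax & (P >= pad[(2 + dy):(ny + 1 + dy),
                               (2 + dx):(nx + 1 + dx)])
  }
  cand <- which(isMax)
  if (!length(cand)) return(emptySpotMatrix())
  cand <- cand[order(-P[cand], cand)]
  gmin <- min(P)
  accepted <- integer(0)
  acceptedVal <- numeric(0)
  for (m in cand) {
    v <- P[m]
    if (v - gmin <= noiseTolerance) next     # cannot protrude enough
    # flood the connected region of pixels > v - tolerance containing m
    lim <- v - noiseTolerance
    visited <- matrix(FALSE, ny, nx)
    queue <- m
    visited[m] <- TRUE
    reject <- FALSE
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      cy <- ((cur - 1) %% ny) + 1
      cx <- ((cur - 1) %/% ny) + 1
      if (P[cur] > v ||
          (P[cur] == v && cur %in% accepted)) { reject <- TRUE; break }
      for (dy in -1:1) for (dx in -1:1) {
        yy <- cy + dy; xx <- cx + dx
        if (yy < 1 || yy > ny || xx < 1 || xx > nx) next
        nb <- (xx - 1) * ny + yy
        if (!visited[nb] && P[nb] > lim) {
          visited[nb] <- TRUE
          queue <- c(queue, nb)
        }
      }
    }
    if (!reject) {
      accepted <- c(accepted, m)
      acceptedVal <- c(acceptedVal, v)
    }
  }
  if (!length(accepted)) return(emptySpotMatrix())
  ord <- order(-acceptedVal, accepted)[seq_len(min(maxSpots,
                                                   length(accepted)))]
  cbind(y = ((accepted[ord] - 1) %% ny) + 1,
        x = ((accepted[ord] - 1) %/% ny) + 1,
        value = acceptedVal[ord])
}

emptySpotMatrix <- function()
  cbind(y = integer(0), x = integer(0), value = numeric(0))

#' Assign a z-plane to a detected (y, x) spot position
#'
#' The z-index is the argmax of the channel intensity along the z-column at
#' `(y, x)`, restricted to the nucleus's plane extent, after 1-plane boxcar
#' smoothing; ties resolve to the lower z.
#'
#' @param stack An [ImageStack-class].
#' @param channel Channel name.
#' @param yx Integer `(y, x)` position.
#' @param record Nucleus record with `zMin`, `zMax`.
#' @return z plane index (absolute, 1-based).
#' @export
assignZ <- function(stack, channel, yx, record) {
  img <- stack[[channel]]
  col <- img[record$zMin:record$zMax, yx[1], yx[2]]
  if (all(col == 0)) stop("z-column is all zero at the requested position")
  n <- length(col)
  sm <- vapply(seq_len(n), function(i)
    mean(col[max(1, i - 1):min(n, i + 1)]), 0)
  record$zMin + which.max(sm) - 1L
}

#' Absolute radial distance of a voxel to the nuclear border
#'
#' Anisotropy-aware Euclidean distance from the spot voxel center to the
#' nearest background voxel center, computed with a 3D distance transform
#' whose per-axis sampling equals the voxel spacing.
#'
#' @param mask Logical 3D array (TRUE inside the nucleus).
#' @param spotVoxel Integer `(z, y, x)` voxel indices; must lie inside the
#'   mask.
#' @param spacing `(dz, dy, dx)` in um.
#' @return Distance in um.
#' @examples
#' m <- array(TRUE, c(3, 5, 5))
#' radialDistance(m, c(2, 3, 3), c(0.5, 0.1, 0.1))  # 0.3: lateral beats axial
#' @export
radialDistance <- function(mask, spotVoxel, spacing) {
  if (!mask[spotVoxel[1], spotVoxel[2], spotVoxel[3]])
    stop("spot voxel lies outside the nucleus mask")
  dt <- edt3d(padMask(mask), spacing)
  dt[spotVoxel[1] + 1, spotVoxel[2] + 1, spotVoxel[3] + 1]
}

# pad a mask with one background voxel on every face so that nuclei touching
# the crop boundary still see background there
padMask <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d + 2L)
  out[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  out
}

#' Normalize a radial distance to percent of the maximum attainable (Z/2)
#'
#' In 3D the height Z is the smallest nuclear dimension, so the largest
#' distance a locus can attain from the border is Z/2; the nuclear border
#' maps to 0% and the nuclear center to 100%.
#'
#' @param dAbsUm Absolute distance(s) in um (>= 0).
#' @param Z Nuclear height in um (> 0).
#' @return Normalized position(s) in percent, clipped to `[0, 100]`.
#' @examples
#' normalizeRadial(1.2, 6)  # 40
#' @export
normalizeRadial <- function(dAbsUm, Z) {
  if (any(Z <= 0)) stop("nuclear height Z must be positive")
  if (any(dAbsUm < 0)) stop("distances must be non-negative")
  pmin(pmax(100 * dAbsUm / (Z / 2), 0), 100)
}

#' Peripheral-layer membership of a normalized position
#'
#' A locus is "peripheral" when its normalized radial position lies within
#' the heterochromatin layer, i.e. at or below the layer thickness in
#' normalized units (boundary inclusive).
#'
#' @param rNormPct Normalized position(s), percent.
#' @param layerNormThicknessPct Layer thickness in normalized percent units.
#' @return Logical vector.
#' @export
classifyLayerMembership <- function(rNormPct, layerNormThicknessPct) {
  stopifnot(layerNormThicknessPct >= 0, layerNormThicknessPct <= 100)
  rNormPct <= layerNormThicknessPct
}

#' Detect and localize reporter spots for every segmented nucleus
#'
#' Runs the per-nucleus chain: maximum z-projection of the reporter channel
#' over the nucleus footprint, prominence-based maxima detection, z
#' assignment, absolute radial distance (anisotropic EDT to the nuclear
#' border) and normalization to the nucleus's own Z/2. Nuclei flagged as
#' touching the lateral border are skipped; calls whose voxel falls outside
#' the 3D nucleus mask are discarded as background.
#'
#' @param stack An [ImageStack-class] with reporter channel.
#' @param seg A [SegmentationResult-class] from the same stack.
#' @param channel Reporter channel name (default "gfp").
#' @param noiseTolerance Prominence threshold for [detectSpots()].
#' @param maxSpotsPerNucleus Maximum calls per nucleus (default 3).
#' @return `DataFrame` with one row per call: nucleusId, voxel indices
#'   (z, y, x), physical position (um), peak intensity, `dAbsUm`,
#'   `rNormPct`.
#' @export
spotTable <- function(stack, seg, channel = "gfp", noiseTolerance,
                      maxSpotsPerNucleus = 3L) {
  labs <- seg@labels
  sp <- seg@spacing
  nuc <- seg@nuclei
  rows <- list()
  for (i in seq_len(nrow(nuc))) {
    rec <- nuc[i, ]
    if (rec$touchesBorder) next
    sub <- labs[, rec$yMin:rec$yMax, rec$xMin:rec$xMax, drop = FALSE] ==
      rec$id
    foot <- apply(sub, c(2, 3), any)
    proj <- maxProject(stack, channel,
                       roi = list(y = c(rec$yMin, rec$yMax),
                                  x = c(rec$xMin, rec$xMax)))
    proj[!foot] <- min(proj[foot])
    calls <- detectSpots(proj, noiseTolerance, maxSpotsPerNucleus)
    if (!nrow(calls)) next
    mask <- labs == rec$id
    dt <- edt3d(padMask(mask), sp)
    img <- stack[[channel]]
    for (k in seq_len(nrow(calls))) {
      y <- rec$yMin + calls[k, "y"] - 1L
      x <- rec$xMin + calls[k, "x"] - 1L
      inCol <- which(mask[, y, x])
      if (!length(inCol)) {
        # border spot whose projected peak sits a pixel outside the
        # footprint: snap to the nearest footprint pixel (<= 3 px away)
        fy <- calls[k, "y"]; fx <- calls[k, "x"]
        cand <- which(foot, arr.ind = TRUE)
        dd <- (cand[, 1] - fy)^2 + (cand[, 2] - fx)^2
        if (min(dd) > 9) next                    # genuine background call
        best <- cand[which.min(dd), ]
        y <- rec$yMin + best[1] - 1L
        x <- rec$xMin + best[2] - 1L
        inCol <- which(mask[, y, x])
      }
      # argmax of the smoothed intensity column over in-mask planes
      col <- img[, y, x]
      n <- length(col)
      sm <- vapply(seq_len(n), function(i)
        mean(col[max(1, i - 1):min(n, i + 1)]), 0)
      z <- inCol[which.max(sm[inCol])]
      dAbs <- dt[z + 1, y + 1, x + 1]
      rows[[length(rows) + 1L]] <- list(
        nucleusId = rec$id, z = z, y = y, x = x,
        xUm = (x - 0.5) * sp[3], yUm = (y - 0.5) * sp[2],
        zUm = (z - 0.5) * sp[1],
        peakIntensity = calls[k, "value"], dAbsUm = dAbs,
        rNormPct = normalizeRadial(dAbs, rec$heightUm))
    }
  }
  if (!length(rows))
    return(S4Vectors::DataFrame(nucleusId = integer(), z = integer(),
                                y = integer(), x = integer(),
                                xUm = numeric(), yUm = numeric(),
                                zUm = numeric(), peakIntensity = numeric(),
                                dAbsUm = numeric(), rNormPct = numeric()))
  S4Vectors::DataFrame(do.call(rbind, lapply(rows, function(r)
    data.frame(r, stringsAsFactors = FALSE))))
}

#' Evaluate spot calls against ground truth
#'
#' Greedy nearest-neighbor one-to-one matching in 3D physical coordinates
#' within `matchRadiusUm`. The false-positive rate is the fraction of calls
#' left unmatched; the false-negative rate the fraction of (non-spurious)
#' truth spots left unmatched. Omitted (simulated false-negative) truth
#' spots stay in the truth table, so planted omission rates are recovered.
#'
#' @param calls Table with `xUm`, `yUm`, `zUm` (e.g. from [spotTable()]).
#' @param truth Ground-truth spot table (e.g. from [plantSpots()]); rows
#'   with `isSpurious = TRUE` are excluded from the truth side.
#' @param matchRadiusUm Maximum match distance (default 0.5 um).
#' @return List with `nTruth`, `nCalls`, `nMatched`, `fpRate`, `fnRate`,
#'   `matchRadiusUm`.
#' @export
evaluateDetection <- function(calls, truth, matchRadiusUm = 0.5) {
  stopifnot(matchRadiusUm > 0)
  if (!is.null(truth$isSpurious)) truth <- truth[!truth$isSpurious, ]
  nC <- nrow(calls); nT <- nrow(truth)
  nM <- 0L
  if (nC > 0 && nT > 0) {
    D <- outer(calls$xUm, truth$xUm, "-")^2 +
         outer(calls$yUm, truth$yUm, "-")^2 +
         outer(calls$zUm, truth$zUm, "-")^2
    D <- sqrt(D)
    repeat {
      mn <- which.min(D)
      if (!length(mn) || D[mn] > matchRadiusUm) break
      i <- ((mn - 1) %% nC) + 1
      j <- ((mn - 1) %/% nC) + 1
      D[i, ] <- Inf; D[, j] <- Inf
      nM <- nM + 1L
    }
  }
  list(nTruth = nT, nCalls = nC, nMatched = nM,
       fpRate = if (nC == 0) 0 else (nC - nM) / nC,
       fnRate = if (nT == 0) 0 else (nT - nM) / nT,
       matchRadiusUm = matchRadiusUm)
}
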