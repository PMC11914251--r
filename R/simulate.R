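#' Simulate a field of ellipsoidal nuclei in a DNA-stain channel
#'
#' Places `nNuclei` axis-aligned, pairwise non-overlapping ellipsoidal nuclei
#' in a 3D field and renders a "hoechst" channel: ellipsoid interiors at
#' `foreground` intensity, everything else at `background`, plus additive
#' Gaussian noise clipped to the bit-depth range. Nucleus centers are snapped
#' to z-plane boundaries and the z semi-axis c to a whole number of planes, so
#' the true height is exactly `Z = 2c` and coincides with the plane-count
#' height estimator used downstream.
#'
#' @param nNuclei Number of nuclei to place (0 gives a background-only stack).
#' @param fieldShape Stack shape `(nz, ny, nx)` in voxels.
#' @param spacing Voxel spacing `(dz, dy, dx)` in um.
#' @param foreground,background Mean interior / background intensity.
#' @param noiseSd Standard deviation of additive Gaussian noise (0 = none).
#' @param bitDepth Detector bit depth (intensities clipped to its range).
#' @param semiAxesXY Range (um) from which lateral semi-axes a, b are drawn.
#' @param semiAxisZ Range (um) for the z semi-axis c (snapped to multiples
#'   of dz).
#' @param margin Minimum clearance between nucleus bounding boxes (um).
#' @param maxTries Placement attempts per nucleus before giving up.
#' @param seed Optional RNG seed for reproducibility.
#' @return A list with `stack` (an [ImageStack-class] with channel
#'   "hoechst") and `nuclei`, a `DataFrame` of ground truth (centers and
#'   semi-axes in um, z-plane extent, `heightUm = 2c`).
#' @examples
#' fld <- makeNucleusField(2, fieldShape = c(14, 224, 224), seed = 1)
#' fld$nuclei
#' @export
makeNucleusField <- function(nNuclei, fieldShape = c(16L, 256L, 256L),
                             spacing = c(0.5, 0.1, 0.1),
                             foreground = 3000, background = 300,
                             noiseSd = 60, bitDepth = 16L,
                             semiAxesXY = c(2.8, 4.2), semiAxisZ = c(2, 3),
                             margin = 0.4, maxTries = 1000L, seed = NULL) {
  stopifnot(nNuclei >= 0, length(fieldShape) == 3)
  nz <- fieldShape[1]; ny <- fieldShape[2]; nx <- fieldShape[3]
  dz <- spacing[1]; dy <- spacing[2]; dx <- spacing[3]
  withSeed(seed, {
    kRange <- seq(ceiling(semiAxisZ[1] / dz), floor(semiAxisZ[2] / dz))
    if (length(kRange) == 0) stop("semiAxisZ range contains no multiple of dz")
    placed <- list()
    restarts <- 0L
    i <- 1L
    while (i <= nNuclei) {
      ok <- FALSE
      for (try in seq_len(maxTries)) {
        a <- runif(1, semiAxesXY[1], semiAxesXY[2])
        b <- runif(1, semiAxesXY[1], semiAxesXY[2])
        k <- if (length(kRange) == 1) kRange else sample(kRange, 1)
        cc <- k * dz
        if (2 * k > nz) next
        m <- if (nz - k >= k) sample(seq(k, nz - k), 1) else next
        cz <- m * dz
        loX <- a + margin; hiX <- nx * dx - a - margin
        loY <- b + margin; hiY <- ny * dy - b - margin
        if (loX >= hiX || loY >= hiY) next
        cx <- runif(1, loX, hiX)
        cy <- runif(1, loY, hiY)
        clash <- FALSE
        for (p in placed) {
          if (abs(cx - p$cx) <= a + p$a + margin &&
              abs(cy - p$cy) <= b + p$b + margin &&
              abs(cz - p$cz) <= cc + p$c + margin) { clash <- TRUE; break }
        }
        if (!clash) {
          placed[[i]] <- list(cx = cx, cy = cy, cz = cz, a = a, b = b,
                              c = cc, k = k, m = m)
          ok <- TRUE
          break
        }
      }
      if (ok) {
        i <- i + 1L
      } else {
        # dead-end layout: discard it and replan the whole field
        restarts <- restarts + 1L
        if (restarts > 25L)
          stop("cannot place nuclei: field too crowded after ",
               maxTries, " attempts and ", restarts - 1L, " restarts")
        placed <- list()
        i <- 1L
      }
    }
    img <- array(background, c(nz, ny, nx))
    zc <- axisCenters(nz, dz); yc <- axisCenters(ny, dy)
    xc <- axisCenters(nx, dx)
    for (p in placed) {
      zi <- which(abs(zc - p$cz) < p$c)
      yi <- which(abs(yc - p$cy) < p$b)
      xi <- which(abs(xc - p$cx) < p$a)
      ez <- ((zc[zi] - p$cz) / p$c)^2
      ey <- ((yc[yi] - p$cy) / p$b)^2
      ex <- ((xc[xi] - p$cx) / p$a)^2
      inside <- outer(outer(ez, ey, "+"), ex, "+") <= 1
      sub <- img[zi, yi, xi, drop = FALSE]
      sub[inside] <- foreground
      img[zi, yi, xi] <- sub
    }
    if (noiseSd > 0)
      img <- img + array(rnorm(length(img), 0, noiseSd), dim(img))
    img <- pmin(pmax(img, 0), 2^bitDepth - 1)
    truth <- S4Vectors::DataFrame(
      id = seq_along(placed),
      cxUm = vapply(placed, `[[`, 0, "cx"),
      cyUm = vapply(placed, `[[`, 0, "cy"),
      czUm = vapply(placed, `[[`, 0, "cz"),
      aUm = vapply(placed, `[[`, 0, "a"),
      bUm = vapply(placed, `[[`, 0, "b"),
      cUm = vapply(placed, `[[`, 0, "c"),
      zPlaneMin = vapply(placed, function(p) p$m - p$k + 1, 0),
      zPlaneMax = vapply(placed, function(p) p$m + p$k, 0),
      heightUm = vapply(placed, function(p) 2 * p$c, 0))
    list(stack = ImageStack(list(hoechst = img), spacing = spacing,
                            bitDepth = as.integer(bitDepth)),
         nuclei = truth)
  })
}

#' Plant diffraction-limited reporter spots at known radial positions
#'
#' Renders a "gfp" channel containing one 3D Gaussian spot per planted locus.
#' Each spot's true normalized radial position r (percent of Z/2, 0 = border,
#' 100 = center) is drawn from `rSampler`; the spot is placed along a random
#' ray from the nucleus center at the point whose exact shortest distance to
#' the ellipsoid surface equals `r/100 * Z/2`. Planted spots are omitted from
#' the image (but kept, flagged, in the truth table) with probability
#' `fnRate`; spurious background spots are added with probability `fpRate`
#' per nucleus.
#'
#' @param field Result of [makeNucleusField()] (list with `stack`, `nuclei`),
#'   or an [ImageStack-class] plus a `nuclei` truth table.
#' @param nucleiTruth Ground-truth nucleus table (defaults to
#'   `field$nuclei`).
#' @param rSampler Function `n -> n` values in `[0, 100]`; default a
#'   peripherally biased scaled Beta(1.2, 3) mimicking a lamina-tethered
#'   locus.
#' @param spotsPerNucleus Integer count per nucleus, or NULL to draw 1-3
#'   dots per nucleus uniformly (the reporter phenotype).
#' @param fpRate,fnRate Spurious-spot and omission probabilities in `[0, 1)`.
#' @param psfSigma Gaussian PSF sigma `(z, xy)` in um.
#' @param amplitude Peak spot intensity above background.
#' @param background,noiseSd Channel baseline and Gaussian noise sd.
#' @param channel Name for the new channel (default "gfp").
#' @param seed Optional RNG seed.
#' @return List with `stack` (input stack plus the new channel) and `spots`,
#'   a `DataFrame`: nucleusId, xUm/yUm/zUm, dTrueUm, rTruePct, isSpurious,
#'   omitted.
#' @examples
#' fld <- makeNucleusField(1, fieldShape = c(12, 96, 96), seed = 1)
#' ps <- plantSpots(fld, spotsPerNucleus = 2, seed = 2)
#' ps$spots
#' @export
plantSpots <- function(field, nucleiTruth = field$nuclei,
                       rSampler = function(n) 100 * stats::rbeta(n, 1.2, 3),
                       spotsPerNucleus = NULL, fpRate = 0, fnRate = 0,
                       psfSigma = c(z = 0.6, xy = 0.15), amplitude = 8000,
                       background = 200, noiseSd = 40, channel = "gfp",
                       seed = NULL) {
  stack <- if (is(field, "ImageStack")) field else field$stack
  stopifnot(fpRate >= 0, fpRate < 1, fnRate >= 0, fnRate < 1)
  d <- dim(stack); sp <- stack@spacing
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  withSeed(seed, {
    rows <- list()
    for (i in seq_len(nrow(nucleiTruth))) {
      nuc <- nucleiTruth[i, ]
      ctr <- c(nuc$cxUm, nuc$cyUm, nuc$czUm)         # (x, y, z)
      ax <- c(nuc$aUm, nuc$bUm, nuc$cUm)
      ns <- if (is.null(spotsPerNucleus)) sample(1:3, 1)
            else as.integer(spotsPerNucleus)
      rv <- rSampler(ns)
      if (any(rv < 0 | rv > 100))
        stop("rSampler emitted values outside [0, 100]")
      for (r in rv) {
        dTarget <- r / 100 * nuc$heightUm / 2
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        sB <- 1 / sqrt(sum((u / ax)^2))
        if (dTarget >= min(ax) - 1e-9) {
          s <- 0
        } else if (dTarget <= 1e-9) {
          s <- sB
        } else {
          g <- function(s) ellipsoidSurfaceDistance(
            rbind(ctr + s * u), ctr, ax) - dTarget
          s <- stats::uniroot(g, c(0, sB), tol = 1e-10)$root
        }
        pos <- ctr + s * u
        dTrue <- ellipsoidSurfaceDistance(rbind(pos), ctr, ax)
        rows[[length(rows) + 1L]] <- list(
          nucleusId = nuc$id, xUm = pos[1], yUm = pos[2], zUm = pos[3],
          dTrueUm = dTrue, rTruePct = r, isSpurious = FALSE,
          omitted = runif(1) < fnRate)
      }
      if (runif(1) < fpRate) {
        for (try in seq_len(200)) {
          pos <- c(runif(1, 0.5, nx * sp[3] - 0.5),
                   runif(1, 0.5, ny * sp[2] - 0.5),
                   runif(1, sp[1], (nz - 1) * sp[1]))
          insideAny <- FALSE
          for (j in seq_len(nrow(nucleiTruth))) {
            nj <- nucleiTruth[j, ]
            v <- ((pos[1] - nj$cxUm) / nj$aUm)^2 +
                 ((pos[2] - nj$cyUm) / nj$bUm)^2 +
                 ((pos[3] - nj$czUm) / nj$cUm)^2
            if (v <= 1.2) { insideAny <- TRUE; break }
          }
          if (!insideAny) {
            rows[[length(rows) + 1L]] <- list(
              nucleusId = NA_integer_, xUm = pos[1], yUm = pos[2],
              zUm = pos[3], dTrueUm = NA_real_, rTruePct = NA_real_,
              isSpurious = TRUE, omitted = FALSE)
            break
          }
        }
      }
    }
    img <- array(background, d)
    zc <- axisCenters(nz, sp[1]); yc <- axisCenters(ny, sp[2])
    xc <- axisCenters(nx, sp[3])
    sz <- psfSigma[[1]]; sxy <- psfSigma[[2]]
    for (row in rows) {
      if (row$omitted) next
      zi <- which(abs(zc - row$zUm) <= 4 * sz)
      yi <- which(abs(yc - row$yUm) <= 4 * sxy)
      xi <- which(abs(xc - row$xUm) <= 4 * sxy)
      if (!length(zi) || !length(yi) || !length(xi)) next
      ez <- ((zc[zi] - row$zUm) / sz)^2
      ey <- ((yc[yi] - row$yUm) / sxy)^2
      ex <- ((xc[xi] - row$xUm) / sxy)^2
      g <- amplitude * exp(-0.5 * outer(outer(ez, ey, "+"), ex, "+"))
      img[zi, yi, xi] <- img[zi, yi, xi] + g
    }
    if (noiseSd > 0)
      img <- img + array(rnorm(length(img), 0, noiseSd), d)
    img <- pmin(pmax(img, 0), 2^stack@bitDepth - 1)
    spots <- if (length(rows)) {
      S4Vectors::DataFrame(do.call(rbind, lapply(rows, function(r)
        data.frame(r, stringsAsFactors = FALSE))))
    } else {
      S4Vectors::DataFrame(nucleusId = integer(), xUm = numeric(),
                           yUm = numeric(), zUm = numeric(),
                           dTrueUm = numeric(), rTruePct = numeric(),
                           isSpurious = logical(), omitted = logical())
    }
    list(stack = setChannel(stack, channel, img), spots = spots)
  })
}

#' Render a chromatin-mark channel with a peripheral shell and interior foci
#'
#' Emulates the two heterochromatin phenotypes the chromatin-profile module
#' quantifies: a high-intensity rim of given physical thickness just inside
#' the nuclear border (peripheral heterochromatin layer) and bright spherical
#' foci in the nuclear interior. Shell membership uses the exact analytic
#' distance to the ellipsoid surface.
#'
#' @inheritParams plantSpots
#' @param shellThicknessUm Rim thickness in um (must be smaller than the
#'   smallest semi-axis).
#' @param shellGain Rim intensity as a multiple of the interior intensity
#'   (1 = no layer).
#' @param nFoci Number of interior foci per nucleus.
#' @param focusRadiusUm Focus radius (um).
#' @param fociGain Focus intensity as a multiple of the interior intensity.
#' @param interiorGain Mean intensity of the nuclear interior.
#' @param maxTries Redraw attempts for foci that would overlap the shell.
#' @return List with `stack` (channel added) and `truth` (shell thickness,
#'   per-focus centers/radius/area `pi r^2` in um^2).
#' @examples
#' fld <- makeNucleusField(1, fieldShape = c(12, 96, 96), seed = 1)
#' ch <- makeChromatinChannel(fld, shellThicknessUm = 0.8, seed = 2)
#' @export
makeChromatinChannel <- function(field, nucleiTruth = field$nuclei,
                                 shellThicknessUm = 0.8, shellGain = 2,
                                 nFoci = 0L, focusRadiusUm = 0.6,
                                 fociGain = 2.5, interiorGain = 1500,
                                 background = 200, noiseSd = 0,
                                 channel = "stain", maxTries = 200L,
                                 seed = NULL) {
  stack <- if (is(field, "ImageStack")) field else field$stack
  d <- dim(stack); sp <- stack@spacing
  if (nrow(nucleiTruth) > 0 &&
      shellThicknessUm >= min(nucleiTruth$aUm, nucleiTruth$bUm,
                              nucleiTruth$cUm))
    stop("shellThicknessUm must be smaller than the smallest semi-axis")
  withSeed(seed, {
    img <- array(background, d)
    zc <- axisCenters(d[1], sp[1]); yc <- axisCenters(d[2], sp[2])
    xc <- axisCenters(d[3], sp[3])
    fociRows <- list()
    for (i in seq_len(nrow(nucleiTruth))) {
      nuc <- nucleiTruth[i, ]
      ctr <- c(nuc$cxUm, nuc$cyUm, nuc$czUm)
      ax <- c(nuc$aUm, nuc$bUm, nuc$cUm)
      zi <- which(abs(zc - ctr[3]) < ax[3])
      yi <- which(abs(yc - ctr[2]) < ax[2])
      xi <- which(abs(xc - ctr[1]) < ax[1])
      grid <- expand.grid(z = zc[zi], y = yc[yi], x = xc[xi])
      pts <- cbind(grid$x, grid$y, grid$z)
      inside <- ((pts[, 1] - ctr[1]) / ax[1])^2 +
                ((pts[, 2] - ctr[2]) / ax[2])^2 +
                ((pts[, 3] - ctr[3]) / ax[3])^2 <= 1
      val <- rep(NA_real_, nrow(pts))
      sd2 <- ellipsoidSurfaceDistance(pts[inside, , drop = FALSE], ctr, ax)
      val[inside] <- ifelse(sd2 <= shellThicknessUm,
                            shellGain * interiorGain, interiorGain)
      # foci: redrawn until clear of the shell (and of each other)
      centers <- matrix(numeric(0), ncol = 3)
      for (f in seq_len(nFoci)) {
        placedF <- FALSE
        for (try in seq_len(maxTries)) {
          cand <- ctr + c(runif(1, -ax[1], ax[1]), runif(1, -ax[2], ax[2]),
                          runif(1, -ax[3], ax[3]))
          v <- sum(((cand - ctr) / ax)^2)
          if (v > 1) next
          sdC <- ellipsoidSurfaceDistance(rbind(cand), ctr, ax)
          if (sdC < shellThicknessUm + focusRadiusUm + 0.1) next
          if (nrow(centers) &&
              any(sqrt(rowSums(sweep(centers, 2, cand)^2)) <
                  2 * focusRadiusUm + 0.1)) next
          centers <- rbind(centers, cand)
          placedF <- TRUE
          break
        }
        if (!placedF) stop("cannot place foci clear of the shell after ",
                           maxTries, " attempts")
        fociRows[[length(fociRows) + 1L]] <- list(
          nucleusId = nuc$id, xUm = centers[nrow(centers), 1],
          yUm = centers[nrow(centers), 2], zUm = centers[nrow(centers), 3],
          radiusUm = focusRadiusUm, areaUm2 = pi * focusRadiusUm^2)
      }
      if (nrow(centers)) {
        for (f in seq_len(nrow(centers))) {
          df <- sqrt((pts[, 1] - centers[f, 1])^2 +
                     (pts[, 2] - centers[f, 2])^2 +
                     (pts[, 3] - centers[f, 3])^2)
          val[df <= focusRadiusUm] <- fociGain * interiorGain
        }
      }
      sub <- img[zi, yi, xi, drop = FALSE]
      keep <- !is.na(val)
      sub[array(keep, dim(sub))] <- val[keep]
      img[zi, yi, xi] <- sub
    }
    if (noiseSd > 0)
      img <- img + array(rnorm(length(img), 0, noiseSd), d)
    img <- pmin(pmax(img, 0), 2^stack@bitDepth - 1)
    foci <- if (length(fociRows))
      S4Vectors::DataFrame(do.call(rbind, lapply(fociRows, function(r)
        data.frame(r, stringsAsFactors = FALSE))))
    else S4Vectors::DataFrame(nucleusId = integer(), xUm = numeric(),
                              yUm = numeric(), zUm = numeric(),
                              radiusUm = numeric(), areaUm2 = numeric())
    list(stack = setChannel(stack, channel, img),
         truth = list(shellThicknessUm = shellThicknessUm, foci = foci))
  })
}
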