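test_that("empty and noiseless nucleus fields are exact", {
  fld0 <- makeNucleusField(0, fieldShape = c(8, 64, 64), noiseSd = 0,
                           seed = 1)
  expect_equal(nrow(fld0$nuclei), 0)
  expect_true(all(fld0$stack[["hoechst"]] == 300))

  fld <- makeNucleusField(1, fieldShape = c(14, 96, 96), noiseSd = 0,
                          foreground = 3000, background = 300, seed = 2)
  nuc <- fld$nuclei[1, ]
  img <- fld$stack[["hoechst"]]
  sp <- spacing(fld$stack)
  # voxels inside the analytic ellipsoid carry the foreground value exactly
  zc <- (seq_len(dim(img)[1]) - 0.5) * sp[1]
  yc <- (seq_len(dim(img)[2]) - 0.5) * sp[2]
  xc <- (seq_len(dim(img)[3]) - 0.5) * sp[3]
  v <- sample(which(img == 3000), 50)
  idx <- arrayInd(v, dim(img))
  e <- ((zc[idx[, 1]] - nuc$czUm) / nuc$cUm)^2 +
       ((yc[idx[, 2]] - nuc$cyUm) / nuc$bUm)^2 +
       ((xc[idx[, 3]] - nuc$cxUm) / nuc$aUm)^2
  expect_true(all(e <= 1))
  # truth height is 2c snapped to the plane grid
  expect_equal(nuc$heightUm, 2 * nuc$cUm)
  expect_equal((nuc$zPlaneMax - nuc$zPlaneMin + 1) * unname(sp[1]),
               nuc$heightUm)
})

test_that("field generation is deterministic under a fixed seed", {
  a <- makeNucleusField(5, seed = 7)
  b <- makeNucleusField(5, seed = 7)
  expect_identical(a$stack[["hoechst"]], b$stack[["hoechst"]])
  expect_identical(as.data.frame(a$nuclei), as.data.frame(b$nuclei))
  pa <- plantSpots(a, spotsPerNucleus = 2, seed = 9)
  pb <- plantSpots(b, spotsPerNucleus = 2, seed = 9)
  expect_identical(pa$stack[["gfp"]], pb$stack[["gfp"]])
  expect_identical(as.data.frame(pa$spots), as.data.frame(pb$spots))
})

test_that("overcrowded fields fail with a placement error", {
  expect_error(makeNucleusField(40, fieldShape = c(12, 96, 96),
                                maxTries = 20, seed = 1),
               "cannot place nuclei")
})

test_that("planted spots sit at their requested radial positions", {
  fld <- makeNucleusField(2, fieldShape = c(16, 224, 224), seed = 11)
  # r = 0: on the surface; r = 100: at the center-distance d = Z/2
  ps0 <- plantSpots(fld, rSampler = function(n) rep(0, n),
                    spotsPerNucleus = 1, seed = 2)
  expect_true(all(abs(ps0$spots$dTrueUm) < 1e-6))
  ps100 <- plantSpots(fld, rSampler = function(n) rep(100, n),
                      spotsPerNucleus = 1, seed = 3)
  expect_equal(ps100$spots$dTrueUm, fld$nuclei$heightUm / 2,
               tolerance = 1e-6)
  # sampler emitting out-of-range values is rejected
  expect_error(plantSpots(fld, rSampler = function(n) rep(120, n),
                          spotsPerNucleus = 1, seed = 4),
               "outside")
})

test_that("stored true distances agree with a brute-force surface search", {
  fld <- makeNucleusField(2, fieldShape = c(16, 224, 224), seed = 13)
  ps <- plantSpots(fld, spotsPerNucleus = 3, seed = 14)
  tr <- ps$spots[!ps$spots$isSpurious, ]
  for (i in seq_len(nrow(tr))) {
    nuc <- fld$nuclei[fld$nuclei$id == tr$nucleusId[i], ]
    ref <- oracleEllipsoidDist(c(tr$xUm[i], tr$yUm[i], tr$zUm[i]),
                               c(nuc$cxUm, nuc$cyUm, nuc$czUm),
                               c(nuc$aUm, nuc$bUm, nuc$cUm))
    expect_lt(abs(ref - tr$dTrueUm[i]), 1e-6)
  }
})

test_that("omission flags follow the requested false-negative rate", {
  fld <- makeNucleusField(4, fieldShape = c(16, 256, 256), seed = 5)
  nOm <- 0L; nTot <- 0L
  for (s in 1:85) {
    ps <- plantSpots(fld, spotsPerNucleus = 3, fnRate = 0.19, noiseSd = 0,
                     seed = s)
    nOm <- nOm + sum(ps$spots$omitted)
    nTot <- nTot + nrow(ps$spots)
  }
  # ~1000 Bernoulli(0.19) draws: stay within the 99.9% binomial band
  expect_gt(nTot, 900)
  ci <- 0.19 + c(-1, 1) * 3.3 * sqrt(0.19 * 0.81 / nTot)
  expect_gt(nOm / nTot, ci[1])
  expect_lt(nOm / nTot, ci[2])
  # omitted spots contribute no intensity: image equals the fn-free render
  ps1 <- plantSpots(fld, spotsPerNucleus = 1, fnRate = 0, noiseSd = 0,
                    seed = 77)
  ps2 <- plantSpots(fld, spotsPerNucleus = 1, fnRate = 0.9999, noiseSd = 0,
                    seed = 77)
  expect_identical(sum(ps2$spots$omitted), nrow(ps2$spots))
  expect_true(all(ps2$stack[["gfp"]] == 200))
  expect_gt(max(ps1$stack[["gfp"]]), 5000)
})

test_that("chromatin shell geometry matches the analytic ellipsoid", {
  fld <- makeNucleusField(1, fieldShape = c(16, 128, 128), noiseSd = 0,
                          seed = 3)
  ch <- makeChromatinChannel(fld, shellThicknessUm = 0.8, shellGain = 2,
                             noiseSd = 0, seed = 4)
  img <- ch$stack[["stain"]]
  sp <- spacing(ch$stack)
  nuc <- fld$nuclei[1, ]
  # classify voxels analytically and compare intensities
  shellIdx <- which(img == 3000)
  idx <- arrayInd(sample(shellIdx, 50), dim(img))
  pts <- cbind((idx[, 3] - 0.5) * sp[3], (idx[, 2] - 0.5) * sp[2],
               (idx[, 1] - 0.5) * sp[1])
  dists <- vapply(seq_len(nrow(pts)), function(i)
    oracleEllipsoidDist(pts[i, ], c(nuc$cxUm, nuc$cyUm, nuc$czUm),
                        c(nuc$aUm, nuc$bUm, nuc$cUm)), 0)
  expect_true(all(dists <= 0.8 + 1e-6))
  # null phenotype: gain 1, no foci -> uniform interior
  ch0 <- makeChromatinChannel(fld, shellThicknessUm = 0.8, shellGain = 1,
                              nFoci = 0, noiseSd = 0, seed = 5)
  expect_setequal(unique(as.numeric(ch0$stack[["stain"]])), c(200, 1500))
  # two foci of radius r: truth areas are exactly pi r^2
  ch2 <- makeChromatinChannel(fld, shellThicknessUm = 0.5, nFoci = 2,
                              focusRadiusUm = 0.6, seed = 6)
  expect_equal(ch2$truth$foci$areaUm2, rep(pi * 0.36, 2))
})
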