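test_that("max projection reduces z correctly", {
  arr <- array(5, c(4, 6, 6))
  st <- ImageStack(list(gfp = arr))
  expect_true(all(maxProject(st) == 5))
  arr[3, 4, 2] <- 99
  st <- ImageStack(list(gfp = arr))
  p <- maxProject(st)
  expect_equal(p[4, 2], 99)
  expect_equal(sum(p == 99), 1)
  expect_error(maxProject(st, roi = list(y = c(5, 3), x = c(1, 2))),
               "roi")
})

test_that("prominence-based maxima detection follows find-maxima rules", {
  # uniform image: no maxima
  expect_equal(nrow(detectSpots(matrix(7, 15, 15), 5)), 0)
  # one Gaussian, amplitude 100 over background 10, tolerance 20
  g <- outer(1:21, 1:21, function(y, x)
    10 + 100 * exp(-((y - 11)^2 + (x - 11)^2) / 8))
  m <- detectSpots(g, 20)
  expect_equal(nrow(m), 1)
  expect_equal(unname(m[1, c("y", "x")]), c(11, 11))
  # two spots 10 px apart, both prominent
  g2 <- outer(1:31, 1:31, function(y, x)
    10 + 100 * exp(-((y - 10)^2 + (x - 15)^2) / 6) +
    80 * exp(-((y - 20)^2 + (x - 15)^2) / 6))
  m2 <- detectSpots(g2, 20)
  expect_equal(nrow(m2), 2)
  # a shoulder below tolerance merges into the main maximum
  g3 <- outer(1:31, 1:31, function(y, x)
    10 + 100 * exp(-((y - 14)^2 + (x - 15)^2) / 20) +
    5 * exp(-((y - 20)^2 + (x - 15)^2) / 4))
  expect_equal(nrow(detectSpots(g3, 20)), 1)
  # ranking and truncation
  m4 <- detectSpots(g2, 20, maxSpots = 1)
  expect_equal(nrow(m4), 1)
  expect_equal(unname(m4[1, "y"]), 10)
})

test_that("z assignment takes the smoothed column argmax with low-z ties", {
  arr <- array(1, c(10, 5, 5))
  arr[6:8, 3, 3] <- c(20, 50, 20)     # peaked column, as a real PSF gives
  st <- ImageStack(list(gfp = arr))
  rec <- list(zMin = 1L, zMax = 10L)
  expect_equal(assignZ(st, "gfp", c(3, 3), rec), 7)
  # constant column: tie resolves to zMin
  expect_equal(assignZ(st, "gfp", c(1, 1), rec), 1)
  # two-plane plateau: lower plane wins
  arr2 <- array(1, c(10, 5, 5))
  arr2[5:6, 3, 3] <- 50
  st2 <- ImageStack(list(gfp = arr2))
  expect_equal(assignZ(st2, "gfp", c(3, 3), rec), 5)
  arr3 <- array(0, c(4, 3, 3))
  st3 <- ImageStack(list(gfp = arr3))
  expect_error(assignZ(st3, "gfp", c(2, 2), list(zMin = 1L, zMax = 4L)),
               "all zero")
})

test_that("radial distance matches adjacency and box-mask arithmetic", {
  # boundary voxel: one lateral step to background
  m <- array(TRUE, c(3, 5, 5))
  expect_equal(radialDistance(m, c(2, 1, 3), c(0.5, 0.1, 0.1)), 0.1)
  # center of a 5x5x3 box: 3 lateral voxels (0.3) beat 2 axial planes (1.0)
  expect_equal(radialDistance(m, c(2, 3, 3), c(0.5, 0.1, 0.1)), 0.3)
  expect_error(radialDistance(!m, c(2, 3, 3), c(0.5, 0.1, 0.1)),
               "outside")
})

test_that("radial distance equals the brute-force background minimum", {
  set.seed(55)
  for (rep in 1:40) {
    d <- c(sample(3:12, 1), sample(4:20, 1), sample(4:20, 1))
    m <- array(runif(prod(d)) > 0.35, d)
    sp <- c(0.5, 0.1, 0.1)
    fg <- which(m, arr.ind = TRUE)
    if (!nrow(fg) || all(m)) next
    pick <- fg[sample(nrow(fg), min(5, nrow(fg))), , drop = FALSE]
    for (k in seq_len(nrow(pick))) {
      v <- pick[k, ]
      ref <- min(oracleVoxelDist(m, v, sp),
                 # padded faces are background one step outside
                 (v[1] - 0) * sp[1], (d[1] + 1 - v[1]) * sp[1],
                 (v[2] - 0) * sp[2], (d[2] + 1 - v[2]) * sp[2],
                 (v[3] - 0) * sp[3], (d[3] + 1 - v[3]) * sp[3])
      expect_lt(abs(radialDistance(m, v, sp) - ref), 1e-9)
    }
  }
})

test_that("normalization maps border to 0, center to 100", {
  expect_equal(normalizeRadial(0, 6), 0)
  expect_equal(normalizeRadial(3, 6), 100)
  expect_equal(normalizeRadial(1.2, 6), 40)
  expect_equal(normalizeRadial(4, 6), 100)   # clipped
  expect_error(normalizeRadial(1, 0), "positive")
})

test_that("r_norm is monotone along a ray from border to center", {
  fld <- makeNucleusField(1, fieldShape = c(16, 128, 128), noiseSd = 0,
                          seed = 61)
  nuc <- fld$nuclei[1, ]
  seg <- segmentNuclei(fld$stack)
  mask <- labelVolume(seg) == 1
  sp <- spacing(fld$stack)
  dt <- periloc:::edt3d(periloc:::padMask(mask), sp)
  # walk along +x at the nucleus mid-height
  z <- round(nuc$czUm / sp[1])
  y <- round(nuc$cyUm / sp[2])
  xs <- which(mask[z, y, ])
  dvals <- dt[z + 1, y + 1, xs[xs <= round(nuc$cxUm / sp[3])] + 1]
  r <- normalizeRadial(dvals, nuc$heightUm)
  expect_true(all(diff(r) >= -1e-9))
})

test_that("layer membership is boundary-inclusive", {
  expect_true(classifyLayerMembership(0, 10))
  expect_false(classifyLayerMembership(100, 10))
  expect_true(classifyLayerMembership(10, 10))
})

test_that("detection evaluation counts matches greedily", {
  truth <- data.frame(xUm = c(1, 2, 3), yUm = 1, zUm = 1,
                      isSpurious = FALSE)
  callsEq <- data.frame(xUm = c(1, 2, 3), yUm = 1, zUm = 1)
  ev <- evaluateDetection(callsEq, truth)
  expect_equal(ev$fpRate, 0)
  expect_equal(ev$fnRate, 0)
  # 10 truth, 11 calls, 10 matched -> FP = 1/11, FN = 0
  t10 <- data.frame(xUm = seq(1, 10), yUm = 0, zUm = 0,
                    isSpurious = FALSE)
  c11 <- data.frame(xUm = c(seq(1, 10) + 0.1, 50), yUm = 0, zUm = 0)
  ev2 <- evaluateDetection(c11, t10)
  expect_equal(ev2$fpRate, 1 / 11)
  expect_equal(ev2$fnRate, 0)
  # 20 truth, 20 calls, 16 matched -> FP = FN = 20%
  t20 <- data.frame(xUm = seq(1, 20) * 2, yUm = 0, zUm = 0,
                    isSpurious = FALSE)
  c20 <- data.frame(xUm = c(seq(1, 16) * 2 + 0.2, 100, 110, 120, 130),
                    yUm = 0, zUm = 0)
  ev3 <- evaluateDetection(c20, t20)
  expect_equal(ev3$fpRate, 0.2)
  expect_equal(ev3$fnRate, 0.2)
  # empty sides are defined as zero rates
  expect_equal(evaluateDetection(callsEq[0, ], t10)$fpRate, 0)
  expect_equal(evaluateDetection(callsEq[0, ], t10)$fnRate, 1)
  expect_equal(evaluateDetection(c11, t10[0, ])$fnRate, 0)
})
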