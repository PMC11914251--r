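test_that("KS test reproduces exact small-sample p-values", {
  r <- ksTwoSample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(statValue(r)), 0)
  expect_equal(pValue(r), 1)
  r2 <- ksTwoSample(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(statValue(r2)), 1)
  expect_equal(pValue(r2), 0.1)      # 2 of the 20 assignments are extreme
  expect_error(ksTwoSample(numeric(0), 1:3), "non-empty")
})

test_that("exact KS p equals the full-permutation oracle for n+m <= 12", {
  set.seed(77)
  for (n in 2:6) for (m in n:min(6, 12 - n)) {
    x <- round(rnorm(n), 2)
    y <- round(rnorm(m, 0.5), 2)
    if (anyDuplicated(c(x, y))) next
    expect_equal(pValue(ksTwoSample(x, y)), oracleKsPerm(x, y),
                 tolerance = 1e-10,
                 info = sprintf("n=%d m=%d", n, m))
  }
})

test_that("Hochberg adjustment matches the step-up formula", {
  expect_equal(hochbergAdjust(c(0.01, 0.04, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(hochbergAdjust(0.2), 0.2)
  expect_equal(hochbergAdjust(rep(1, 5)), rep(1, 5))
  expect_error(hochbergAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(5)
  for (rep in 1:300) {
    p <- runif(sample(1:12, 1))
    adj <- hochbergAdjust(p)
    expect_equal(adj, oracleHochberg(p))
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    # monotone in the sorted order
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))
  }
})

test_that("two-sided t p-values match quadrature of the t density", {
  expect_equal(signif(pFromT(8.31, 7), 2), 7.1e-5)
  expect_equal(pFromT(0, 12), 1)
  set.seed(9)
  for (rep in 1:25) {
    t <- runif(1, 0, 6); v <- sample(3:40, 1)
    q <- stats::integrate(function(u) stats::dt(u, v), abs(t), Inf,
                          rel.tol = 1e-12)$value
    expect_equal(pFromT(t, v), 2 * q, tolerance = 1e-8)
  }
})

test_that("t tests report statistic, df and effect size coherently", {
  set.seed(11)
  x <- rnorm(9, 1); y <- rnorm(12)
  r <- tTest(x, y)
  expect_equal(r@df, 19)
  expect_equal(pValue(r), pFromT(unname(statValue(r)), 19))
  expect_equal(r@effectSize, cohensD(x, y))
  rw <- tTest(x, y, welch = TRUE)
  expect_lt(rw@df, 19 + 1e-9)
  # degenerate equal constants give p = 1 by convention
  expect_equal(pValue(tTest(rep(2, 3), rep(2, 4))), 1)
  expect_error(tTest(rep(1, 3), rep(2, 4)), "zero variance")
})

test_that("Kruskal-Wallis and Dunn follow the rank formulas", {
  expect_equal(unname(statValue(kruskalWallis(list(c(1, 2), c(1, 2))))), 0)
  r <- kruskalWallis(list(c(1, 2), c(3, 4)))
  expect_equal(unname(statValue(r)), 2.4)  # ranks 1,2 vs 3,4 with N = 4
  r3 <- kruskalWallis(list(c(1, 2, 9), c(3, 4), c(5, 6)))
  expect_equal(r3@df, 2)                   # reported as H(2)
  # identical observations: H = 0, p = 1
  expect_equal(pValue(kruskalWallis(list(c(2, 2), c(2, 2)))), 1)
  dn <- dunnPosthoc(list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9)))
  expect_length(dn, 3)
  # hand check of the first pair: mean ranks 2 and 5, N = 9, no ties
  z <- (2 - 5) / sqrt((9 * 10 / 12) * (1 / 3 + 1 / 3))
  expect_equal(unname(statValue(dn[["a vs b"]])), z)
  expect_true(all(vapply(dn, function(r) pAdjusted(r) >= pValue(r), TRUE)))
})

test_that("Cohen's d follows the pooled-sd formula", {
  expect_equal(cohensD(c(1, 2, 3), c(1, 2, 3)), 0)
  x <- c(0, 2); y <- c(2, 4)            # means differ by one pooled sd
  expect_equal(cohensD(y, x), sqrt(2))  # pooled sd = sqrt(2)
  set.seed(13)
  a <- rnorm(20); b <- rnorm(25, 0.4)
  sp <- sqrt((19 * var(a) + 24 * var(b)) / 43)
  expect_equal(cohensD(a, b), (mean(a) - mean(b)) / sp)
  expect_error(cohensD(rep(1, 3), rep(1, 4)), "zero pooled")
})

test_that("distribution summaries report medians and bounded densities", {
  s <- summarizeDistribution(c(0, 100))
  expect_equal(s$median, 50)
  sc <- summarizeDistribution(rep(42, 5))
  expect_equal(sc$median, 42)
  expect_true(sc$degenerate)
  set.seed(17)
  v <- 100 * rbeta(2000, 2, 5)
  sv <- summarizeDistribution(v)
  expect_false(sv$degenerate)
  # KDE mode near the true Beta(2, 5) mode at 100 * 1/5 = 20
  expect_lt(abs(sv$x[which.max(sv$density)] - 20), 6)
  # boundary reflection approximately conserves mass on the support
  mass <- sum(sv$density) * diff(sv$x[1:2])
  expect_equal(mass, 1, tolerance = 0.02)
})

test_that("KS power and size behave under shift alternatives", {
  set.seed(19)
  rej0 <- 0L; rej10 <- 0L; nrep <- 60
  for (k in seq_len(nrep)) {
    a <- 100 * rbeta(200, 1.2, 3)
    b <- 100 * rbeta(200, 1.2, 3)
    c2 <- pmin(100, 100 * rbeta(200, 1.2, 3) + 10)
    if (pValue(ksTwoSample(a, b)) < 0.05) rej0 <- rej0 + 1L
    if (pValue(ksTwoSample(a, c2)) < 0.05) rej10 <- rej10 + 1L
  }
  expect_lt(rej0 / nrep, 0.12)     # near-nominal type I
  expect_gt(rej10 / nrep, 0.9)     # strong power at a 10-point shift
})
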