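#' Two-sample two-sided Kolmogorov-Smirnov test
#'
#' D is the supremum of the absolute difference between the two empirical
#' cumulative distribution functions. The p-value is exact (network
#' algorithm) when `n * m <= exactLimit` and asymptotic (Kolmogorov
#' distribution) otherwise, matching common practice for the sample sizes
#' involved in radial-position comparisons.
#'
#' @param x,y Numeric samples (non-empty).
#' @param exactLimit Use the exact p-value when `length(x) * length(y)`
#'   is at most this (default 10000).
#' @return A [TestResult-class] with statistic D and Cohen's d as effect
#'   size.
#' @examples
#' ksTwoSample(c(1, 2, 3), c(4, 5, 6))  # D = 1, exact p = 0.1
#' @export
ksTwoSample <- function(x, y, exactLimit = 10000) {
  if (length(x) < 1 || length(y) < 1) stop("samples must be non-empty")
  exact <- length(x) * length(y) <= exactLimit
  kt <- suppressWarnings(stats::ks.test(x, y, exact = exact))
  d <- if (length(x) >= 2 && length(y) >= 2 &&
           stats::sd(c(x, y)) > 0) tryCatch(cohensD(x, y),
                                            error = function(e) NA_real_)
       else NA_real_
  TestResult("two-sample KS", c(D = unname(kt$statistic)),
             p.value = min(1, kt$p.value), effectSize = d,
             n = c(length(x), length(y)))
}

#' Hochberg step-up adjustment of p-values
#'
#' For ascending-sorted p-values p(1) <= ... <= p(m), the adjusted value is
#' `adj(k) = min over j >= k of (m - j + 1) p(j)`, capped at 1, returned in
#' the input order (the `p.adjust` "hochberg" method).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @examples
#' hochbergAdjust(c(0.01, 0.04, 0.03))  # 0.03 0.04 0.04
#' @export
hochbergAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "hochberg")
}

#' Adjust a list of TestResults together (Hochberg)
#'
#' @param results List of [TestResult-class] objects.
#' @return The list with `p.adjusted` slots filled.
#' @export
adjustResults <- function(results) {
  p <- vapply(results, function(r) r@p.value, 0)
  adj <- hochbergAdjust(p)
  for (i in seq_along(results)) results[[i]]@p.adjusted <- adj[i]
  results
}

#' Two-sided p-value from a t statistic
#'
#' `p = 2 * S_t(|t|; df)` with `S_t` the t-distribution survival function.
#'
#' @param t Observed t statistic.
#' @param df Degrees of freedom.
#' @return Two-sided p-value.
#' @examples
#' pFromT(8.31, 7)  # 7.1e-05
#' @export
pFromT <- function(t, df) {
  stopifnot(df > 0)
  2 * stats::pt(-abs(t), df)
}

#' Two-sample t-test (pooled or Welch)
#'
#' @param x,y Numeric samples with at least 2 observations each.
#' @param welch Use the Welch-Satterthwaite correction (default FALSE:
#'   pooled variance with `df = n1 + n2 - 2`).
#' @return A [TestResult-class] with t, df, p and Cohen's d.
#' @export
tTest <- function(x, y, welch = FALSE) {
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 observations")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y))
      return(TestResult(if (welch) "Welch t" else "t",
                        c(t = 0), df = length(x) + length(y) - 2,
                        p.value = 1, n = c(length(x), length(y))))
    stop("zero variance in both groups with unequal means")
  }
  tt <- stats::t.test(x, y, var.equal = !welch)
  TestResult(if (welch) "Welch t" else "t",
             c(t = unname(tt$statistic)), df = unname(tt$parameter),
             p.value = tt$p.value,
             effectSize = tryCatch(cohensD(x, y), error = function(e)
               NA_real_),
             n = c(length(x), length(y)))
}

#' Kruskal-Wallis rank test across groups
#'
#' H is tie-corrected; `df = k - 1` for k groups (reported as H(df) in
#' figure legends).
#'
#' @param groups List of numeric vectors (>= 2 groups, each non-empty).
#' @return A [TestResult-class].
#' @export
kruskalWallis <- function(groups) {
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 1))
  if (length(unique(unlist(groups))) == 1L)
    return(TestResult("Kruskal-Wallis", c(H = 0),
                      df = length(groups) - 1, p.value = 1,
                      n = lengths(groups)))
  kt <- stats::kruskal.test(groups)
  TestResult("Kruskal-Wallis", c(H = unname(kt$statistic)),
             df = unname(kt$parameter), p.value = kt$p.value,
             n = lengths(groups))
}

#' Dunn's post-hoc pairwise z-tests on mean ranks
#'
#' Follows a Kruskal-Wallis test: for each pair of groups,
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))`
#' with `T = sum(t^3 - t)` over tied-value groups. Pairwise p-values are
#' two-sided and, by default, Hochberg-adjusted.
#'
#' @param groups Named (or unnamed) list of numeric vectors.
#' @param adjust Adjustment for the pairwise p-values: "hochberg" (default)
#'   or "none".
#' @return List of [TestResult-class], one per pair, named "i vs j".
#' @export
dunnPosthoc <- function(groups, adjust = c("hochberg", "none")) {
  adjust <- match.arg(adjust)
  k <- length(groups)
  stopifnot(k >= 2)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  all <- unlist(groups, use.names = FALSE)
  N <- length(all)
  rk <- rank(all)
  gidx <- rep(seq_len(k), lengths(groups))
  rbar <- tapply(rk, gidx, mean)
  ties <- table(all)
  Tsum <- sum(ties^3 - ties)
  varTerm <- N * (N + 1) / 12 - Tsum / (12 * (N - 1))
  res <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(varTerm * (1 / lengths(groups)[i] + 1 / lengths(groups)[j]))
    z <- (rbar[[i]] - rbar[[j]]) / se
    res[[paste(names(groups)[i], "vs", names(groups)[j])]] <-
      TestResult("Dunn z", c(z = z), p.value = 2 * stats::pnorm(-abs(z)),
                 n = lengths(groups)[c(i, j)])
  }
  if (adjust == "hochberg") res <- adjustResults(res)
  res
}

#' Cohen's d effect size
#'
#' `(mean(x) - mean(y)) / s_pooled` with the pooled standard deviation on
#' `n1 + n2 - 2` degrees of freedom.
#'
#' @param x,y Numeric samples with at least 2 observations each.
#' @return Cohen's d.
#' @export
cohensD <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 2, n2 >= 2)
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
             (n1 + n2 - 2))
  if (sp == 0) stop("zero pooled standard deviation")
  (mean(x) - mean(y)) / sp
}

#' Summary of a radial-position distribution for plotting
#'
#' Median plus a Gaussian-kernel density estimate on the `[0, 100]` support
#' (Silverman bandwidth, boundary reflection at both ends). The density is
#' for display; no inference is based on it.
#'
#' @param values Numeric sample (n >= 1).
#' @param support Density support, default `c(0, 100)`.
#' @param nGrid Grid size for the density.
#' @return List: `median`, `n`, `x`, `density`, `degenerate` (TRUE for a
#'   constant sample, where the KDE is undefined).
#' @export
summarizeDistribution <- function(values, support = c(0, 100),
                                  nGrid = 512L) {
  stopifnot(length(values) >= 1)
  med <- stats::median(values)
  if (length(values) < 2 || stats::sd(values) == 0)
    return(list(median = med, n = length(values),
                x = seq(support[1], support[2], length.out = nGrid),
                density = rep(NA_real_, nGrid), degenerate = TRUE))
  bw <- stats::bw.nrd0(values)
  xg <- seq(support[1], support[2], length.out = nGrid)
  dens <- function(at) {
    vapply(at, function(x0) mean(stats::dnorm(x0, values, bw)), 0)
  }
  # reflect mass that leaks past the support boundaries back inside
  f <- dens(xg) + dens(2 * support[1] - xg) + dens(2 * support[2] - xg)
  list(median = med, n = length(values), x = xg, density = f,
       degenerate = FALSE)
}
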