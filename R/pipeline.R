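#' Simulate one imaging experiment and measure radial spot positions
#'
#' End-to-end chain on synthetic data: nucleus fields are generated, the
#' reporter channel planted, nuclei segmented from the DNA-stain channel and
#' spots detected and localized. Returns the measured per-spot table
#' together with the ground truth, so detection and positional accuracy can
#' be scored.
#'
#' @param nFields Number of independent fields to simulate.
#' @param nucleiPerField Nuclei per field.
#' @param spotsPerNucleus Planted spots per nucleus (NULL: 1-3 at random).
#' @param rSampler Sampler of true normalized positions on `[0, 100]`.
#' @param fpRate,fnRate Planted spurious-spot / omission rates.
#' @param noiseTolerance Spot-detection prominence threshold.
#' @param fieldShape,spacing,noiseSd,amplitude,spotNoiseSd Field geometry
#'   and noise settings passed to the generators.
#' @param segCfg A [segConfig()].
#' @param matchRadiusUm Truth-matching radius for scoring.
#' @param seed Master seed; all per-field seeds derive from it.
#' @return List: `spots` (measured calls with per-field ids), `truth`
#'   (planted spots), `eval` (pooled [evaluateDetection()] result),
#'   `errors` (per matched spot `|r_norm - r_true|`, percentage points),
#'   `nuclei` (per-field truth tables).
#' @export
simulateRadialExperiment <- function(nFields = 2L, nucleiPerField = 5L,
                                     spotsPerNucleus = NULL,
                                     rSampler = function(n)
                                       100 * stats::rbeta(n, 1.2, 3),
                                     fpRate = 0, fnRate = 0,
                                     noiseTolerance = 2000,
                                     fieldShape = c(16L, 256L, 256L),
                                     spacing = c(0.5, 0.1, 0.1),
                                     noiseSd = 60, amplitude = 8000,
                                     spotNoiseSd = 40,
                                     segCfg = segConfig(),
                                     matchRadiusUm = 0.5, seed = NULL) {
  seeds <- childSeeds(seed, 2L * nFields)
  allCalls <- list(); allTruth <- list(); allNuc <- list()
  errors <- numeric(0)
  nT <- 0L; nC <- 0L; nM <- 0L
  for (f in seq_len(nFields)) {
    fld <- makeNucleusField(nucleiPerField, fieldShape = fieldShape,
                            spacing = spacing, noiseSd = noiseSd,
                            seed = seeds[2 * f - 1])
    ps <- plantSpots(fld, rSampler = rSampler,
                     spotsPerNucleus = spotsPerNucleus, fpRate = fpRate,
                     fnRate = fnRate, amplitude = amplitude,
                     noiseSd = spotNoiseSd, seed = seeds[2 * f])
    seg <- segmentNuclei(ps$stack, config = segCfg)
    calls <- spotTable(ps$stack, seg, noiseTolerance = noiseTolerance)
    ev <- evaluateDetection(calls, ps$spots, matchRadiusUm)
    nT <- nT + ev$nTruth; nC <- nC + ev$nCalls; nM <- nM + ev$nMatched
    # per-spot normalized-position errors for matched pairs
    tr <- ps$spots[!ps$spots$isSpurious, ]
    if (nrow(calls) > 0 && nrow(tr) > 0) {
      D <- sqrt(outer(calls$xUm, tr$xUm, "-")^2 +
                outer(calls$yUm, tr$yUm, "-")^2 +
                outer(calls$zUm, tr$zUm, "-")^2)
      repeat {
        mn <- which.min(D)
        if (!length(mn) || D[mn] > matchRadiusUm) break
        i <- ((mn - 1) %% nrow(calls)) + 1
        j <- ((mn - 1) %/% nrow(calls)) + 1
        errors <- c(errors, abs(calls$rNormPct[i] - tr$rTruePct[j]))
        D[i, ] <- Inf; D[, j] <- Inf
      }
    }
    calls$field <- rep(f, nrow(calls))
    tr2 <- ps$spots
    tr2$field <- rep(f, nrow(tr2))
    allCalls[[f]] <- calls; allTruth[[f]] <- tr2
    allNuc[[f]] <- fld$nuclei
  }
  spots <- do.call(rbind, allCalls)
  truth <- do.call(rbind, allTruth)
  list(spots = spots, truth = truth,
       eval = list(nTruth = nT, nCalls = nC, nMatched = nM,
                   fpRate = if (nC == 0) 0 else (nC - nM) / nC,
                   fnRate = if (nT == 0) 0 else (nT - nM) / nT,
                   matchRadiusUm = matchRadiusUm),
       errors = errors, nuclei = allNuc)
}

#' Compare radial-position distributions across experimental groups
#'
#' Runs all pairwise two-sample KS comparisons between groups of normalized
#' radial positions, applies the Hochberg correction across the pairs and
#' returns per-group distribution summaries (median, KDE). Groups may be
#' given directly as numeric vectors of r values or as simulation
#' configurations (lists of [simulateRadialExperiment()] arguments).
#'
#' @param groups Named list: numeric vectors of `r_norm` values, or lists
#'   of simulation arguments.
#' @param seed Master seed for simulated groups.
#' @return List: `summaries` (per group), `tests` (pairwise
#'   [TestResult-class] list, Hochberg-adjusted; empty for a single group),
#'   `r` (the per-group value vectors).
#' @export
runPositionExperiment <- function(groups, seed = NULL) {
  stopifnot(length(groups) >= 1, !is.null(names(groups)))
  seeds <- childSeeds(seed, length(groups))
  rvals <- list()
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    rvals[[names(groups)[i]]] <- if (is.numeric(g)) g else
      do.call(simulateRadialExperiment,
              c(g, list(seed = seeds[i])))$spots$rNormPct
  }
  summaries <- lapply(rvals, summarizeDistribution)
  tests <- list()
  if (length(rvals) >= 2) {
    nm <- names(rvals)
    for (i in seq_len(length(rvals) - 1)) for (j in (i + 1):length(rvals))
      tests[[paste(nm[i], "vs", nm[j])]] <-
        ksTwoSample(rvals[[i]], rvals[[j]])
    tests <- adjustResults(tests)
  }
  list(summaries = summaries, tests = tests, r = rvals)
}

#' Detection-recovery benchmark against synthetic ground truth
#'
#' Convenience wrapper around [simulateRadialExperiment()] reporting the
#' pooled false-positive/false-negative rates and the distribution of
#' normalized-position errors.
#'
#' @param ... Arguments passed to [simulateRadialExperiment()].
#' @param seed Master seed.
#' @return List: `eval`, `medianAbsErrorPct`, `maxAbsErrorPct`, `errors`.
#' @export
runRecoveryBenchmark <- function(..., seed = NULL) {
  sim <- simulateRadialExperiment(..., seed = seed)
  list(eval = sim$eval,
       medianAbsErrorPct = stats::median(sim$errors),
       maxAbsErrorPct = if (length(sim$errors)) max(sim$errors) else
         NA_real_,
       errors = sim$errors)
}

#' Observed vs shuffle-null category overlap for a peak set
#'
#' Classifies peaks against category sets (in precedence order) and
#' contrasts the observed per-category percentages with the distribution
#' obtained from repeatedly shuffling the peaks (same chromosome, same
#' lengths; optionally restricted to include regions).
#'
#' @param peaks GRanges of observed peaks.
#' @param categorySets Named list of GRanges in precedence order.
#' @param chromSizes Named chromosome lengths.
#' @param nShuffles Number of shuffle replicates (default 200).
#' @param includeRegions Optional GRanges restricting shuffle placements.
#' @param seed Master seed.
#' @return List: `observed` (named percents), `null` (replicates x
#'   categories matrix), `nullMean`, `nullSE` (Monte-Carlo standard error
#'   of the mean), `nShuffles`.
#' @export
runPeakAnalysis <- function(peaks, categorySets, chromSizes,
                            nShuffles = 200L, includeRegions = NULL,
                            seed = NULL) {
  if (length(peaks) == 0) {
    warning("empty peak input: nothing to analyze")
    return(list(observed = NULL, null = NULL, nullMean = NULL,
                nullSE = NULL, nShuffles = 0L))
  }
  obs <- classifyByCcre(peaks, categorySets)$percent
  seeds <- childSeeds(seed, nShuffles)
  null <- matrix(NA_real_, nShuffles, length(obs),
                 dimnames = list(NULL, names(obs)))
  for (k in seq_len(nShuffles)) {
    sh <- shuffleIntervals(peaks, chromSizes, includeRegions,
                           seed = seeds[k])
    null[k, ] <- classifyByCcre(sh, categorySets)$percent
  }
  list(observed = obs, null = null, nullMean = colMeans(null),
       nullSE = apply(null, 2, stats::sd) / sqrt(nShuffles),
       nShuffles = nShuffles)
}

#' Density plot of normalized radial positions with median annotation
#'
#' Base-graphics rendering of the per-group KDE from
#' [runPositionExperiment()], with the peripheral heterochromatin layer
#' shown as a shaded band near the border when a normalized thickness is
#' given.
#'
#' @param experiment Result of [runPositionExperiment()].
#' @param layerPct Optional normalized layer thickness (percent) to shade.
#' @param cols Colors, one per group.
#' @return Invisibly, NULL; draws on the active device.
#' @export
plotRadialDensity <- function(experiment, layerPct = NULL, cols = NULL) {
  s <- experiment$summaries
  if (is.null(cols)) cols <- seq_along(s) + 1
  ymax <- max(vapply(s, function(x)
    if (x$degenerate) 0 else max(x$density), 0), 0.001)
  graphics::plot(NA, xlim = c(0, 100), ylim = c(0, ymax * 1.1),
                 xlab = "normalized radial position (% of Z/2)",
                 ylab = "density", main = "radial position distributions")
  if (!is.null(layerPct))
    graphics::rect(0, 0, layerPct, ymax * 1.1,
                   col = grDevices::adjustcolor("gray", 0.4), border = NA)
  for (i in seq_along(s)) {
    if (!s[[i]]$degenerate)
      graphics::lines(s[[i]]$x, s[[i]]$density, col = cols[i], lwd = 2)
    graphics::abline(v = s[[i]]$median, col = cols[i], lty = 2)
  }
  graphics::legend("topright",
                   legend = sprintf("%s (median %.1f)", names(s),
                                    vapply(s, `[[`, 0, "median")),
                   col = cols, lwd = 2, bty = "n")
  invisible(NULL)
}
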