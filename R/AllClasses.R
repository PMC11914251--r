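#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importFrom Rcpp evalCpp
#' @useDynLib periloc, .registration = TRUE
NULL

#' Multi-channel 3D image stack
#'
#' Container for a multi-channel fluorescence z-stack. Every channel is a
#' numeric 3D array ordered \code{(z, y, x)}; all channels share one shape and
#' one anisotropic physical voxel spacing \code{(dz, dy, dx)} in micrometers.
#'
#' @slot channels A [S4Vectors::SimpleList] of named numeric 3D arrays.
#' @slot spacing Numeric length-3 vector \code{(dz, dy, dx)} in um with
#'   \code{dz >= dy == dx > 0}.
#' @slot bitDepth Integer; intensities lie in \code{[0, 2^bitDepth - 1]}.
#'
#' @seealso [makeNucleusField()], [segmentNuclei()]
#' @export
setClass("ImageStack",
  representation(channels = "SimpleList", spacing = "numeric",
                 bitDepth = "integer"))

setValidity("ImageStack", function(object) {
  ch <- object@channels
  if (length(ch) == 0L) return("at least one channel required")
  if (is.null(names(ch)) || anyDuplicated(names(ch)))
    return("channels must have unique names")
  dims <- lapply(ch, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    return("channels must be 3D arrays ordered (z, y, x)")
  if (length(unique(lapply(dims, as.integer))) != 1L)
    return("all channels must share an identical shape")
  sp <- object@spacing
  if (length(sp) != 3L || any(!is.finite(sp)) || any(sp <= 0))
    return("spacing must be three positive values (dz, dy, dx)")
  if (sp[2] != sp[3] || sp[1] < sp[2] - 1e-12)
    return("spacing must satisfy dz >= dy == dx > 0")
  if (length(object@bitDepth) != 1L || object@bitDepth < 1L)
    return("bitDepth must be a positive integer")
  hi <- 2^object@bitDepth - 1
  rng <- range(vapply(ch, function(a) range(a), numeric(2)))
  if (rng[1] < 0 || rng[2] > hi)
    return(sprintf("intensities must lie in [0, %g]", hi))
  TRUE
})

#' Construct an ImageStack
#'
#' @param channels Named list of numeric 3D arrays ordered \code{(z, y, x)}.
#' @param spacing Voxel spacing \code{(dz, dy, dx)} in um.
#' @param bitDepth Bit depth of the (simulated) detector; default 16.
#' @return An [ImageStack-class] object.
#' @examples
#' st <- ImageStack(list(hoechst = array(0, c(4, 8, 8))))
#' dim(st)
#' @export
ImageStack <- function(channels, spacing = c(0.5, 0.1, 0.1), bitDepth = 16L) {
  new("ImageStack", channels = S4Vectors::SimpleList(channels),
      spacing = as.numeric(spacing), bitDepth = as.integer(bitDepth))
}

#' Result of 3D nucleus segmentation
#'
#' @slot labels Integer 3D array; 0 is background, k > 0 the k-th nucleus.
#' @slot nuclei A [S4Vectors::DataFrame] with one row per nucleus (id,
#'   voxel count, bounding box, centroid in um, z-plane extent, height
#'   \code{Z = (zMax - zMin + 1) * dz}, border flag).
#' @slot spacing Voxel spacing \code{(dz, dy, dx)} in um.
#' @slot threshold The global intensity threshold that produced the mask.
#' @export
setClass("SegmentationResult",
  representation(labels = "array", nuclei = "DataFrame",
                 spacing = "numeric", threshold = "numeric"))

setValidity("SegmentationResult", function(object) {
  nuc <- object@nuclei
  labs <- sort(unique(as.integer(object@labels)))
  labs <- labs[labs != 0L]
  if (nrow(nuc) != length(labs)) return("records and labels not in bijection")
  if (nrow(nuc) > 0 && !identical(sort(nuc$id), labs))
    return("nucleus ids must match label values")
  if (nrow(nuc) > 0 && any(nuc$zMin > nuc$zMax))
    return("zMin must not exceed zMax")
  TRUE
})

#' A single hypothesis-test result
#'
#' Light-weight S4 value object holding one statistical comparison:
#' the test name, its statistic (KS D, Kruskal-Wallis H, t or Dunn z),
#' degrees of freedom where defined, raw and (optionally) Hochberg-adjusted
#' p-values, Cohen's d where defined and the group sizes.
#'
#' @slot test Character test name.
#' @slot statistic Named numeric statistic.
#' @slot df Numeric degrees of freedom (NA when not applicable).
#' @slot p.value Raw p-value.
#' @slot p.adjusted Adjusted p-value (NA until adjusted).
#' @slot effectSize Cohen's d (NA when not applicable).
#' @slot n Integer vector of group sizes.
#' @export
setClass("TestResult",
  representation(test = "character", statistic = "numeric", df = "numeric",
                 p.value = "numeric", p.adjusted = "numeric",
                 effectSize = "numeric", n = "integer"))

setValidity("TestResult", function(object) {
  p <- object@p.value
  if (!is.na(p) && (p < 0 || p > 1)) return("p.value outside [0, 1]")
  pa <- object@p.adjusted
  if (!is.na(pa) && (pa < p - 1e-12 || pa > 1))
    return("adjusted p must lie in [p, 1]")
  TRUE
})

TestResult <- function(test, statistic, df = NA_real_, p.value,
                       p.adjusted = NA_real_, effectSize = NA_real_,
                       n = integer()) {
  new("TestResult", test = test, statistic = statistic, df = as.numeric(df),
      p.value = as.numeric(p.value), p.adjusted = as.numeric(p.adjusted),
      effectSize = as.numeric(effectSize), n = as.integer(n))
}
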