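#' @describeIn ImageStack Channel names.
#' @param x,object An `ImageStack`.
#' @export
setMethod("names", "ImageStack", function(x) names(x@channels))

#' @describeIn ImageStack Extract one channel as a 3D array.
#' @param i Channel name or index.
#' @export
setMethod("[[", "ImageStack", function(x, i) {
  if (is.character(i) && !i %in% names(x@channels))
    stop("channel '", i, "' not present (have: ",
         paste(names(x@channels), collapse = ", "), ")")
  x@channels[[i]]
})

#' @describeIn ImageStack Shape of the stack, \code{(nz, ny, nx)}.
#' @export
setMethod("dim", "ImageStack", function(x) dim(x@channels[[1]]))

setGeneric("spacing", function(object) standardGeneric("spacing"))
#' @describeIn ImageStack Voxel spacing \code{(dz, dy, dx)} in um.
#' @export
setMethod("spacing", "ImageStack", function(object) {
  sp <- object@spacing
  names(sp) <- c("dz", "dy", "dx")
  sp
})

setGeneric("bitDepth", function(object) standardGeneric("bitDepth"))
#' @describeIn ImageStack Detector bit depth.
#' @export
setMethod("bitDepth", "ImageStack", function(object) object@bitDepth)

setGeneric("setChannel", function(object, name, value)
  standardGeneric("setChannel"))
#' @describeIn ImageStack Add or replace a channel (returns a new stack).
#' @param name Channel name.
#' @param value Numeric 3D array with the stack's shape.
#' @export
setMethod("setChannel", "ImageStack", function(object, name, value) {
  ch <- as.list(object@channels)
  ch[[name]] <- value
  out <- ImageStack(ch, spacing = object@spacing, bitDepth = object@bitDepth)
  out
})

#' @export
setMethod("show", "ImageStack", function(object) {
  d <- dim(object)
  cat(sprintf("ImageStack: %d channel(s) [%s], %d x %d x %d (z,y,x)\n",
              length(object@channels),
              paste(names(object@channels), collapse = ", "),
              d[1], d[2], d[3]))
  cat(sprintf("  spacing (dz,dy,dx): %.3g x %.3g x %.3g um, %d-bit\n",
              object@spacing[1], object@spacing[2], object@spacing[3],
              object@bitDepth))
})

setGeneric("nuclei", function(object) standardGeneric("nuclei"))
#' @describeIn SegmentationResult Per-nucleus table (a `DataFrame`).
#' @param object A `SegmentationResult`.
#' @export
setMethod("nuclei", "SegmentationResult", function(object) object@nuclei)

setGeneric("labelVolume", function(object) standardGeneric("labelVolume"))
#' @describeIn SegmentationResult Integer label array (0 = background).
#' @export
setMethod("labelVolume", "SegmentationResult",
          function(object) object@labels)

#' @export
setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf(
    "SegmentationResult: %d nucleus(ei), threshold %.4g\n",
    nrow(object@nuclei), object@threshold))
  if (nrow(object@nuclei) > 0) {
    cat(sprintf("  heights (um): %s\n",
                paste(sprintf("%.2g", object@nuclei$heightUm),
                      collapse = ", ")))
  }
})

#' @export
setMethod("show", "TestResult", function(object) {
  st <- sprintf("%s = %.4g", names(object@statistic)[1], object@statistic[1])
  if (!is.na(object@df)) st <- sprintf("%s (df = %.3g)", st, object@df)
  cat(sprintf("TestResult [%s]: %s, p = %.3g", object@test, st,
              object@p.value))
  if (!is.na(object@p.adjusted))
    cat(sprintf(", adj. p = %.3g", object@p.adjusted))
  if (!is.na(object@effectSize))
    cat(sprintf(", Cohen's d = %.3g", object@effectSize))
  if (length(object@n)) cat(sprintf(" (n = %s)", paste(object@n,
                                                       collapse = "/")))
  cat("\n")
})

setGeneric("pValue", function(object) standardGeneric("pValue"))
#' @describeIn TestResult Raw p-value.
#' @param object A `TestResult`.
#' @export
setMethod("pValue", "TestResult", function(object) object@p.value)

setGeneric("pAdjusted", function(object) standardGeneric("pAdjusted"))
#' @describeIn TestResult Hochberg-adjusted p-value (NA until adjusted).
#' @export
setMethod("pAdjusted", "TestResult", function(object) object@p.adjusted)

setGeneric("statValue", function(object) standardGeneric("statValue"))
#' @describeIn TestResult The test statistic.
#' @export
setMethod("statValue", "TestResult", function(object) object@statistic)
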