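#' Read a multi-page TIFF z-stack into a channel
#'
#' Reads one multi-page TIFF per channel; pages become z-planes. Intensities
#' are rescaled from the TIFF's unit-interval convention back to the
#' bit-depth range.
#'
#' @param paths Named character vector: channel name -> TIFF path.
#' @param spacing Voxel spacing `(dz, dy, dx)` in um.
#' @param bitDepth Detector bit depth of the stored data.
#' @return An [ImageStack-class].
#' @export
readImageStack <- function(paths, spacing = c(0.5, 0.1, 0.1),
                           bitDepth = 16L) {
  channels <- lapply(paths, function(p) {
    pages <- tiff::readTIFF(p, all = TRUE)
    arr <- array(0, c(length(pages), dim(pages[[1]])[1:2]))
    for (z in seq_along(pages)) {
      pg <- pages[[z]]
      if (length(dim(pg)) == 3) pg <- pg[, , 1]
      arr[z, , ] <- pg
    }
    arr * (2^bitDepth - 1)
  })
  ImageStack(channels, spacing = spacing, bitDepth = bitDepth)
}

#' Write each channel of a stack as a multi-page TIFF
#'
#' @param stack An [ImageStack-class].
#' @param dir Output directory (created if absent).
#' @param prefix Filename prefix; files are `<prefix><channel>.tif`.
#' @return Invisibly, the written paths.
#' @export
writeImageStack <- function(stack, dir, prefix = "") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hi <- 2^stack@bitDepth - 1
  paths <- vapply(names(stack@channels), function(ch) {
    arr <- stack[[ch]] / hi
    pages <- lapply(seq_len(dim(arr)[1]), function(z) arr[z, , ])
    p <- file.path(dir, paste0(prefix, ch, ".tif"))
    tiff::writeTIFF(pages, p, bits.per.sample = 16L)
    p
  }, "")
  invisible(paths)
}

#' Read a chrom.sizes file
#'
#' @param path Two-column whitespace-separated file: chrom, length.
#' @return Named integer vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "",
                          col.names = c("chrom", "size"),
                          stringsAsFactors = FALSE)
  stats::setNames(as.integer(df$size), df$chrom)
}

#' Read a BED file as GRanges
#'
#' 0-based half-open BED records become 1-based closed GRanges.
#'
#' @param path BED file path.
#' @param chromSizes Optional named chromosome lengths to attach as
#'   seqlengths.
#' @return GRanges.
#' @export
readBed <- function(path, chromSizes = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(chromSizes))
    GenomeInfoDb::seqlengths(gr) <-
      unlist(chromSizes)[GenomeInfoDb::seqlevels(gr)]
  gr
}

#' Write GRanges as a BED file (0-based half-open)
#'
#' @param gr GRanges.
#' @param path Output path.
#' @export
writeBed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a bedGraph signal track as GRanges with a score column
#'
#' @inheritParams readBed
#' @return GRanges with `score`.
#' @export
readBedGraph <- function(path, chromSizes = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (!is.null(chromSizes))
    GenomeInfoDb::seqlengths(gr) <-
      unlist(chromSizes)[GenomeInfoDb::seqlevels(gr)]
  gr
}

#' Write a signal track as bedGraph
#'
#' @param gr GRanges with `score`.
#' @param path Output path.
#' @export
writeBedGraph <- function(gr, path) {
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Write a per-spot table as TSV
#'
#' Columns: nucleus_id, x_um, y_um, z_um, d_abs_um, r_norm_pct.
#'
#' @param spots Spot table from [spotTable()].
#' @param path Output path.
#' @export
writeSpotTable <- function(spots, path) {
  df <- data.frame(nucleus_id = spots$nucleusId, x_um = spots$xUm,
                   y_um = spots$yUm, z_um = spots$zUm,
                   d_abs_um = spots$dAbsUm, r_norm_pct = spots$rNormPct)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
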