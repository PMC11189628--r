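# Reading and writing image stacks and truth tables.
#
# Stacks are stored as multi-page TIFF, one page per z per channel
# (channel-major), with the channel order, shape and pixel spacing in a
# JSON sidecar next to the TIFF. Intensities are written as 32-bit float
# pages. Ground-truth label images go to a separate label TIFF plus a CSV
# truth table.

#' Write an ImageStack to a multi-page TIFF with a JSON sidecar
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param path output TIFF path; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
writeImageStack <- function(stack, path) {
  stopifnot(is(stack, "ImageStack"))
  d <- dim(stack@channels[[1L]])
  pages <- list()
  for (nm in channelNames(stack)) {
    a <- stack@channels[[nm]]
    for (z in seq_len(d[1])) pages[[length(pages) + 1L]] <- a[z, , ]
  }
  scale <- max(1, vapply(pages, max, numeric(1)))
  tiff::writeTIFF(lapply(pages, function(p) p / scale), path,
                  bits.per.sample = 32L)
  meta <- list(channels = channelNames(stack), shape = d,
               pixel_size_um = stack@pixelSize, z_step_um = stack@zStep,
               intensity_scale = scale, page_order = "channel_major")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an ImageStack written by \code{\link{writeImageStack}}
#'
#' @param path TIFF path with its JSON sidecar alongside.
#' @return an \linkS4class{ImageStack}.
#' @export
readImageStack <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop(sprintf("channel-map sidecar '%s' not found", sidecar))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(meta$shape)
  channels <- list()
  k <- 0L
  for (nm in meta$channels) {
    a <- array(0, dim = d)
    for (z in seq_len(d[1])) {
      k <- k + 1L
      a[z, , ] <- pages[[k]] * meta$intensity_scale
    }
    channels[[nm]] <- a
  }
  ImageStack(channels, pixelSize = meta$pixel_size_um,
             zStep = meta$z_step_um)
}

#' Write generator ground truth to plain files
#'
#' The cell (and, when present, mitochondrial and nuclear) label images
#' go to single-page label TIFFs; per-cell truth values go to a CSV.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param prefix file prefix; files `<prefix>_cells.tif` etc. are
#'   created.
#' @return character vector of the files written, invisibly.
#' @export
writeGroundTruth <- function(truth, prefix) {
  written <- character()
  writeLabels <- function(m, suffix) {
    p <- paste0(prefix, "_", suffix, ".tif")
    tiff::writeTIFF(m / max(1, max(m)), p, bits.per.sample = 32L)
    p
  }
  if (length(truth@cellMasks))
    written <- c(written, writeLabels(truth@cellMasks, "cells"))
  if (length(truth@mitoMasks))
    written <- c(written, writeLabels(truth@mitoMasks, "mito"))
  if (length(truth@nuclearMasks))
    written <- c(written, writeLabels(truth@nuclearMasks, "nuclei"))
  n <- max(0L, truth@cellMasks)
  if (n > 0) {
    tab <- data.frame(cell_id = seq_len(n))
    if (length(truth@trueSpgfpMedian))
      tab$true_spgfp_median <- truth@trueSpgfpMedian
    if (length(truth@trueNcRatio)) tab$true_nc_ratio <- truth@trueNcRatio
    p <- paste0(prefix, "_truth.csv")
    write.csv(tab, p, row.names = FALSE)
    written <- c(written, p)
  }
  invisible(written)
}
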