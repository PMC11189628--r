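# Nucleocytoplasmic ratio of a reporter against a nuclear marker.
#
# The nucleus of each cell is segmented from the nuclear-marker channel by
# Otsu's between-class-variance criterion applied within the cell; the
# cytoplasm is a ring obtained by dilating the nuclear mask and removing
# the nucleus, clipped to the cell. The ratio is the mean reporter
# intensity over the nucleus divided by the mean over the ring.

#' Otsu threshold by exhaustive between-class-variance search
#'
#' Considers every unique value of `v` except the maximum as a candidate
#' threshold `t` (classes `v <= t` and `v > t`) and returns the candidate
#' maximising the between-class variance. Ties go to the smallest
#' threshold.
#'
#' @param v numeric vector with at least two distinct values.
#' @return the threshold, or `NA` if `v` is constant.
#' @export
otsuThreshold <- function(v) {
  u <- sort(unique(v))
  if (length(u) < 2L) return(NA_real_)
  n <- length(v)
  cnt <- tabulate(match(v, u), nbins = length(u))
  csum <- cumsum(cnt * u)
  cn <- cumsum(cnt)
  k <- seq_len(length(u) - 1L)
  w0 <- cn[k] / n
  w1 <- 1 - w0
  m0 <- csum[k] / cn[k]
  m1 <- (csum[length(u)] - csum[k]) / (n - cn[k])
  bcv <- w0 * w1 * (m0 - m1)^2
  u[which.max(bcv)]
}

#' Segment one nucleus per cell from a nuclear-marker projection
#'
#' Within each labelled cell the marker is thresholded by
#' \code{\link{otsuThreshold}} and the largest above-threshold connected
#' component is kept as the nucleus. Cells with an effectively flat
#' marker (no bimodality to threshold) are flagged and receive no
#' nucleus.
#'
#' @param rfpProjection 2D nuclear-marker sum projection.
#' @param cellLabels integer cell label matrix (from
#'   \code{\link{splitCells}}).
#' @param flatTol relative intensity range below which a cell's marker is
#'   considered flat.
#' @return integer matrix of nuclear masks labelled by owning cell, with
#'   attribute `"flagged"` listing cells where no nucleus was found.
#' @export
segmentNuclei <- function(rfpProjection, cellLabels, flatTol = 1e-8) {
  stopifnot(identical(dim(rfpProjection), dim(cellLabels)))
  out <- matrix(0L, nrow(cellLabels), ncol(cellLabels))
  flagged <- integer()
  for (i in seq_len(max(cellLabels, 0L))) {
    cell <- cellLabels == i
    v <- rfpProjection[cell]
    rng <- range(v)
    if (diff(rng) <= flatTol * max(abs(rng), 1)) {
      flagged <- c(flagged, i)
      next
    }
    thr <- otsuThreshold(v)
    nucm <- cell & (rfpProjection > thr)
    if (!any(nucm)) { flagged <- c(flagged, i); next }
    comp <- .asMat(EBImage::bwlabel(nucm * 1))
    sizes <- tabulate(comp[comp > 0])
    big <- which.max(sizes)
    out[comp == big] <- i
  }
  attr(out, "flagged") <- flagged
  out
}

#' Nucleocytoplasmic ratio of one cell
#'
#' The cytoplasmic ring is `dilate(nucleus, disc(radius))` minus the
#' nucleus, clipped to the cell mask. The ratio is the mean reporter
#' intensity over the nucleus divided by the mean over the ring.
#'
#' @param gfpProjection 2D reporter sum projection.
#' @param cellMask logical mask of the cell.
#' @param nuclearMask logical mask of the nucleus (subset of the cell).
#' @param dilationRadius ring radius, pixels (default 3).
#' @param cellId id recorded in the output row.
#' @return one-row data.frame: cell_id, nuc_area, cyto_area, nuc_mean,
#'   cyto_mean, nc_ratio, qc_flags (flagged when the ring is empty).
#' @examples
#' g <- matrix(10, 9, 9); g[4:6, 4:6] <- 20
#' cell <- matrix(TRUE, 9, 9)
#' nuc <- matrix(FALSE, 9, 9); nuc[4:6, 4:6] <- TRUE
#' measureNCRatio(g, cell, nuc)$nc_ratio
#' @export
measureNCRatio <- function(gfpProjection, cellMask, nuclearMask,
                           dilationRadius = 3, cellId = 1L) {
  stopifnot(identical(dim(gfpProjection), dim(cellMask)),
            identical(dim(gfpProjection), dim(nuclearMask)))
  cellMask <- cellMask > 0
  nuclearMask <- nuclearMask > 0
  if (any(nuclearMask & !cellMask))
    stop("'nuclearMask' must lie inside 'cellMask'")
  if (!any(nuclearMask)) stop("'nuclearMask' is empty")
  ring <- .asMat(EBImage::dilate(nuclearMask * 1,
                                 .discBrush(dilationRadius))) > 0
  ring <- ring & !nuclearMask & cellMask
  flags <- character()
  nucMean <- mean(gfpProjection[nuclearMask])
  if (!any(ring)) {
    flags <- c(flags, "empty_ring")
    cytoMean <- NA_real_
  } else {
    cytoMean <- mean(gfpProjection[ring])
  }
  data.frame(cell_id = cellId, nuc_area = sum(nuclearMask),
             cyto_area = sum(ring), nuc_mean = nucMean, cyto_mean = cytoMean,
             nc_ratio = if (!is.na(cytoMean) && cytoMean > 0)
               nucMean / cytoMean else NA_real_,
             qc_flags = .joinFlags(flags), stringsAsFactors = FALSE)
}

#' Quantify nucleocytoplasmic ratios across a field
#'
#' Convenience pipeline for a stack with `gfp` and `rfp` channels: the
#' field is segmented on the gfp + rfp sum projection, nuclei are
#' segmented per cell from the rfp projection, and
#' \code{\link{measureNCRatio}} is applied per cell. The populational
#' mean over unflagged cells is the per-replicate summary statistic.
#'
#' @param stack an \linkS4class{ImageStack} with `gfp` and `rfp`.
#' @param dilationRadius ring radius, pixels.
#' @param ... passed to \code{\link{segmentForeground}} and
#'   \code{\link{splitCells}} (smoothRadius, bgQuantile, fgQuantile,
#'   rwBeta, minDistance, minArea, excludeBorder).
#' @return list with `cells` (per-cell records), `summary` (n_cells and
#'   mean_nc_ratio over unflagged cells) and `labels`.
#' @export
quantifyNCField <- function(stack, dilationRadius = 3, ...) {
  gfp <- sumProject(stack, "gfp")
  rfp <- sumProject(stack, "rfp")
  args <- list(...)
  segArgs <- args[names(args) %in%
                    c("smoothRadius", "bgQuantile", "fgQuantile", "rwBeta")]
  splitArgs <- args[names(args) %in%
                      c("minDistance", "minArea", "excludeBorder")]
  fg <- do.call(segmentForeground, c(list(gfp + rfp), segArgs))
  lab <- do.call(splitCells, c(list(fg), splitArgs))
  nuc <- segmentNuclei(rfp, lab)
  rows <- list()
  for (i in seq_len(max(lab, 0L))) {
    if (i %in% attr(nuc, "flagged")) next
    rows[[length(rows) + 1L]] <-
      measureNCRatio(gfp, lab == i, nuc == i,
                     dilationRadius = dilationRadius, cellId = i)
  }
  cells <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = integer(), nuc_area = integer(),
               cyto_area = integer(), nuc_mean = numeric(),
               cyto_mean = numeric(), nc_ratio = numeric(),
               qc_flags = character())
  ok <- cells$qc_flags == ""
  list(cells = cells,
       summary = data.frame(
         n_cells = sum(ok),
         mean_nc_ratio = if (any(ok)) mean(cells$nc_ratio[ok]) else NA_real_),
       labels = lab)
}
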