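# Per-cell mitochondrial split-GFP quantification.
#
# The pipeline mirrors common practice for yeast confocal stacks: channels
# are summed along z, the field is split into background and foreground by
# seeded random-walker diffusion, adjoining cells are separated by a
# seeded watershed on the distance transform, mitochondria are detected
# per cell at a fraction of the cell's maximal marker intensity, and the
# per-cell reporter statistic is the median reporter intensity over the
# mitochondrial mask. All 2D work uses (row, col) indexing with label 0
# reserved for background.

#' Sum projection along z
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param channel channel name.
#' @return 2D numeric matrix; `out[y, x] = sum_z in[z, y, x]`. Accumulation
#'   is in double precision, so 16-bit integer inputs cannot overflow.
#' @examples
#' a <- array(1, dim = c(3, 2, 2))
#' sumProject(ImageStack(list(gfp = a)), "gfp")
#' @export
sumProject <- function(stack, channel) {
  a <- getChannel(stack, channel)
  apply(a * 1.0, c(2, 3), sum)
}

# Build the 4-connected graph Laplacian of an image and solve the
# random-walker Dirichlet problem for the probability of absorbing at a
# foreground seed.
.randomWalkerProb <- function(img, fgSeed, bgSeed, beta) {
  ny <- nrow(img); nx <- ncol(img)
  n <- ny * nx
  rng <- range(img)
  g <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
  id <- matrix(seq_len(n), ny, nx)
  # vertical and horizontal edges
  i <- c(as.vector(id[-ny, ]), as.vector(id[, -nx]))
  j <- c(as.vector(id[-1, ]), as.vector(id[, -1]))
  dg <- c(as.vector(g[-ny, ] - g[-1, ]), as.vector(g[, -nx] - g[, -1]))
  # scale gradients by the image spread so beta acts on contrast relative
  # to the field, not on absolute intensity steps
  s <- sd(g)
  if (s > 0) dg <- dg / s
  w <- exp(-beta * dg^2) + 1e-10
  W <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(w, w),
                            dims = c(n, n))
  L <- Matrix::Diagonal(n, Matrix::rowSums(W)) - W
  seeded <- fgSeed | bgSeed
  prob <- as.numeric(fgSeed)
  u <- which(!seeded)
  if (length(u)) {
    s <- which(seeded)
    b <- -L[u, s, drop = FALSE] %*% prob[s]
    prob[u] <- as.numeric(Matrix::solve(L[u, u], b))
  }
  matrix(prob, ny, nx)
}

#' Random-walker foreground segmentation
#'
#' Splits a summed projection into background and foreground. The
#' projection is first denoised with an edge-preserving median filter;
#' background and foreground seeds are the pixels below the `bgQuantile` /
#' above the `fgQuantile` of the filtered image, and all remaining pixels
#' are assigned by random-walker diffusion labelling (edge weights
#' `exp(-beta * dI^2)` on normalised intensity steps). Seed pixels always
#' retain their seed label in the output.
#'
#' A median filter is used rather than Gaussian smoothing because it
#' suppresses shot noise without bleeding the bright organelle signal
#' into the cell-boundary neighbourhood, which would displace the
#' walker's boundary outward wherever a tubule runs close to the cell
#' edge.
#'
#' @param projection 2D numeric matrix, typically the gfp + mcherry sum
#'   projection.
#' @param smoothRadius median-filter window radius in pixels (default 2,
#'   i.e. a 5x5 window); 0 disables filtering.
#' @param bgQuantile,fgQuantile seed quantiles on the filtered image.
#' @param rwBeta random-walker edge-weight sharpness.
#' @param saturate clip the filtered image just above the background-seed
#'   level (at 20 percent of the span up to the foreground-seed level)
#'   before computing diffusion weights (default TRUE). Everything
#'   clearly above background is equally "cell": without the clip the
#'   bright organelle interior forms a stronger diffusion barrier than
#'   the cell boundary itself and the walker stops at the organelle rim.
#'   Seeds are taken from the unclipped image.
#' @return logical matrix (TRUE = foreground) with attribute
#'   `"degenerate"` set to TRUE for a constant image (all background, with
#'   a warning).
#' @export
segmentForeground <- function(projection, smoothRadius = 2, bgQuantile = 0.20,
                              fgQuantile = 0.95, rwBeta = 130,
                              saturate = TRUE) {
  stopifnot(is.matrix(projection))
  if (diff(range(projection)) == 0) {
    warning("constant projection: no cells detected")
    mask <- matrix(FALSE, nrow(projection), ncol(projection))
    attr(mask, "degenerate") <- TRUE
    return(mask)
  }
  sm <- if (smoothRadius > 0) .medianSmooth(projection, smoothRadius)
        else projection
  qs <- quantile(sm, c(bgQuantile, fgQuantile), names = FALSE)
  bgSeed <- sm <= qs[1]
  fgSeed <- sm >= qs[2]
  # quantile ties can make the seed sets overlap; background wins there
  fgSeed[bgSeed] <- FALSE
  wimg <- if (saturate) pmin(sm, qs[1] + 0.2 * (qs[2] - qs[1])) else sm
  prob <- .randomWalkerProb(wimg, as.vector(fgSeed), as.vector(bgSeed), rwBeta)
  mask <- prob > 0.5
  mask[fgSeed] <- TRUE
  mask[bgSeed] <- FALSE
  attr(mask, "degenerate") <- FALSE
  mask
}

# Edge-preserving median filter (EBImage works on [0, 1] data).
.medianSmooth <- function(m, radius) {
  mn <- min(m)
  mx <- max(m)
  if (mx <= mn) return(m)
  .asMat(EBImage::medianFilter((m - mn) / (mx - mn), radius)) *
    (mx - mn) + mn
}

# Local maxima of the distance transform, greedily thinned so that kept
# markers are >= minDistance apart (ties broken by height then raster
# order, so marker choice is deterministic).
.distanceMarkers <- function(dist, minDistance) {
  r <- max(1L, floor(minDistance))
  dmax <- .asMat(EBImage::dilate(dist, .discBrush(r)))
  peaks <- which(dist > 0 & dist >= dmax, arr.ind = TRUE)
  if (nrow(peaks) == 0L) return(peaks)
  h <- dist[peaks]
  ord <- order(-h, peaks[, 1], peaks[, 2])
  peaks <- peaks[ord, , drop = FALSE]
  keep <- logical(nrow(peaks))
  for (k in seq_len(nrow(peaks))) {
    if (!any(keep)) { keep[k] <- TRUE; next }
    d2 <- (peaks[keep, 1] - peaks[k, 1])^2 + (peaks[keep, 2] - peaks[k, 2])^2
    if (all(d2 >= minDistance^2)) keep[k] <- TRUE
  }
  peaks[keep, , drop = FALSE]
}

# Multi-source geodesic label propagation inside a mask: uniform-cost BFS
# over the 4-neighbourhood; equidistant ties go to the smaller label.
.geodesicAssign <- function(mask, markers) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  lab[markers] <- seq_len(nrow(markers))
  frontier <- lab > 0L
  repeat {
    cand <- matrix(Inf, ny, nx)
    src <- ifelse(frontier, lab, Inf)
    cand[-1, ] <- pmin(cand[-1, ], src[-ny, ])
    cand[-ny, ] <- pmin(cand[-ny, ], src[-1, ])
    cand[, -1] <- pmin(cand[, -1], src[, -nx])
    cand[, -nx] <- pmin(cand[, -nx], src[, -1])
    newpix <- mask & lab == 0L & is.finite(cand)
    if (!any(newpix)) break
    lab[newpix] <- as.integer(cand[newpix])
    frontier <- newpix
  }
  lab
}

# Drop listed labels and renumber the remainder contiguously (original
# label order preserved).
.relabel <- function(lab, drop) {
  keep <- setdiff(sort(unique(lab[lab > 0L])), drop)
  out <- matrix(0L, nrow(lab), ncol(lab))
  for (k in seq_along(keep)) out[lab == keep[k]] <- k
  out
}

#' Separate adjoining cells by seeded watershed on the distance transform
#'
#' Markers are local maxima of the Euclidean distance transform of the
#' foreground mask, thinned to a minimum separation; foreground pixels are
#' then assigned to the geodesically nearest marker within the mask
#' (4-connected; equidistant pixels go to the smaller label). Components
#' below `minArea` are removed, and labels touching the image border are
#' flagged and, by default, excluded.
#'
#' @param mask logical foreground matrix.
#' @param minDistance minimum marker separation, pixels (default 15, just under the smallest centre distance of touching cells at the default radii).
#' @param minArea smallest retained cell area, pixels.
#' @param excludeBorder drop border-touching labels (default TRUE).
#' @return integer label matrix (0 = background, labels contiguous from 1)
#'   with attributes `"markers"` (kept marker coordinates) and
#'   `"borderTouching"` (logical per retained label).
#' @export
splitCells <- function(mask, minDistance = 15, minArea = 100,
                       excludeBorder = TRUE) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  mask <- mask > 0
  if (!any(mask)) {
    out <- matrix(0L, nrow(mask), ncol(mask))
    attr(out, "markers") <- matrix(numeric(), 0, 2)
    attr(out, "borderTouching") <- logical()
    return(out)
  }
  dist <- .asMat(EBImage::distmap(mask * 1))
  markers <- .distanceMarkers(dist, minDistance)
  lab <- .geodesicAssign(mask, markers)

  sizes <- tabulate(lab[lab > 0L])
  small <- which(sizes > 0 & sizes < minArea)
  lab <- .relabel(lab, small)

  nlab <- max(lab, 0L)
  border <- logical(nlab)
  if (nlab > 0) {
    edge <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    border[edge[edge > 0L]] <- TRUE
  }
  if (excludeBorder && any(border)) {
    lab <- .relabel(lab, which(border))
    border <- logical(max(lab, 0L))
  }
  attr(lab, "markers") <- markers
  attr(lab, "borderTouching") <- border
  lab
}

#' Per-cell mitochondrial mask by fraction-of-maximum thresholding
#'
#' Within one cell, mitochondria are the pixels whose marker (mcherry)
#' intensity is at least `fraction` times the cell's maximal marker
#' intensity. The maximum is taken per cell, not over the whole image, and
#' the comparison is inclusive (>=).
#'
#' @param mcherryProjection 2D marker sum projection.
#' @param cellMask logical matrix selecting one cell (non-empty).
#' @param fraction threshold fraction of the per-cell maximum (default
#'   0.05).
#' @return logical matrix with attribute `"threshold"` (the intensity
#'   cutoff) and `"qcEmpty"` (TRUE when the marker is all zero in the
#'   cell, in which case the mask is empty).
#' @examples
#' m <- matrix(c(9, 10, 11, 200), 2, 2)
#' mitoMask(m, matrix(TRUE, 2, 2))
#' @export
mitoMask <- function(mcherryProjection, cellMask, fraction = 0.05) {
  stopifnot(identical(dim(mcherryProjection), dim(cellMask)))
  cellMask <- cellMask > 0
  if (!any(cellMask)) stop("'cellMask' is empty")
  mx <- max(mcherryProjection[cellMask])
  if (mx <= 0) {
    mask <- cellMask & FALSE
    attr(mask, "threshold") <- 0
    attr(mask, "qcEmpty") <- TRUE
    return(mask)
  }
  thr <- fraction * mx
  mask <- cellMask & (mcherryProjection >= thr)
  attr(mask, "threshold") <- thr
  attr(mask, "qcEmpty") <- FALSE
  mask
}

#' Quantify mitochondrial reporter signal per cell
#'
#' Runs the full pipeline on a two-channel stack: sum projection of both
#' channels, random-walker foreground segmentation of the gfp + mcherry
#' sum, watershed separation of adjoining cells, per-cell mitochondrial
#' masking of the marker projection, and per-cell reporter statistics.
#' The per-cell statistic is the median reporter intensity over the
#' mitochondrial mask (even counts take the midpoint of the two central
#' values); `spgfp_ratio` divides it by the marker median over the same
#' mask.
#'
#' @param stack an \linkS4class{ImageStack} with `gfp` and `mcherry`
#'   channels.
#' @param fraction mitochondrial threshold fraction (default 0.05).
#' @param smoothRadius,bgQuantile,fgQuantile,rwBeta passed to
#'   \code{\link{segmentForeground}}.
#' @param minDistance,minArea,excludeBorder passed to
#'   \code{\link{splitCells}}.
#' @param perImageMax use the image-wide marker maximum for the
#'   mitochondrial threshold instead of the per-cell maximum.
#' @param backgroundSubtract constant subtracted from both projections
#'   before quantification (clipped at zero); default 0, i.e. none.
#' @return list with `cells`, a data.frame of per-cell records (columns
#'   cell_id, cell_area, mcherry_max, mito_threshold, mito_area,
#'   spgfp_median, mcherry_median, spgfp_ratio, qc_flags), and `summary`,
#'   a one-row data.frame of populational means over cells without qc
#'   flags (n_cells, mean_spgfp_median, mean_spgfp_ratio).
#' @export
quantifyCells <- function(stack, fraction = 0.05, smoothRadius = 2,
                          bgQuantile = 0.20, fgQuantile = 0.95, rwBeta = 130,
                          minDistance = 15, minArea = 100,
                          excludeBorder = TRUE, perImageMax = FALSE,
                          backgroundSubtract = 0) {
  gfp <- sumProject(stack, "gfp")
  mch <- sumProject(stack, "mcherry")
  if (backgroundSubtract > 0) {
    gfp <- pmax(gfp - backgroundSubtract, 0)
    mch <- pmax(mch - backgroundSubtract, 0)
  }
  fg <- segmentForeground(gfp + mch, smoothRadius = smoothRadius,
                          bgQuantile = bgQuantile, fgQuantile = fgQuantile,
                          rwBeta = rwBeta)
  lab <- splitCells(fg, minDistance = minDistance, minArea = minArea,
                    excludeBorder = excludeBorder)
  border <- attr(lab, "borderTouching")
  nlab <- max(lab, 0L)
  rows <- vector("list", nlab)
  imageMax <- if (nlab > 0) max(mch[lab > 0]) else 0
  for (i in seq_len(nlab)) {
    cell <- lab == i
    mm <- mitoMask(mch, cell, fraction = fraction)
    if (perImageMax && imageMax > 0) {
      thr <- fraction * imageMax
      mm <- cell & (mch >= thr)
      attr(mm, "threshold") <- thr
      attr(mm, "qcEmpty") <- !any(mm)
    }
    flags <- character()
    if (length(border) >= i && border[i]) flags <- c(flags, "border")
    if (attr(mm, "qcEmpty") || !any(mm)) flags <- c(flags, "empty_mito")
    gm <- if (any(mm)) median(gfp[mm]) else NA_real_
    cm <- if (any(mm)) median(mch[mm]) else NA_real_
    rows[[i]] <- data.frame(
      cell_id = i, cell_area = sum(cell),
      mcherry_max = max(mch[cell]),
      mito_threshold = attr(mm, "threshold"), mito_area = sum(mm),
      spgfp_median = gm, mcherry_median = cm,
      spgfp_ratio = if (!is.na(cm) && cm > 0) gm / cm else NA_real_,
      qc_flags = .joinFlags(flags), stringsAsFactors = FALSE)
  }
  cells <- if (nlab > 0) do.call(rbind, rows) else
    data.frame(cell_id = integer(), cell_area = integer(),
               mcherry_max = numeric(), mito_threshold = numeric(),
               mito_area = integer(), spgfp_median = numeric(),
               mcherry_median = numeric(), spgfp_ratio = numeric(),
               qc_flags = character())
  ok <- cells$qc_flags == ""
  summary <- data.frame(
    n_cells = sum(ok),
    mean_spgfp_median = if (any(ok)) mean(cells$spgfp_median[ok]) else NA_real_,
    mean_spgfp_ratio = if (any(ok)) mean(cells$spgfp_ratio[ok]) else NA_real_)
  list(cells = cells, summary = summary, labels = lab)
}
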