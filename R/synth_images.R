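# Synthetic microscopy fields with full ground truth.
#
# Cells are rendered as axis-aligned ellipses placed by rejection sampling
# with a configurable minimum gap. Mitochondria are self-avoiding lattice
# walks dilated to a tubule width and confined to the cell, which gives the
# tubular-network morphology of yeast mitochondria without modelling real
# organelle geometry. Signal is distributed over z with a triangular
# profile whose weights sum to 1, so the clean sum projection carries the
# nominal per-cell intensities exactly. Noise (optional) is Poisson shot
# noise on the clean signal followed by additive Gaussian read noise,
# the standard fluorescence camera model, applied last.

#' Specification of a synthetic microscopy field
#'
#' Collects and validates the geometry, intensity and noise parameters of
#' the image generators. Intensities are in arbitrary camera units; sizes
#' in pixels. The defaults emulate a field of yeast-like cells imaged as a
#' 12-plane confocal z-stack.
#'
#' @param fieldShape integer (z, y, x) field dimensions.
#' @param nCells number of cells to place.
#' @param cellRadiusRange range of ellipse semi-axes, pixels.
#' @param mitoTubuleWidth tubule width, pixels; must be below the smallest
#'   cell radius.
#' @param mitoFillFraction target fraction of the cell area covered by
#'   mitochondria.
#' @param gfpOnMito reporter intensity added on mitochondrial pixels
#'   (summed over z). A scalar, a length-`nCells` vector, or a
#'   `function(n)` sampler drawn once per field.
#' @param gfpCytosol reporter intensity added over the whole cell.
#' @param mcherryOnMito mitochondrial marker intensity on mitochondrial
#'   pixels; scalar, vector or sampler like `gfpOnMito`.
#' @param backgroundLevel constant background added to every plane.
#' @param backgroundGradient left-to-right linear background slope,
#'   intensity per pixel, per plane.
#' @param noiseSd standard deviation of additive Gaussian read noise.
#' @param shotNoise logical; apply Poisson shot noise to the clean signal.
#' @param minGap minimum empty gap between neighbouring cells, pixels;
#'   set to 0 to allow touching cells (useful for watershed stress tests).
#' @param seed integer seed; identical spec and seed give bit-identical
#'   output.
#' @return a validated `SynthImageSpec` (a classed list).
#' @examples
#' sp <- synthImageSpec(fieldShape = c(4, 96, 96), nCells = 3, seed = 7)
#' @export
synthImageSpec <- function(fieldShape = c(12L, 512L, 512L), nCells = 20L,
                           cellRadiusRange = c(8, 13), mitoTubuleWidth = 2,
                           mitoFillFraction = 0.25, gfpOnMito = 60,
                           gfpCytosol = 25, mcherryOnMito = 120,
                           backgroundLevel = 0, backgroundGradient = 0,
                           noiseSd = 0, shotNoise = FALSE, minGap = 1,
                           seed = 1L) {
  stopifnot(length(fieldShape) == 3L, all(fieldShape >= 1))
  if (nCells < 0) stop("'nCells' must be >= 0")
  stopifnot(length(cellRadiusRange) == 2L,
            cellRadiusRange[1] <= cellRadiusRange[2], cellRadiusRange[1] > 0)
  if (mitoTubuleWidth >= cellRadiusRange[1])
    stop("cell radii must exceed the mitochondrial tubule width")
  stopifnot(mitoFillFraction > 0, mitoFillFraction <= 1)
  for (nm in c("gfpCytosol", "backgroundLevel", "noiseSd"))
    if (get(nm) < 0) stop(sprintf("'%s' must be >= 0", nm))
  for (nm in c("gfpOnMito", "mcherryOnMito")) {
    v <- get(nm)
    if (!is.function(v) && any(v < 0))
      stop(sprintf("'%s' intensities must be >= 0", nm))
  }
  structure(list(fieldShape = as.integer(fieldShape), nCells = as.integer(nCells),
                 cellRadiusRange = cellRadiusRange,
                 mitoTubuleWidth = mitoTubuleWidth,
                 mitoFillFraction = mitoFillFraction, gfpOnMito = gfpOnMito,
                 gfpCytosol = gfpCytosol, mcherryOnMito = mcherryOnMito,
                 backgroundLevel = backgroundLevel,
                 backgroundGradient = backgroundGradient, noiseSd = noiseSd,
                 shotNoise = shotNoise, minGap = minGap,
                 seed = as.integer(seed)),
            class = "SynthImageSpec")
}

# Resolve a per-cell intensity parameter (scalar, vector or sampler).
.perCell <- function(value, n, what) {
  if (is.function(value)) value <- value(n)
  if (length(value) == 1L) value <- rep(value, n)
  if (length(value) != n)
    stop(sprintf("'%s' must be a scalar, a length-%d vector, or a sampler",
                 what, n))
  if (any(value < 0)) stop(sprintf("'%s' intensities must be >= 0", what))
  value
}

# Place nCells non-overlapping ellipses; returns the label matrix and the
# per-cell geometry. Rejection sampling with a retry cap.
.placeCells <- function(spec, ny, nx, maxTries = 400L) {
  labels <- matrix(0L, ny, nx)
  occupied <- matrix(FALSE, ny, nx)  # cells dilated by minGap
  geom <- vector("list", spec$nCells)
  rr <- spec$cellRadiusRange
  gap <- spec$minGap
  placed <- 0L
  tries <- 0L
  while (placed < spec$nCells) {
    tries <- tries + 1L
    if (tries > maxTries * max(1L, spec$nCells)) {
      dens <- sum(labels > 0) / length(labels)
      stop(sprintf(paste0("could not place %d cells after %d attempts; ",
                          "achieved %d cells (density %.1f%%) - reduce ",
                          "'nCells' or the cell radii"),
                   spec$nCells, tries, placed, 100 * dens))
    }
    ry <- runif(1, rr[1], rr[2])
    rx <- runif(1, rr[1], rr[2])
    # keep cells clear of the field border so segmented masks are not
    # truncated (smoothing spreads the foreground by a few pixels)
    m <- gap + 4
    cy <- runif(1, ry + m, ny - ry - m)
    cx <- runif(1, rx + m, nx - rx - m)
    ys <- max(1L, floor(cy - ry - gap)):min(ny, ceiling(cy + ry + gap))
    xs <- max(1L, floor(cx - rx - gap)):min(nx, ceiling(cx + rx + gap))
    dy <- (ys - cy) / ry
    dx <- (xs - cx) / rx
    inside <- outer(dy^2, dx^2, "+") <= 1
    gy <- (ys - cy) / (ry + gap)
    gx <- (xs - cx) / (rx + gap)
    near <- outer(gy^2, gx^2, "+") <= 1
    if (any(occupied[ys, xs] & near)) next
    placed <- placed + 1L
    block <- labels[ys, xs]
    block[inside] <- placed
    labels[ys, xs] <- block
    occupied[ys, xs] <- occupied[ys, xs] | near
    geom[[placed]] <- list(cy = cy, cx = cx, ry = ry, rx = rx)
  }
  list(labels = labels, geom = geom)
}

# Self-avoiding lattice walk inside a cell, dilated to the tubule width and
# clipped to the cell mask. Returns a logical matrix (full field size).
.growTubules <- function(cellPixels, ny, nx, width, fillFraction) {
  target <- max(1L, ceiling(fillFraction * nrow(cellPixels)))
  inCell <- matrix(FALSE, ny, nx)
  inCell[cellPixels] <- TRUE
  path <- matrix(FALSE, ny, nx)
  visited <- matrix(FALSE, ny, nx)
  steps <- c(-1L, 1L, 0L, 0L)
  stepsx <- c(0L, 0L, -1L, 1L)
  # multiple walk branches until the dilated path reaches the fill target
  for (branch in seq_len(6L)) {
    start <- cellPixels[sample.int(nrow(cellPixels), 1L), , drop = TRUE]
    y <- start[1]; x <- start[2]
    path[y, x] <- TRUE; visited[y, x] <- TRUE
    for (s in seq_len(10L * target)) {
      ord <- sample.int(4L)
      moved <- FALSE
      for (k in ord) {
        yy <- y + steps[k]; xx <- x + stepsx[k]
        if (yy >= 1 && yy <= ny && xx >= 1 && xx <= nx &&
            inCell[yy, xx] && !visited[yy, xx]) {
          y <- yy; x <- xx
          path[y, x] <- TRUE; visited[y, x] <- TRUE
          moved <- TRUE
          break
        }
      }
      if (!moved) break  # walk is stuck; start a new branch
    }
    dil <- .asMat(EBImage::dilate(path * 1, .discBrush(floor(width / 2)))) > 0
    if (sum(dil & inCell) >= target) break
  }
  dil <- .asMat(EBImage::dilate(path * 1, .discBrush(floor(width / 2)))) > 0
  dil & inCell
}

# Triangular z profile with weights summing to 1.
.zProfile <- function(nz) {
  w <- pmin(seq_len(nz), rev(seq_len(nz)))
  w / sum(w)
}

# Apply the camera noise model to a clean stack (list of 3D arrays).
.applyNoise <- function(channels, spec) {
  if (!spec$shotNoise && spec$noiseSd == 0) return(channels)
  lapply(channels, function(a) {
    if (spec$shotNoise) a[] <- rpois(length(a), lambda = a)
    if (spec$noiseSd > 0) a[] <- a + rnorm(length(a), sd = spec$noiseSd)
    a[a < 0] <- 0
    a
  })
}

.backgroundPlane <- function(spec, ny, nx) {
  matrix(spec$backgroundLevel, ny, nx) +
    outer(rep(1, ny), seq_len(nx) - 1L) * spec$backgroundGradient
}

#' Generate a synthetic two-channel mitochondrial reporter field
#'
#' Renders `nCells` elliptical cells containing tubular mitochondrial
#' networks. The reporter (gfp) channel carries signal on mitochondrial
#' pixels plus a dimmer cytosolic fill; the marker (mcherry) channel is
#' mitochondrial only. Ground truth contains the cell and mitochondrial
#' label masks and the per-cell median of the clean reporter sum
#' projection over the true mitochondrial pixels.
#'
#' @param spec a \code{\link{synthImageSpec}}.
#' @return list with elements `stack` (\linkS4class{ImageStack}, channels
#'   gfp and mcherry) and `truth` (\linkS4class{GroundTruth}).
#' @examples
#' f <- generateImageField(synthImageSpec(fieldShape = c(4, 128, 128),
#'                                        nCells = 4, seed = 2))
#' max(f$truth@cellMasks)
#' @export
generateImageField <- function(spec) {
  stopifnot(inherits(spec, "SynthImageSpec"))
  .withSeed(spec$seed, {
    nz <- spec$fieldShape[1]; ny <- spec$fieldShape[2]; nx <- spec$fieldShape[3]
    pl <- .placeCells(spec, ny, nx)
    labels <- pl$labels
    n <- spec$nCells
    gfpMito <- .perCell(spec$gfpOnMito, n, "gfpOnMito")
    mchMito <- .perCell(spec$mcherryOnMito, n, "mcherryOnMito")

    mito <- matrix(0L, ny, nx)
    gfpSum <- .backgroundPlane(spec, ny, nx) * nz
    mchSum <- .backgroundPlane(spec, ny, nx) * nz
    for (i in seq_len(n)) {
      px <- which(labels == i, arr.ind = TRUE)
      tub <- .withSeed(.subSeed(spec$seed, i),
                       .growTubules(px, ny, nx, spec$mitoTubuleWidth,
                                    spec$mitoFillFraction))
      mito[tub] <- i
      gfpSum[labels == i] <- gfpSum[labels == i] + spec$gfpCytosol
      gfpSum[tub] <- gfpSum[tub] + gfpMito[i]
      mchSum[tub] <- mchSum[tub] + mchMito[i]
    }

    wz <- .zProfile(nz)
    mk3d <- function(plane2d) {
      a <- array(0, dim = c(nz, ny, nx))
      for (z in seq_len(nz)) a[z, , ] <- plane2d * wz[z]
      a
    }
    channels <- .applyNoise(list(gfp = mk3d(gfpSum), mcherry = mk3d(mchSum)),
                            spec)
    trueMed <- vapply(seq_len(n), function(i) {
      if (!any(mito == i)) return(NA_real_)
      median(gfpSum[mito == i])
    }, numeric(1))

    list(stack = ImageStack(channels, pixelSize = 0.1, zStep = 0.5),
         truth = new("GroundTruth", cellMasks = labels, mitoMasks = mito,
                     trueSpgfpMedian = trueMed))
  })
}

#' Generate a synthetic nuclear-marker field with prescribed N/C ratios
#'
#' Renders cells with one nuclear disk strictly inside each cell. The
#' reporter (gfp) channel is uniform over the cytoplasm at `gfpCytosol`
#' and equals `gfpCytosol * ncRatios[i]` over the nucleus, so the mean
#' nuclear / mean cytoplasmic reporter intensity equals the requested
#' ratio exactly before noise. The nuclear marker (rfp) channel is bright
#' over the nucleus only.
#'
#' @param spec a \code{\link{synthImageSpec}}; `gfpCytosol` must be > 0.
#' @param ncRatios per-cell nucleocytoplasmic ratios (> 0); recycled if
#'   scalar.
#' @param rfpNuclear nuclear marker intensity (summed over z).
#' @return list with `stack` (channels gfp, rfp) and `truth` (cell and
#'   nuclear masks plus `trueNcRatio`).
#' @export
generateNCField <- function(spec, ncRatios, rfpNuclear = 150) {
  stopifnot(inherits(spec, "SynthImageSpec"))
  if (any(ncRatios <= 0)) stop("'ncRatios' must be > 0")
  if (spec$gfpCytosol <= 0)
    stop("'gfpCytosol' must be > 0 for a nucleocytoplasmic field")
  if (length(ncRatios) == 1L) ncRatios <- rep(ncRatios, spec$nCells)
  stopifnot(length(ncRatios) == spec$nCells)
  .withSeed(spec$seed, {
    nz <- spec$fieldShape[1]; ny <- spec$fieldShape[2]; nx <- spec$fieldShape[3]
    pl <- .placeCells(spec, ny, nx)
    labels <- pl$labels
    n <- spec$nCells

    nuc <- matrix(0L, ny, nx)
    gfpSum <- .backgroundPlane(spec, ny, nx) * nz
    rfpSum <- .backgroundPlane(spec, ny, nx) * nz
    for (i in seq_len(n)) {
      g <- pl$geom[[i]]
      rn <- 0.35 * min(g$ry, g$rx)
      # nucleus centre jittered but kept strictly inside the cell
      off <- 0.25 * min(g$ry, g$rx)
      cyN <- g$cy + runif(1, -off, off)
      cxN <- g$cx + runif(1, -off, off)
      ys <- max(1L, floor(cyN - rn)):min(ny, ceiling(cyN + rn))
      xs <- max(1L, floor(cxN - rn)):min(nx, ceiling(cxN + rn))
      disk <- outer(((ys - cyN) / rn)^2, ((xs - cxN) / rn)^2, "+") <= 1
      block <- nuc[ys, xs]
      block[disk & labels[ys, xs] == i] <- i
      nuc[ys, xs] <- block
      gfpSum[labels == i] <- gfpSum[labels == i] + spec$gfpCytosol
      gfpSum[nuc == i] <- gfpSum[nuc == i] +
        spec$gfpCytosol * (ncRatios[i] - 1)
      rfpSum[nuc == i] <- rfpSum[nuc == i] + rfpNuclear
    }

    wz <- .zProfile(nz)
    mk3d <- function(plane2d) {
      a <- array(0, dim = c(nz, ny, nx))
      for (z in seq_len(nz)) a[z, , ] <- plane2d * wz[z]
      a
    }
    channels <- .applyNoise(list(gfp = mk3d(gfpSum), rfp = mk3d(rfpSum)), spec)
    list(stack = ImageStack(channels, pixelSize = 0.1, zStep = 0.5),
         truth = new("GroundTruth", cellMasks = labels, nuclearMasks = nuc,
                     trueNcRatio = ncRatios))
  })
}
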