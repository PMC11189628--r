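#' @import methods
#' @importFrom stats median quantile rbinom rlnorm rnorm rpois runif sd t.test pt var
#' @importFrom utils read.csv write.csv head modifyList
NULL

#' Multi-channel 3D fluorescence stack
#'
#' Container for a named set of 3D intensity arrays (z, y, x) acquired from
#' the same field, with the pixel and z spacing recorded in micrometres.
#' All channels must share one shape, and intensities must be finite and
#' non-negative.
#'
#' @slot channels named list of 3D numeric arrays, dimensions (z, y, x).
#' @slot pixelSize lateral pixel size in micrometres.
#' @slot zStep axial step between planes in micrometres.
#'
#' @examples
#' a <- array(runif(2 * 4 * 4), dim = c(2, 4, 4))
#' st <- ImageStack(list(gfp = a, mcherry = a), pixelSize = 0.1, zStep = 0.5)
#' channelNames(st)
#' @export
setClass("ImageStack",
  representation(channels = "list", pixelSize = "numeric", zStep = "numeric"),
  prototype(channels = list(), pixelSize = NA_real_, zStep = NA_real_))

setValidity("ImageStack", function(object) {
  ch <- object@channels
  if (length(ch) == 0L) return("'channels' must contain at least one array")
  if (is.null(names(ch)) || any(!nzchar(names(ch))) || anyDuplicated(names(ch)))
    return("'channels' must have unique non-empty names")
  d <- dim(ch[[1L]])
  for (nm in names(ch)) {
    a <- ch[[nm]]
    if (!is.array(a) || length(dim(a)) != 3L)
      return(sprintf("channel '%s' is not a 3D array", nm))
    if (!identical(dim(a), d))
      return("all channels must share the same (z, y, x) shape")
    if (any(!is.finite(a)) || any(a < 0))
      return(sprintf("channel '%s' has non-finite or negative intensities", nm))
  }
  TRUE
})

#' Construct an ImageStack
#'
#' @param channels named list of 3D arrays (z, y, x).
#' @param pixelSize lateral pixel size (micrometres).
#' @param zStep z spacing (micrometres).
#' @return an \linkS4class{ImageStack}.
#' @export
ImageStack <- function(channels, pixelSize = NA_real_, zStep = NA_real_) {
  new("ImageStack", channels = channels,
      pixelSize = as.numeric(pixelSize), zStep = as.numeric(zStep))
}

#' @describeIn ImageStack names of the channels present.
#' @param x,object an ImageStack.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @export
setMethod("channelNames", "ImageStack", function(x) names(x@channels))

#' Extract one channel of a stack
#'
#' @param x an \linkS4class{ImageStack}.
#' @param channel channel name.
#' @return the 3D array for that channel.
#' @export
setGeneric("getChannel", function(x, channel) standardGeneric("getChannel"))

#' @export
setMethod("getChannel", "ImageStack", function(x, channel) {
  if (!channel %in% names(x@channels))
    stop(sprintf("unknown channel '%s' (available: %s)", channel,
                 paste(names(x@channels), collapse = ", ")))
  x@channels[[channel]]
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@channels[[1L]])
  cat("ImageStack with", length(object@channels), "channel(s):",
      paste(names(object@channels), collapse = ", "), "\n")
  cat(sprintf("  shape (z, y, x): %d x %d x %d\n", d[1], d[2], d[3]))
  cat(sprintf("  pixel size: %s um, z step: %s um\n",
              format(object@pixelSize), format(object@zStep)))
})

#' Generator-side ground truth
#'
#' Truth tables emitted alongside synthetic data: label masks, per-cell
#' true medians and ratios, per-event positivity, and true strain classes.
#' Slots not applicable to a given generator are left empty.
#'
#' @slot cellMasks integer label matrix (0 = background, 1..n = cells).
#' @slot mitoMasks integer label matrix of mitochondrial pixels, labelled by
#'   owning cell; always a subset of the cell mask.
#' @slot nuclearMasks integer label matrix of nuclei, labelled by owning cell.
#' @slot trueSpgfpMedian per-cell median reporter intensity of the clean
#'   (noise-free) sum projection over the true mitochondrial mask.
#' @slot trueNcRatio per-cell true nucleocytoplasmic ratio.
#' @slot positives per-event logical positivity flags (flow samples).
#' @slot truePositiveFraction fraction of truly positive events.
#' @slot trueClass named character vector of true strain classes.
#' @export
setClass("GroundTruth",
  representation(cellMasks = "matrix", mitoMasks = "matrix",
                 nuclearMasks = "matrix", trueSpgfpMedian = "numeric",
                 trueNcRatio = "numeric", positives = "logical",
                 truePositiveFraction = "numeric", trueClass = "character"),
  prototype(cellMasks = matrix(integer(), 0, 0),
            mitoMasks = matrix(integer(), 0, 0),
            nuclearMasks = matrix(integer(), 0, 0),
            trueSpgfpMedian = numeric(), trueNcRatio = numeric(),
            positives = logical(), truePositiveFraction = numeric(),
            trueClass = character()))

setValidity("GroundTruth", function(object) {
  cm <- object@cellMasks
  if (length(cm)) {
    labs <- sort(unique(as.integer(cm[cm > 0])))
    if (length(labs) && !identical(labs, seq_along(labs)))
      return("cell labels must be contiguous from 1")
    for (nm in c("mitoMasks", "nuclearMasks")) {
      sub <- slot(object, nm)
      if (length(sub)) {
        if (!identical(dim(sub), dim(cm)))
          return(sprintf("'%s' shape differs from 'cellMasks'", nm))
        if (any(sub > 0 & sub != cm))
          return(sprintf("'%s' is not contained in its cell mask", nm))
      }
    }
  }
  TRUE
})

setMethod("show", "GroundTruth", function(object) {
  n <- max(0L, object@cellMasks)
  cat("GroundTruth:", n, "cell(s)")
  if (length(object@positives))
    cat(";", sum(object@positives), "of", length(object@positives),
        "events positive")
  if (length(object@trueClass))
    cat(";", length(object@trueClass), "strain labels")
  cat("\n")
})

#' Flow-cytometry event sample
#'
#' One acquisition: a table with one row per event and one named intensity
#' column per channel, plus free-form metadata (strain, condition,
#' replicate).
#'
#' @slot sampleId sample identifier.
#' @slot events data.frame of per-event channel intensities.
#' @slot metadata named list of sample annotations.
#' @export
setClass("FlowSample",
  representation(sampleId = "character", events = "data.frame",
                 metadata = "list"),
  prototype(sampleId = NA_character_, events = data.frame(),
            metadata = list()))

setValidity("FlowSample", function(object) {
  ev <- object@events
  if (ncol(ev)) {
    if (is.null(names(ev)) || any(!nzchar(names(ev))))
      return("event channels must be named")
    for (nm in names(ev))
      if (!is.numeric(ev[[nm]]) || any(!is.finite(ev[[nm]])))
        return(sprintf("channel '%s' has non-finite intensities", nm))
  }
  TRUE
})

#' Construct a FlowSample
#'
#' @param events data.frame with one numeric column per channel.
#' @param sampleId sample identifier.
#' @param metadata named list of annotations.
#' @return a \linkS4class{FlowSample}.
#' @export
FlowSample <- function(events, sampleId = "sample", metadata = list()) {
  new("FlowSample", sampleId = as.character(sampleId),
      events = as.data.frame(events), metadata = metadata)
}

#' Number of events in a flow sample
#' @param x a \linkS4class{FlowSample}.
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))

#' @export
setMethod("nEvents", "FlowSample", function(x) nrow(x@events))

setMethod("show", "FlowSample", function(object) {
  cat(sprintf("FlowSample '%s': %d events, channels: %s\n", object@sampleId,
              nrow(object@events), paste(names(object@events), collapse = ", ")))
})

#' Calibrated positivity gate
#'
#' A threshold on one channel, calibrated on a negative-control sample so
#' that strictly fewer than `maxPositive` of the control's events exceed it.
#'
#' @slot channel gated channel name.
#' @slot threshold intensity threshold; events strictly above it are positive.
#' @slot maxPositive calibration bound on the control positive fraction.
#' @slot calibrationSampleId id of the control sample used.
#' @export
setClass("GateModel",
  representation(channel = "character", threshold = "numeric",
                 maxPositive = "numeric", calibrationSampleId = "character"))

setMethod("show", "GateModel", function(object) {
  cat(sprintf(
    "GateModel on '%s': threshold %.6g (control '%s' kept < %.3g%% positive)\n",
    object@channel, object@threshold, object@calibrationSampleId,
    100 * object@maxPositive))
})

#' Gate threshold accessor
#' @param x a \linkS4class{GateModel}.
#' @export
setGeneric("gateThreshold", function(x) standardGeneric("gateThreshold"))

#' @export
setMethod("gateThreshold", "GateModel", function(x) x@threshold)

#' Simulated genome-wide screen dataset
#'
#' Per-strain flow event samples at 30 degrees C (pre) and after heat shock
#' (post), per-strain imaging-validation samples, a reporter-free
#' background control, and the true class labels.
#'
#' @slot strainIds strain identifiers.
#' @slot preEvents named list of per-strain 30C event intensity vectors.
#' @slot postEvents named list of per-strain post-heat-shock event vectors.
#' @slot validation named list; per strain a list with per-cell `ratio30`
#'   (spGFP/mCherry ratios at 30C), `pre` and `post` (spGFP intensities
#'   before/after heat shock).
#' @slot wtRatio30 per-cell 30C ratios of the designated wild-type
#'   reference strain.
#' @slot backgroundEvents events from reporter-free control wells.
#' @slot wtId id of the wild-type reference strain.
#' @slot truth a \linkS4class{GroundTruth} carrying the true class labels.
#' @export
setClass("ScreenDataset",
  representation(strainIds = "character", preEvents = "list",
                 postEvents = "list", validation = "list",
                 wtRatio30 = "numeric", backgroundEvents = "numeric",
                 wtId = "character", truth = "GroundTruth"))

setValidity("ScreenDataset", function(object) {
  ids <- object@strainIds
  if (anyDuplicated(ids)) return("duplicated strain ids")
  for (nm in c("preEvents", "postEvents", "validation"))
    if (!identical(names(slot(object, nm)), ids))
      return(sprintf("'%s' must be named by strainIds, in order", nm))
  if (!object@wtId %in% ids) return("wild-type reference strain missing")
  TRUE
})

setMethod("show", "ScreenDataset", function(object) {
  tc <- object@truth@trueClass
  cat(sprintf("ScreenDataset: %d strains (WT reference '%s')\n",
              length(object@strainIds), object@wtId))
  if (length(tc)) print(table(factor(tc)))
})

#' Strain ids of a screen dataset
#' @param x a \linkS4class{ScreenDataset}.
#' @export
setGeneric("strainIds", function(x) standardGeneric("strainIds"))

#' @export
setMethod("strainIds", "ScreenDataset", function(x) x@strainIds)

#' Ground truth accessor
#' @param x an object carrying generator truth.
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @export
setMethod("groundTruth", "ScreenDataset", function(x) x@truth)
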