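# Flow-cytometry gating and population statistics.
#
# Positivity is defined by a strict ">" comparison against a threshold
# calibrated on a negative-control sample with a nearest-rank rule: the
# smallest observed control intensity above which strictly fewer than
# `maxPositive` of the control's events lie. On the calibration sample the
# positive fraction is therefore below the bound by construction, for any
# control. Raw intensities are used throughout (no compensation or
# variance-stabilising transform).

.getEvents <- function(sample, channel) {
  stopifnot(is(sample, "FlowSample"))
  if (nEvents(sample) == 0L)
    stop(sprintf("sample '%s' has no events", sample@sampleId))
  if (!channel %in% names(sample@events))
    stop(sprintf("channel '%s' not present in sample '%s'", channel,
                 sample@sampleId))
  sample@events[[channel]]
}

#' Calibrate a positivity gate on a negative control
#'
#' Chooses the smallest observed control intensity `v` such that the
#' fraction of control events strictly above `v` is below `maxPositive`.
#'
#' @param control negative-control \linkS4class{FlowSample}.
#' @param channel channel to gate on.
#' @param maxPositive calibration bound (default 0.01, i.e. fewer than 1
#'   percent of control events positive).
#' @return a \linkS4class{GateModel}.
#' @examples
#' ctl <- FlowSample(data.frame(spgfp = 1:1000), "etoh_control")
#' gateThreshold(calibrateGate(ctl, "spgfp"))  # 991
#' @export
calibrateGate <- function(control, channel, maxPositive = 0.01) {
  v <- .getEvents(control, channel)
  stopifnot(maxPositive > 0, maxPositive <= 1)
  n <- length(v)
  u <- sort(unique(v))
  countAbove <- n - cumsum(tabulate(match(v, u), nbins = length(u)))
  thr <- u[which(countAbove / n < maxPositive)[1L]]
  new("GateModel", channel = channel, threshold = thr,
      maxPositive = maxPositive,
      calibrationSampleId = control@sampleId)
}

#' Fraction of events above a gate
#'
#' @param sample a \linkS4class{FlowSample}.
#' @param gate a \linkS4class{GateModel}.
#' @return fraction of events strictly above the gate threshold.
#' @export
positiveFraction <- function(sample, gate) {
  v <- .getEvents(sample, gate@channel)
  mean(v > gate@threshold)
}

#' Population mean and spread of one channel
#'
#' Arithmetic mean and standard deviation over all events. Samples below
#' `minEvents` events are flagged (a warning condition, not an error):
#' populational means in this assay are conventionally computed from at
#' least 25,000 single cells.
#'
#' @param sample a \linkS4class{FlowSample}.
#' @param channel channel name.
#' @param minEvents flag threshold on the event count (default 25000).
#' @return list with `mean`, `sd`, `n`, `lowN`.
#' @export
populationStats <- function(sample, channel, minEvents = 25000L) {
  v <- .getEvents(sample, channel)
  list(mean = mean(v), sd = sd(v), n = length(v),
       lowN = length(v) < minEvents)
}

#' Compare a second channel between gate-positive and gate-negative events
#'
#' Splits the sample by the gate on its channel and computes
#' \code{\link{populationStats}} of `valueChannel` in each group. A group
#' with no events gets `NA` statistics and a flag.
#'
#' @param sample a \linkS4class{FlowSample} carrying both channels.
#' @param gate a \linkS4class{GateModel}.
#' @param valueChannel channel summarised within each group.
#' @param minEvents passed to \code{\link{populationStats}}.
#' @return list with `positive` and `negative`, each a list with `mean`,
#'   `sd`, `n`, `lowN` and `empty`.
#' @export
splitByGate <- function(sample, gate, valueChannel, minEvents = 25000L) {
  g <- .getEvents(sample, gate@channel)
  v <- .getEvents(sample, valueChannel)
  grp <- function(x) {
    if (length(x) == 0L)
      return(list(mean = NA_real_, sd = NA_real_, n = 0L, lowN = TRUE,
                  empty = TRUE))
    list(mean = mean(x), sd = sd(x), n = length(x),
         lowN = length(x) < minEvents, empty = FALSE)
  }
  pos <- g > gate@threshold
  list(positive = grp(v[pos]), negative = grp(v[!pos]))
}
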