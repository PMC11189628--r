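# Synthetic flow-cytometry event tables and whole screens with truth.

#' Generate a synthetic flow-cytometry sample
#'
#' Event intensities are lognormal (strictly positive), emulating the
#' right-skewed single-cell reporter distributions seen on a cytometer. A
#' fraction of events may belong to a positive subpopulation whose
#' log-intensity is shifted upwards by `positiveShift`. An optional second
#' channel (e.g. a membrane-potential dye) is drawn per population with
#' its own log-means, so gated comparisons have a known true difference.
#'
#' @param nEvents number of events (> 0).
#' @param nullLogMean,nullLogSd log-intensity mean and sd of the null
#'   (negative) population on the reporter channel.
#' @param positiveFraction fraction of events in the positive
#'   subpopulation, in [0, 1]; the exact count is `round(nEvents *
#'   positiveFraction)`.
#' @param positiveShift log-intensity added to positive events.
#' @param channel reporter channel name.
#' @param secondChannel optional list describing a second channel:
#'   `name`, `negLogMean`, `posLogMean`, `logSd`.
#' @param sampleId sample identifier.
#' @param seed integer seed.
#' @return list with `sample` (\linkS4class{FlowSample}) and `truth`
#'   (\linkS4class{GroundTruth} with per-event positivity flags).
#' @examples
#' fs <- generateFlowSample(nEvents = 1000, positiveFraction = 0.2, seed = 3)
#' mean(fs$truth@positives)
#' @export
generateFlowSample <- function(nEvents = 25000L, nullLogMean = log(100),
                               nullLogSd = 0.4, positiveFraction = 0,
                               positiveShift = 2, channel = "spgfp",
                               secondChannel = NULL, sampleId = "sample",
                               seed = 1L) {
  if (nEvents <= 0) stop("'nEvents' must be > 0")
  if (positiveFraction < 0 || positiveFraction > 1)
    stop("'positiveFraction' must lie in [0, 1]")
  .withSeed(seed, {
    nPos <- as.integer(round(nEvents * positiveFraction))
    pos <- rep(FALSE, nEvents)
    if (nPos > 0) pos[sample.int(nEvents, nPos)] <- TRUE
    mu <- ifelse(pos, nullLogMean + positiveShift, nullLogMean)
    ev <- data.frame(rlnorm(nEvents, meanlog = mu, sdlog = nullLogSd))
    names(ev) <- channel
    if (!is.null(secondChannel)) {
      stopifnot(all(c("name", "negLogMean", "posLogMean", "logSd") %in%
                      names(secondChannel)))
      mu2 <- ifelse(pos, secondChannel$posLogMean, secondChannel$negLogMean)
      ev[[secondChannel$name]] <- rlnorm(nEvents, meanlog = mu2,
                                         sdlog = secondChannel$logSd)
    }
    list(sample = FlowSample(ev, sampleId = sampleId),
         truth = new("GroundTruth", positives = pos,
                     truePositiveFraction = nPos / nEvents))
  })
}

#' Assign true classes to a set of screen strains
#'
#' Convenience constructor for the `classAssignments` argument of
#' \code{\link{generateScreenDataset}}: the first strain is the wild-type
#' reference, the next `nClass1` strains are Class 1, the following
#' `nClass2` are Class 2, and the remainder are Responsive.
#'
#' @param nStrains total number of strains (including the WT reference).
#' @param nClass1,nClass2 numbers of true Class 1 / Class 2 strains.
#' @return named character vector of classes; names are strain ids and
#'   the first id is the WT reference.
#' @export
makeClassAssignments <- function(nStrains, nClass1, nClass2) {
  stopifnot(nStrains >= 1 + nClass1 + nClass2)
  ids <- sprintf("strain%04d", seq_len(nStrains))
  cls <- rep("Responsive", nStrains)
  cls[seq_len(nClass1) + 1L] <- "Class1"
  cls[seq_len(nClass2) + 1L + nClass1] <- "Class2"
  names(cls) <- ids
  cls
}

#' Generate a synthetic knockout-screen dataset
#'
#' Emulates a flow-based screen of knockout strains measured at 30C (pre)
#' and after heat shock (post), plus the per-strain imaging-validation
#' samples used for classification. Event intensities are background plus
#' a lognormal signal, so the background-subtracted populational mean of a
#' responsive strain increases by `wtFold` after heat shock while Class 2
#' strains show no increase and Class 1 strains an elevated 30C baseline.
#' Validation samples are Gaussian per-cell measurements with effects in
#' units of the within-sample standard deviation.
#'
#' @param nStrains number of strains.
#' @param classAssignments named character vector mapping every strain id
#'   to "Class1", "Class2" or "Responsive"; see
#'   \code{\link{makeClassAssignments}}.
#' @param wtId id of the designated wild-type reference strain (must be
#'   assigned "Responsive").
#' @param cellsPerStrain flow events per strain and condition.
#' @param validationCells cells per imaging-validation sample.
#' @param effectParams list of effect sizes and population parameters:
#'   `wtFold` (heat-shock fold change of background-subtracted signal in
#'   responsive strains), `class1Baseline` (30C baseline multiplier of
#'   Class 1 strains), `class1EffectSd` and `hsEffectSd` (validation
#'   effects in within-sample SDs), `baseLogMean`, `baseLogSd`
#'   (lognormal signal), `background` (reporter-free well level),
#'   `ratioMean`, `ratioSd`, `intMean`, `intSd` (validation Gaussians).
#' @param seed integer seed.
#' @return a \linkS4class{ScreenDataset}.
#' @examples
#' cls <- makeClassAssignments(20, 2, 3)
#' ds <- generateScreenDataset(20, cls, cellsPerStrain = 500, seed = 4)
#' table(groundTruth(ds)@trueClass)
#' @export
generateScreenDataset <- function(nStrains, classAssignments,
                                  wtId = names(classAssignments)[1L],
                                  cellsPerStrain = 5000L,
                                  validationCells = 50L,
                                  effectParams = list(), seed = 1L) {
  ids <- names(classAssignments)
  if (is.null(ids) || length(classAssignments) != nStrains)
    stop("'classAssignments' must be a named vector covering all strains")
  if (!all(classAssignments %in% c("Class1", "Class2", "Responsive")))
    stop("classes must be Class1, Class2 or Responsive")
  if (is.null(wtId) || !wtId %in% ids)
    stop("a designated wild-type reference strain must be present")
  if (classAssignments[[wtId]] != "Responsive")
    stop("the wild-type reference must be a Responsive strain")
  p <- modifyList(list(wtFold = 2, class1Baseline = 3, class1EffectSd = 3,
                       hsEffectSd = 3, baseLogMean = log(50), baseLogSd = 0.3,
                       background = 5, ratioMean = 1, ratioSd = 0.2,
                       intMean = 10, intSd = 2), effectParams)
  .withSeed(seed, {
    pre <- post <- validation <- vector("list", nStrains)
    names(pre) <- names(post) <- names(validation) <- ids
    wtRatio30 <- rnorm(validationCells, p$ratioMean, p$ratioSd)
    for (i in seq_len(nStrains)) {
      cls <- classAssignments[[i]]
      muPre <- p$baseLogMean +
        if (cls == "Class1") log(p$class1Baseline) else 0
      muPost <- muPre +
        if (cls == "Responsive") log(p$wtFold) else 0
      pre[[i]] <- p$background +
        rlnorm(cellsPerStrain, meanlog = muPre, sdlog = p$baseLogSd)
      post[[i]] <- p$background +
        rlnorm(cellsPerStrain, meanlog = muPost, sdlog = p$baseLogSd)
      ratioMu <- p$ratioMean +
        if (cls == "Class1") p$class1EffectSd * p$ratioSd else 0
      intPostMu <- p$intMean +
        if (cls == "Class2") 0 else p$hsEffectSd * p$intSd
      validation[[i]] <- list(
        ratio30 = rnorm(validationCells, ratioMu, p$ratioSd),
        pre = rnorm(validationCells, p$intMean, p$intSd),
        post = rnorm(validationCells, intPostMu, p$intSd))
    }
    bg <- p$background + rnorm(cellsPerStrain, 0, 0.02 * p$background)
    bg[bg < 0] <- 0
    new("ScreenDataset", strainIds = ids, preEvents = pre, postEvents = post,
        validation = validation, wtRatio30 = wtRatio30, backgroundEvents = bg,
        wtId = wtId,
        truth = new("GroundTruth",
                    trueClass = structure(as.character(classAssignments),
                                          names = ids)))
  })
}
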