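# Genome-wide screen hit calling and imaging-validation classification.
#
# The flow stage calls candidate strains whose background-subtracted
# populational reporter mean increases less than 1.1-fold after heat
# shock. The imaging stage classifies strains from per-cell measurements:
# Class 1 strains show significantly greater reporter/marker ratio than
# wild type at 30C (p < alpha with a greater mean), Class 2 strains show
# no significant reporter increase after heat shock (p > alpha, or a
# non-increasing mean), and remaining strains are Responsive. Class 1 is
# evaluated first; the two classes are disjoint per strain. P-values are
# per-strain without multiple-testing correction, matching the screen's
# per-strain p < 0.01 rule (a Benjamini-Hochberg option is available).

#' Welch's unequal-variance t-test
#'
#' Two-sided Welch statistic with Satterthwaite degrees of freedom. When
#' both samples are constant the test is degenerate: equal constants give
#' t = 0, p = 1 by convention; unequal constants give p = 0.
#'
#' @param x,y numeric samples, each with at least two values.
#' @return list with `t`, `df`, `p`.
#' @examples
#' welchT(c(1, 2, 3), c(2, 3, 4))
#' @export
welchT <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs at least 2 values")
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = NA_real_, p = 1))
    return(list(t = sign(mean(x) - mean(y)) * Inf, df = NA_real_, p = 0))
  }
  tt <- t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Call candidate strains by background-subtracted fold change
#'
#' For each strain, `fold_change = (post - background) / (pre -
#' background)`; candidates are strains with `fold_change < cutoff`.
#' Strains whose background-subtracted 30C mean is not positive are
#' flagged invalid and are never candidates.
#'
#' @param records data.frame with columns `strain_id`, `pre_mean`,
#'   `post_mean` (populational reporter means at 30C and after heat
#'   shock).
#' @param background background intensity measured from designated
#'   reporter-free control wells (scalar); required.
#' @param cutoff fold-change cutoff (default 1.1).
#' @return the records with added columns `fold_change`, `candidate`,
#'   `invalid`.
#' @examples
#' r <- data.frame(strain_id = c("a", "b"), pre_mean = c(50, 40),
#'                 post_mean = c(70, 42))
#' callCandidates(r, background = 10)
#' @export
callCandidates <- function(records, background, cutoff = 1.1) {
  stopifnot(is.data.frame(records),
            all(c("strain_id", "pre_mean", "post_mean") %in% names(records)))
  if (missing(background) || is.null(background) || !is.finite(background))
    stop("'background' (from designated control wells) is required")
  denom <- records$pre_mean - background
  records$fold_change <- ifelse(denom > 0,
                                (records$post_mean - background) / denom,
                                NA_real_)
  records$invalid <- denom <= 0
  records$candidate <- !records$invalid & records$fold_change < cutoff
  records
}

#' Classify a validated mutant from per-cell imaging measurements
#'
#' @param v list of per-cell samples: `ko30` and `wt30`
#'   (reporter/marker ratios of the mutant and the wild-type reference at
#'   30C) and `pre`, `post` (mutant reporter intensities before/after
#'   heat shock). Each needs at least two cells.
#' @param alpha per-strain significance level (default 0.01).
#' @param test "welch" (default) or "wilcoxon" for the rank-sum
#'   alternative.
#' @return character label: "Class1" (elevated 30C signal), "Class2" (no
#'   heat-shock increase) or "Responsive", plus attributes `p30`
#'   and `pHS` with the two p-values.
#' @export
classifyMutant <- function(v, alpha = 0.01, test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  for (nm in c("ko30", "wt30", "pre", "post")) {
    if (is.null(v[[nm]]))
      stop(sprintf("sample '%s' is missing", nm))
    if (length(v[[nm]]) < 2L)
      stop(sprintf("sample '%s' needs at least 2 cells", nm))
  }
  pOf <- function(x, y) {
    if (test == "welch") welchT(x, y)$p
    else stats::wilcox.test(x, y, exact = FALSE)$p.value
  }
  p30 <- pOf(v$ko30, v$wt30)
  pHS <- pOf(v$pre, v$post)
  label <- if (p30 < alpha && mean(v$ko30) > mean(v$wt30)) "Class1"
  else if (pHS > alpha || mean(v$post) <= mean(v$pre)) "Class2"
  else "Responsive"
  structure(label, p30 = p30, pHS = pHS)
}

#' Relabel excluded strains
#'
#' Strains on the exclusion list (e.g. genes of known mitochondrial
#' import pathways) are relabelled "Excluded" regardless of their test
#' outcome. Listed strains absent from `labels` are ignored with a
#' warning.
#'
#' @param labels named character vector of class labels.
#' @param exclusionList character vector of strain ids to exclude.
#' @return the relabelled vector.
#' @export
applyExclusions <- function(labels, exclusionList) {
  if (length(exclusionList) == 0L) return(labels)
  missing <- setdiff(exclusionList, names(labels))
  if (length(missing))
    warning(sprintf("exclusion list strains not in labels: %s",
                    paste(missing, collapse = ", ")))
  hit <- intersect(exclusionList, names(labels))
  labels[hit] <- "Excluded"
  labels
}

#' Count validated hits by phenotype class
#'
#' Reads a hits table (columns `systematic_name`, `standard_name`,
#' `magic_phenotype`) and counts strains per phenotype label. Duplicated
#' systematic names are an error. The table of validated regulators
#' shipped with the package is used when `hits` is omitted.
#'
#' @param hits path to a CSV file, or a data.frame.
#' @return named integer vector of counts per phenotype.
#' @examples
#' countByClass()
#' @export
countByClass <- function(hits = system.file("extdata", "table1_hits.csv",
                                            package = "mitoSpGFP")) {
  tab <- if (is.data.frame(hits)) hits else
    read.csv(hits, stringsAsFactors = FALSE)
  need <- c("systematic_name", "standard_name", "magic_phenotype")
  if (!all(need %in% names(tab)))
    stop(sprintf("hits table must have columns: %s",
                 paste(need, collapse = ", ")))
  if (nrow(tab) == 0L) return(integer(0))
  dup <- tab$systematic_name[duplicated(tab$systematic_name)]
  if (length(dup))
    stop(sprintf("duplicated systematic name(s): %s",
                 paste(unique(dup), collapse = ", ")))
  cnt <- table(tab$magic_phenotype)
  structure(as.integer(cnt), names = names(cnt))
}

#' Run candidate calling and classification over a screen dataset
#'
#' End-to-end screen analysis of a \linkS4class{ScreenDataset}:
#' populational means of the per-strain 30C and heat-shock event samples
#' are computed with \code{\link{populationStats}}, candidates are called
#' against the reporter-free background wells with
#' \code{\link{callCandidates}}, candidate strains are classified from
#' their imaging-validation samples with \code{\link{classifyMutant}},
#' and non-candidates are labelled "Responsive".
#'
#' @param ds a \linkS4class{ScreenDataset}.
#' @param cutoff fold-change cutoff (default 1.1).
#' @param alpha per-strain significance level (default 0.01).
#' @param exclusionList optional strain ids to relabel "Excluded".
#' @param minEvents low-count flag threshold for the flow stage.
#' @return data.frame per strain: strain_id, pre_mean, post_mean,
#'   fold_change, invalid, candidate, p30, pHS, label, true_class.
#' @export
classifyScreen <- function(ds, cutoff = 1.1, alpha = 0.01,
                           exclusionList = character(),
                           minEvents = 25000L) {
  stopifnot(is(ds, "ScreenDataset"))
  ids <- ds@strainIds
  preM <- vapply(ids, function(id)
    populationStats(FlowSample(data.frame(spgfp = ds@preEvents[[id]]),
                               sampleId = id),
                    "spgfp", minEvents = minEvents)$mean, numeric(1))
  postM <- vapply(ids, function(id)
    populationStats(FlowSample(data.frame(spgfp = ds@postEvents[[id]]),
                               sampleId = id),
                    "spgfp", minEvents = minEvents)$mean, numeric(1))
  rec <- data.frame(strain_id = ids, pre_mean = preM, post_mean = postM,
                    stringsAsFactors = FALSE, row.names = NULL)
  rec <- callCandidates(rec, background = mean(ds@backgroundEvents),
                        cutoff = cutoff)
  rec$p30 <- rec$pHS <- NA_real_
  rec$label <- "Responsive"
  for (k in which(rec$candidate)) {
    id <- rec$strain_id[k]
    val <- ds@validation[[id]]
    lab <- classifyMutant(list(ko30 = val$ratio30, wt30 = ds@wtRatio30,
                               pre = val$pre, post = val$post),
                          alpha = alpha)
    rec$label[k] <- as.character(lab)
    rec$p30[k] <- attr(lab, "p30")
    rec$pHS[k] <- attr(lab, "pHS")
  }
  labs <- structure(rec$label, names = rec$strain_id)
  labs <- applyExclusions(labs, exclusionList)
  rec$label <- unname(labs)
  tc <- ds@truth@trueClass
  rec$true_class <- if (length(tc)) unname(tc[rec$strain_id]) else NA_character_
  rec
}

#' Benjamini-Hochberg adjustment of screen p-values
#'
#' Optional FDR control across strains; off by default in
#' \code{\link{classifyScreen}} to match the per-strain p < alpha rule.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values.
#' @export
adjustScreenP <- function(p) stats::p.adjust(p, method = "BH")
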