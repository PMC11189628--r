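# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random stream set to `seed`, then restores
#' the caller's stream so that generator calls do not perturb surrounding
#' randomness.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
.withSeed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Stable per-item sub-seed so that adding items to a field does not
# reshuffle the draws of earlier items. Kept below 2^31 - 1.
.subSeed <- function(seed, key) {
  as.integer(((as.numeric(seed) %% 1000003) * 2011 + 7 * key) %% 2147483647)
}

# Disc-shaped structuring element of given pixel radius.
.discBrush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

# Coerce an EBImage result back to a plain matrix.
.asMat <- function(x) {
  m <- EBImage::imageData(x)
  dim(m) <- dim(m)[1:2]
  m
}

# Join qc flag names into the single comma-separated field used in the
# per-cell output tables.
.joinFlags <- function(flags) {
  if (length(flags) == 0L) "" else paste(flags, collapse = ",")
}
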