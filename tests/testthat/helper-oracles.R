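# Independent brute-force oracles used to validate the vectorised
# implementations, plus small shared helpers.

# elementwise triple-loop sum projection
loopSumProject <- function(a) {
  d <- dim(a)
  out <- matrix(0, d[2], d[3])
  for (y in seq_len(d[2]))
    for (x in seq_len(d[3]))
      for (z in seq_len(d[1]))
        out[y, x] <- out[y, x] + a[z, y, x]
  out
}

# per-pixel loop version of fraction-of-maximum masking
loopMitoMask <- function(mch, cellMask, fraction) {
  mx <- -Inf
  for (k in which(cellMask)) mx <- max(mx, mch[k])
  out <- matrix(FALSE, nrow(mch), ncol(mch))
  for (k in which(cellMask)) if (mch[k] >= fraction * mx) out[k] <- TRUE
  out
}

# sort-based median (even counts: midpoint of the two central values)
sortMedian <- function(v) {
  s <- sort(v)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# accumulation-loop mean
loopMean <- function(v) {
  acc <- 0
  for (x in v) acc <- acc + x
  acc / length(v)
}

# two-sided permutation p-value for a difference in means
permutationP <- function(x, y, B = 20000L) {
  pool <- c(x, y)
  n1 <- length(x)
  obs <- abs(mean(x) - mean(y))
  hits <- 0L
  for (b in seq_len(B)) {
    s <- sample(length(pool), n1)
    if (abs(mean(pool[s]) - mean(pool[-s])) >= obs - 1e-12) hits <- hits + 1L
  }
  hits / B
}

# naive exhaustive Otsu: double loop over candidate thresholds
bruteOtsu <- function(v) {
  u <- sort(unique(v))
  best <- NA_real_
  bestB <- -Inf
  for (t in u[-length(u)]) {
    a <- v[v <= t]
    b <- v[v > t]
    bcv <- (length(a) / length(v)) * (length(b) / length(v)) *
      (mean(a) - mean(b))^2
    if (bcv > bestB + 1e-12) { bestB <- bcv; best <- t }
  }
  best
}

# exhaustive nearest-rank gate threshold: smallest observed value with a
# strict-positive fraction below the bound
bruteGate <- function(v, maxPositive) {
  for (u in sort(unique(v)))
    if (mean(v > u) < maxPositive) return(u)
  stop("unreachable")
}

# multi-source BFS (uniform cost, 4-connectivity, equidistant ties to the
# smaller label) -- the geodesic nearest-marker oracle
bfsLabels <- function(mask, markers) {
  ny <- nrow(mask); nx <- ncol(mask)
  dist <- matrix(Inf, ny, nx)
  lab <- matrix(0L, ny, nx)
  queue <- list()
  for (k in seq_len(nrow(markers))) {
    y <- markers[k, 1]; x <- markers[k, 2]
    dist[y, x] <- 0; lab[y, x] <- k
    queue[[length(queue) + 1L]] <- c(y, x)
  }
  dy <- c(-1, 1, 0, 0); dx <- c(0, 0, -1, 1)
  head <- 1L
  while (head <= length(queue)) {
    p <- queue[[head]]; head <- head + 1L
    for (m in 1:4) {
      y <- p[1] + dy[m]; x <- p[2] + dx[m]
      if (y < 1 || y > ny || x < 1 || x > nx || !mask[y, x]) next
      nd <- dist[p[1], p[2]] + 1
      if (nd < dist[y, x]) {
        dist[y, x] <- nd
        lab[y, x] <- lab[p[1], p[2]]
        queue[[length(queue) + 1L]] <- c(y, x)
      } else if (nd == dist[y, x] && lab[p[1], p[2]] < lab[y, x]) {
        # a smaller label reached this pixel along an equally short path;
        # adopt it and let it cascade
        lab[y, x] <- lab[p[1], p[2]]
        queue[[length(queue) + 1L]] <- c(y, x)
      }
    }
  }
  lab * (mask & is.finite(dist))
}

# intersection over union of two masks
iou <- function(a, b) sum(a & b) / sum(a | b)

# per-label IoU of a recovered labelling against ground-truth cell masks
labelIoUs <- function(lab, truthMasks) {
  vapply(seq_len(max(lab, 0L)), function(i) {
    tl <- truthMasks[lab == i]
    tl <- tl[tl > 0]
    if (!length(tl)) return(0)
    t <- as.integer(names(sort(table(tl), decreasing = TRUE))[1])
    iou(lab == i, truthMasks == t)
  }, numeric(1))
}

# small synthetic field shared by imaging tests
smallField <- function(seed = 5L, nCells = 6L, noiseSd = 0, shot = FALSE,
                       side = 160L) {
  generateImageField(synthImageSpec(fieldShape = c(4L, side, side),
                                    nCells = nCells, noiseSd = noiseSd,
                                    shotNoise = shot, seed = seed))
}
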