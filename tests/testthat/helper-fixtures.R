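# Fixtures are built in code: tiny deterministic images, random rasters and
# independent brute-force oracles used across the test files.

# image whose pixels are given as a list of (R,G,B) triples filling row-major
makeImage <- function(triples, h, w, ...) {
  px <- array(0L, dim = c(h, w, 3L))
  m <- do.call(rbind, triples)
  for (ch in 1:3) px[, , ch] <- matrix(as.integer(m[, ch]), h, w, byrow = TRUE)
  CanopyImage(px, ...)
}

uniformImage <- function(rgb, h = 2L, w = 2L, ...) {
  makeImage(rep(list(rgb), h * w), h, w, ...)
}

randomImage <- function(h, w, seed = 1L, lo = 0L, hi = 255L, ...) {
  set.seed(seed)
  px <- array(sample(lo:hi, h * w * 3L, replace = TRUE), dim = c(h, w, 3L))
  CanopyImage(px, ...)
}

# ---- brute-force oracles (independent of the implementation path) ----------

# per-pixel loop evaluation of one color index
oracleIndex <- function(image, name) {
  px <- pixelData(image)
  h <- dim(px)[1]; w <- dim(px)[2]
  vals <- matrix(NA_real_, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    R <- as.numeric(px[i, j, 1]); G <- as.numeric(px[i, j, 2])
    B <- as.numeric(px[i, j, 3]); S <- R + G + B
    vals[i, j] <- switch(name,
      GR = if (R > 0) G / R else NA_real_,
      GB = if (B > 0) G / B else NA_real_,
      NRI = if (S > 0) R / S else NA_real_,
      NGI = if (S > 0) G / S else NA_real_,
      NBI = if (S > 0) B / S else NA_real_,
      GMRN = if (S > 0) (G - R) / S else NA_real_)
  }
  vals
}

# counting-loop histogram over [lo, hi] with right-open bins (last closed)
oracleHistogram <- function(values, lo, hi, nBins) {
  counts <- numeric(nBins)
  width <- (hi - lo) / nBins
  for (v in values) {
    k <- floor((v - lo) / width) + 1
    if (k < 1) k <- 1
    if (k > nBins) k <- nBins
    counts[k] <- counts[k] + 1
  }
  100 * counts / length(values)
}

oracleMaskedMean <- function(values, sel) {
  tot <- 0; n <- 0
  for (i in seq_along(values)) {
    if (sel[i]) { tot <- tot + values[i]; n <- n + 1 }
  }
  tot / n
}

oraclePearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}

oracleRmse <- function(y, yhat) {
  s <- 0
  for (i in seq_along(y)) s <- s + (y[i] - yhat[i])^2
  sqrt(s / length(y))
}

oracleMape <- function(y, yhat) {
  s <- 0
  for (i in seq_along(y)) s <- s + abs(y[i] - yhat[i]) / abs(y[i])
  100 * s / length(y)
}

oracleCv <- function(v) {
  n <- length(v)
  m <- sum(v) / n
  100 * sqrt(sum((v - m)^2) / (n - 1)) / m
}

# per-sample forward pass of a 1-hidden-layer net, scalar arithmetic only
oracleForward <- function(X, W1, b1, W2, b2) {
  out <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    acc <- b2
    for (j in seq_len(nrow(W1))) {
      z <- b1[j]
      for (k in seq_len(ncol(W1))) z <- z + W1[j, k] * X[i, k]
      acc <- acc + W2[j] / (1 + exp(-z))
    }
    out[i] <- acc
  }
  out
}

# small cohort for protocol tests (fast but non-trivial)
smallCohort <- function(seed = 1L, stagePreset = "reviving") {
  generateCohort(scenarioConfig(
    stagePreset = stagePreset, seed = seed,
    cultivars = c("cvA", "cvB", "cvC"),
    nLevels = c(0, 120, 240), replicates = 2L,
    imageSize = c(64L, 64L)))
}

# shared heavy computation for the acceptance checks: 10-seed medians of the
# comparison protocol under a scenario; memoised per test run
.cmpCache <- new.env(parent = emptyenv())
comparisonMedians <- function(stagePreset, seeds = 1:10) {
  key <- paste(stagePreset, paste(seeds, collapse = ","))
  if (!is.null(.cmpCache[[key]])) return(.cmpCache[[key]])
  rows <- list()
  for (s in seeds) {
    co <- generateCohort(scenarioConfig(stagePreset = stagePreset, seed = s))
    err <- reportErrors(runComparison(co$samples, co$images, seed = s))
    err$seed <- s
    rows[[length(rows) + 1L]] <- err
  }
  df <- do.call(rbind, rows)
  .cmpCache[[key]] <- df
  df
}
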