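#' @include color-index.R
NULL

# Otsu threshold over the valid values of an index raster. Works on a fixed
# 256-level histogram of the theoretical range; when the between-class
# variance plateaus (perfectly separated two-value data) the middle of the
# plateau is taken, which places the cut between the two populations.
.otsuThreshold <- function(values, range, levels = 256L) {
  lo <- range[1]; width <- diff(range) / levels
  idx <- floor((values - lo) / width) + 1
  idx[idx < 1L] <- 1L; idx[idx > levels] <- levels
  counts <- tabulate(idx, nbins = levels)
  w <- counts / sum(counts)
  mids <- lo + (seq_len(levels) - 0.5) * width
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  muT <- mu[levels]
  k <- seq_len(levels - 1L)
  denom <- omega[k] * (1 - omega[k])
  sigma <- (muT * omega[k] - mu[k])^2 / denom
  sigma[denom <= 0] <- -Inf
  best <- which(sigma >= max(sigma) - 1e-15)
  kStar <- best[ceiling(length(best) / 2)]
  lo + kStar * width
}

#' Segment a canopy image into vegetation and soil
#'
#' Thresholds the normalized green-minus-red index (GMRN), the package's
#' vegetation-highlighting index: pixels above the threshold are vegetation.
#' By default the threshold is chosen by Otsu's bimodal split over the valid
#' GMRN values; a fixed threshold can be supplied instead.
#'
#' @param image a \linkS4class{CanopyImage}.
#' @param threshold optional fixed GMRN threshold overriding the Otsu choice.
#' @return A \linkS4class{VegetationMask}; its mask is \code{NA} at pixels
#'   where GMRN is undefined.
#' @export
segmentVegetation <- function(image, threshold = NULL) {
  gm <- computeIndex(image, "GMRN")
  valid <- gm@validMask
  if (!any(valid))
    stopf("cannot segment '%s': no valid pixels under GMRN", image@sampleId)
  if (is.null(threshold))
    threshold <- .otsuThreshold(gm@values[valid], gm@theoreticalRange)
  mask <- gm@values > threshold
  mask[!valid] <- NA
  cov <- sum(mask, na.rm = TRUE) / sum(valid)
  new("VegetationMask", mask = mask, coverage = cov, threshold = threshold)
}

#' Index-image mean value (IIMV)
#'
#' Arithmetic mean of an index raster over the vegetation component — the
#' traditional single-number feature. When the vegetation mask intersects no
#' valid pixel the mean falls back to all valid pixels (reported via a
#' message); with \code{mask = NULL} the mean is over all valid pixels.
#'
#' @param raster an \linkS4class{IndexRaster}.
#' @param mask a \linkS4class{VegetationMask}, a logical matrix, or
#'   \code{NULL}.
#' @return The mean index value (scalar).
#' @export
iimv <- function(raster, mask = NULL) {
  stopifnot(is(raster, "IndexRaster"))
  valid <- raster@validMask
  if (!any(valid)) stopf("IIMV undefined: raster has no valid pixels")
  if (is(mask, "VegetationMask")) mask <- mask@mask
  if (is.null(mask)) {
    sel <- valid
  } else {
    if (!identical(dim(mask), dim(valid)))
      stopf("mask dimensions do not match the raster")
    sel <- valid & !is.na(mask) & mask
    if (!any(sel)) {
      message("IIMV: empty vegetation mask, falling back to all valid pixels")
      sel <- valid
    }
  }
  mean(raster@values[sel])
}

#' Index-image histogram
#'
#' Percentage-per-bin histogram of an index raster over equal-width bins
#' spanning the index's fixed theoretical range. Bins are right-open except
#' the last, which is closed; values outside the range (possible only for the
#' clipped ratio indices G/R and G/B) land in the end bins. Counts are taken
#' over valid pixels only and normalized to percentages.
#'
#' @param raster an \linkS4class{IndexRaster}.
#' @param nBins number of bins (default 256).
#' @return A \linkS4class{HistogramFeature} (peaks not yet detected).
#' @export
indexHistogram <- function(raster, nBins = 256L) {
  stopifnot(is(raster, "IndexRaster"))
  nBins <- as.integer(nBins)
  if (nBins < 2L) stopf("nBins must be at least 2")
  v <- raster@values[raster@validMask]
  if (!length(v)) stopf("histogram undefined: no valid pixels")
  rng <- raster@theoreticalRange
  width <- diff(rng) / nBins
  idx <- floor((v - rng[1]) / width) + 1
  idx[idx < 1L] <- 1L
  idx[idx > nBins] <- nBins
  counts <- tabulate(idx, nbins = nBins)
  new("HistogramFeature", indexName = raster@indexName,
      binEdges = seq(rng[1], rng[2], length.out = nBins + 1L),
      percentages = 100 * counts / length(v))
}

.movingAverage <- function(x, window) {
  k <- (window - 1L) %/% 2L
  if (k == 0L) return(x)
  padded <- c(rep(x[1], k), x, rep(x[length(x)], k))
  as.numeric(stats::filter(padded, rep(1 / window, window), sides = 2))[
    (k + 1L):(k + length(x))]
}

#' Detect the soil and vegetation peaks of an index histogram
#'
#' Smooths the histogram by a centered moving average (edges padded by
#' replication), finds local maxima, and keeps the two tallest maxima at
#' least \code{minSeparation} bins apart: the left one is peak a (soil), the
#' right one peak b (vegetation/crop). If only one maximum exists it is
#' assigned by position relative to the range midpoint; a flat histogram
#' yields no peaks and sets the \code{flat} flag.
#'
#' @param hist a \linkS4class{HistogramFeature}.
#' @param smoothWindow odd moving-average window in bins (default 5).
#' @param minSeparation minimum peak separation in bins (default 20).
#' @return The histogram with \code{smoothed}, \code{peakA}, \code{peakB}
#'   and \code{flat} filled in.
#' @export
detectPeaks <- function(hist, smoothWindow = 5L, minSeparation = 20L) {
  stopifnot(is(hist, "HistogramFeature"))
  smoothWindow <- as.integer(smoothWindow)
  if (smoothWindow < 1L || smoothWindow %% 2L == 0L)
    stopf("smoothWindow must be a positive odd integer")
  p <- hist@percentages
  n <- length(p)
  s <- .movingAverage(p, smoothWindow)
  hist@smoothed <- s
  if (all(abs(p - p[1]) < 1e-12)) {
    hist@flat <- TRUE
    hist@peakA <- NA_integer_
    hist@peakB <- NA_integer_
    return(hist)
  }
  left <- c(-Inf, s[-n]); right <- c(s[-1], -Inf)
  maxima <- which(s > left & s >= right & s > 0)  # empty plateaus are not peaks
  if (!length(maxima)) {           # monotone after smoothing: take argmax
    maxima <- which.max(s)
  }
  ord <- maxima[order(-s[maxima], maxima)]
  primary <- ord[1]
  rest <- ord[-1]
  secondary <- rest[abs(rest - primary) >= minSeparation]
  if (length(secondary)) {
    pair <- sort(c(primary, secondary[1]))
    hist@peakA <- as.integer(pair[1])
    hist@peakB <- as.integer(pair[2])
  } else {
    if (primary > n / 2) hist@peakB <- as.integer(primary)
    else hist@peakA <- as.integer(primary)
  }
  hist
}

#' Per-bin Pearson correlation of histogram percentages with a target
#'
#' For each histogram bin, the Pearson correlation across samples between
#' that bin's percentage and the diagnosis target (leaf N content or yield).
#' Bins whose percentage is constant across samples get r = 0 by convention.
#'
#' @param histMatrix numeric matrix, samples x bins (as from
#'   \code{\link{histogramMatrix}}).
#' @param target numeric vector of per-sample target values.
#' @return Numeric vector of per-bin correlations in [-1, 1].
#' @export
binCorrelations <- function(histMatrix, target) {
  histMatrix <- as.matrix(histMatrix)
  if (nrow(histMatrix) != length(target))
    stopf("target length must match the number of samples")
  if (nrow(histMatrix) < 3L)
    stopf("at least 3 samples are required for bin correlations")
  if (!all(is.finite(histMatrix)) || !all(is.finite(target)))
    stopf("histogram matrix and target must be finite")
  if (stats::var(target) == 0)
    stopf("target has zero variance")
  r <- suppressWarnings(as.numeric(stats::cor(histMatrix, target)))
  r[is.na(r)] <- 0
  r
}

#' Stack per-sample histograms of one index into a matrix
#'
#' @param samples sample table (see \code{\link{readSampleTable}}).
#' @param images named list of \linkS4class{CanopyImage} keyed by sample id;
#'   images absent from the list are read from \code{image_path}.
#' @param indexName which color index to histogram.
#' @param nBins number of bins.
#' @return samples x nBins matrix of percentages, rownames = sample ids.
#' @export
histogramMatrix <- function(samples, images = NULL, indexName = "GMRN",
                            nBins = 256L) {
  imgs <- .resolveImages(samples, images)
  rows <- lapply(imgs, function(im)
    percentages(indexHistogram(computeIndex(im, indexName), nBins)))
  m <- do.call(rbind, rows)
  rownames(m) <- samples$sample_id
  colnames(m) <- sprintf("%s_bin%03d", indexName, seq_len(ncol(m)))
  m
}

#' Select informative histogram bins
#'
#' Default policy \code{"peak_window_corr"}: take the window of
#' \code{window} bins centered on peak b of the template histogram (the
#' cohort-mean histogram of the training samples) and keep bins whose
#' absolute correlation with the target reaches \code{rMin}; when fewer than
#' \code{kMin} survive, fall back to the \code{kMin} largest-|r| bins inside
#' the window. Policy \code{"global_corr"}: the \code{kMin} largest-|r| bins
#' anywhere.
#'
#' @param correlations per-bin Pearson r (from \code{\link{binCorrelations}}).
#' @param template a peak-annotated \linkS4class{HistogramFeature}
#'   (\code{\link{detectPeaks}} output on the cohort-mean histogram).
#' @param targetName \code{"leaf_n"} or \code{"yield"}.
#' @param policy selection policy.
#' @param window window width in bins, centered on peak b.
#' @param rMin correlation threshold.
#' @param kMin minimum number of selected bins.
#' @return A \linkS4class{BinSelection}.
#' @export
selectRegion <- function(correlations, template, targetName = "leaf_n",
                         policy = c("peak_window_corr", "global_corr"),
                         window = 41L, rMin = 0.5, kMin = 8L) {
  policy <- match.arg(policy)
  stopifnot(is(template, "HistogramFeature"))
  n <- length(correlations)
  if (n != length(template@percentages))
    stopf("correlations do not match the template's bin count")
  kMin <- as.integer(kMin)
  if (policy == "peak_window_corr") {
    pb <- template@peakB
    if (is.na(pb))
      stopf(paste("no vegetation peak detected on the template histogram;",
                  "consider policy = 'global_corr'"))
    h <- (as.integer(window) - 1L) %/% 2L
    win <- max(1L, pb - h):min(n, pb + h)
    keep <- win[abs(correlations[win]) >= rMin]
    if (length(keep) < min(kMin, length(win))) {
      ord <- win[order(-abs(correlations[win]), win)]
      keep <- ord[seq_len(min(kMin, length(win)))]
    }
  } else {
    ord <- order(-abs(correlations), seq_len(n))
    keep <- ord[seq_len(min(kMin, n))]
  }
  keep <- sort(unique(as.integer(keep)))
  new("BinSelection", indexName = template@indexName,
      binIndices = keep, correlations = correlations[keep],
      targetName = targetName, binEdges = template@binEdges,
      policy = policy,
      params = list(window = as.integer(window), rMin = rMin, kMin = kMin,
                    peakA = template@peakA, peakB = template@peakB))
}

.resolveImages <- function(samples, images) {
  out <- vector("list", nrow(samples))
  names(out) <- samples$sample_id
  missing <- character(0)
  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    if (!is.null(images) && !is.null(images[[sid]])) {
      out[[sid]] <- images[[sid]]
    } else if (!is.na(samples$image_path[i]) &&
               nzchar(samples$image_path[i]) &&
               file.exists(samples$image_path[i])) {
      out[[sid]] <- readCanopyImage(samples$image_path[i], sampleId = sid,
                                    cultivar = samples$cultivar[i],
                                    stage = samples$stage[i],
                                    nLevel = samples$n_level[i])
    } else {
      missing <- c(missing, sid)
    }
  }
  if (length(missing))
    stopf("missing images for samples: %s", paste(missing, collapse = ", "))
  out
}

#' Build the model design matrix for one feature family
#'
#' Mode \code{"IIMV"}: one column per color index in \code{indexSet}, the
#' mean of that index over the vegetation component of each image. Mode
#' \code{"IIH"}: one column per selected histogram bin (percentages) of the
#' selection's index. Rows follow the sample table.
#'
#' @param samples sample table (see \code{\link{readSampleTable}}).
#' @param images named list of \linkS4class{CanopyImage} (missing entries are
#'   read from \code{image_path}).
#' @param mode \code{"IIMV"} or \code{"IIH"}.
#' @param selection a \linkS4class{BinSelection}; required for IIH, ignored
#'   for IIMV.
#' @param indexSet color indices used in IIMV mode.
#' @param useVegetationMask in IIMV mode, average over the segmented
#'   vegetation component (\code{TRUE}, default) or over the whole frame.
#' @param nBins histogram bin count for IIH (must match the selection).
#' @return A \linkS4class{FeatureMatrix}.
#' @export
buildFeatureMatrix <- function(samples, images = NULL,
                               mode = c("IIMV", "IIH"), selection = NULL,
                               indexSet = colorIndexNames(),
                               useVegetationMask = TRUE, nBins = 256L) {
  mode <- match.arg(mode)
  imgs <- .resolveImages(samples, images)
  if (mode == "IIMV") {
    rows <- lapply(imgs, function(im) {
      mask <- if (useVegetationMask) segmentVegetation(im) else NULL
      vapply(indexSet, function(nm) iimv(computeIndex(im, nm), mask),
             numeric(1))
    })
    v <- do.call(rbind, rows)
    colnames(v) <- paste0("iimv_", indexSet)
    recipe <- list(indexSet = indexSet, useVegetationMask = useVegetationMask)
  } else {
    if (!is(selection, "BinSelection"))
      stopf("IIH mode requires a BinSelection")
    nBins <- length(selection@binEdges) - 1L
    rows <- lapply(imgs, function(im) {
      h <- indexHistogram(computeIndex(im, selection@indexName), nBins)
      percentages(h)[selection@binIndices]
    })
    v <- do.call(rbind, rows)
    colnames(v) <- sprintf("%s_bin%03d", selection@indexName,
                           selection@binIndices)
    recipe <- list(selection = selection)
  }
  rownames(v) <- samples$sample_id
  new("FeatureMatrix", values = v,
      targets = data.frame(leaf_n = samples$leaf_n, yield = samples$yield),
      mode = mode, recipe = recipe)
}

#' Serialize a bin selection to a JSON sidecar
#'
#' Stores the index name, bin edges, selected indices, correlations, policy
#' and parameters so a trained model can be reapplied bit-exactly.
#'
#' @param selection a \linkS4class{BinSelection}.
#' @param path output .json path.
#' @return The path, invisibly.
#' @export
writeBinSelection <- function(selection, path) {
  stopifnot(is(selection, "BinSelection"))
  obj <- list(indexName = selection@indexName,
              binIndices = selection@binIndices,
              correlations = selection@correlations,
              targetName = selection@targetName,
              binEdges = selection@binEdges,
              policy = selection@policy,
              params = selection@params)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

#' Read a bin selection written by \code{\link{writeBinSelection}}
#' @param path .json path.
#' @return A \linkS4class{BinSelection}.
#' @export
readBinSelection <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pk <- function(x) if (is.null(x)) NA_integer_ else as.integer(x)
  new("BinSelection", indexName = obj$indexName,
      binIndices = as.integer(obj$binIndices),
      correlations = as.numeric(obj$correlations),
      targetName = obj$targetName, binEdges = as.numeric(obj$binEdges),
      policy = obj$policy,
      params = list(window = as.integer(obj$params$window),
                    rMin = as.numeric(obj$params$rMin),
                    kMin = as.integer(obj$params$kMin),
                    peakA = pk(obj$params$peakA), peakB = pk(obj$params$peakB)))
}
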