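#' @import methods
NULL

.STAGES <- c("reviving", "jointing")
.INDEX_NAMES <- c("GR", "GB", "NRI", "NGI", "NBI", "GMRN")

#' CanopyImage: an 8-bit RGB canopy photograph with sample metadata
#'
#' Container for a nadir canopy photograph. Pixel values are stored as an
#' integer array of dimension \code{height x width x 3} (R, G, B planes) with
#' values in \code{[0, 255]}; coordinates are row-major with origin at the
#' top-left, as in a plain photograph.
#'
#' @slot pixels integer array \code{h x w x 3}, values in 0..255.
#' @slot sampleId character scalar identifying the sample.
#' @slot cultivar character scalar (may be \code{NA}).
#' @slot stage growth stage, one of \code{"reviving"} or \code{"jointing"}
#'   (or \code{NA} when unknown).
#' @slot nLevel nitrogen application rate in kg N/ha (\code{NA} when unknown).
#'
#' @aliases CanopyImage
#' @exportClass CanopyImage
setClass("CanopyImage",
  representation(
    pixels = "array",
    sampleId = "character",
    cultivar = "character",
    stage = "character",
    nLevel = "numeric"
  )
)

setValidity("CanopyImage", function(object) {
  p <- object@pixels
  if (length(dim(p)) != 3L || dim(p)[3] != 3L)
    return("pixels must be an h x w x 3 array")
  if (dim(p)[1] < 1L || dim(p)[2] < 1L)
    return("image must contain at least one pixel")
  if (!is.integer(p))
    return("pixels must be stored as integers")
  if (anyNA(p) || min(p) < 0L || max(p) > 255L)
    return("channel values must lie in [0, 255]")
  if (length(object@sampleId) != 1L)
    return("sampleId must be a single string")
  st <- object@stage
  if (length(st) != 1L || (!is.na(st) && !st %in% .STAGES))
    return(sprintf("stage must be one of %s or NA",
                   paste(.STAGES, collapse = ", ")))
  if (length(object@nLevel) != 1L || (!is.na(object@nLevel) && object@nLevel < 0))
    return("nLevel must be a single nonnegative number (or NA)")
  TRUE
})

#' Construct a CanopyImage from a pixel array
#'
#' @param pixels numeric or integer array \code{h x w x 3} with values in
#'   \code{[0, 255]}; non-integer values must already be whole numbers.
#' @param sampleId,cultivar,stage,nLevel sample metadata; see
#'   \linkS4class{CanopyImage}.
#' @return A \linkS4class{CanopyImage}.
#' @examples
#' px <- array(c(100, 150, 50), dim = c(1, 1, 3))
#' CanopyImage(px, sampleId = "s1")
#' @export
CanopyImage <- function(pixels, sampleId = "unnamed", cultivar = NA_character_,
                        stage = NA_character_, nLevel = NA_real_) {
  if (is.double(pixels)) {
    if (anyNA(pixels) || any(abs(pixels - round(pixels)) > 1e-9))
      stop("pixel values must be whole numbers in [0, 255]")
    storage.mode(pixels) <- "integer"
  }
  new("CanopyImage", pixels = pixels, sampleId = as.character(sampleId),
      cultivar = as.character(cultivar), stage = as.character(stage),
      nLevel = as.numeric(nLevel))
}

#' IndexRaster: one color-index image with a validity mask
#'
#' Real-valued raster of a single color index, the same shape as its source
#' image. Pixels where the index denominator is zero are invalid: the mask is
#' \code{FALSE} and the value \code{NA}. \code{theoreticalRange} is the fixed
#' interval used for histogramming (unbounded ratio indices G/R and G/B are
#' assigned \code{[0, 5]}; out-of-range pixels are clipped into the end bins
#' at histogram time, never in the raster itself).
#'
#' @slot values numeric matrix (NA at invalid pixels).
#' @slot validMask logical matrix, \code{TRUE} where the index is defined.
#' @slot indexName one of \code{"GR"}, \code{"GB"}, \code{"NRI"},
#'   \code{"NGI"}, \code{"NBI"}, \code{"GMRN"}.
#' @slot theoreticalRange numeric length-2 closed interval.
#' @aliases IndexRaster
#' @exportClass IndexRaster
setClass("IndexRaster",
  representation(
    values = "matrix",
    validMask = "matrix",
    indexName = "character",
    theoreticalRange = "numeric"
  )
)

setValidity("IndexRaster", function(object) {
  if (!identical(dim(object@values), dim(object@validMask)))
    return("values and validMask must share dimensions")
  if (!is.logical(object@validMask))
    return("validMask must be logical")
  if (!object@indexName %in% .INDEX_NAMES)
    return(sprintf("unknown index name '%s'", object@indexName))
  if (length(object@theoreticalRange) != 2L ||
      diff(object@theoreticalRange) <= 0)
    return("theoreticalRange must be an increasing length-2 interval")
  if (any(is.na(object@values[object@validMask])))
    return("valid pixels must carry finite values")
  if (any(!is.na(object@values[!object@validMask])))
    return("invalid pixels must be NA")
  TRUE
})

#' VegetationMask: soil/vegetation segmentation of a canopy image
#'
#' @slot mask logical matrix; \code{TRUE} on vegetation pixels. \code{NA} on
#'   pixels that are invalid under the segmentation index.
#' @slot coverage fraction of valid pixels flagged vegetation, in [0, 1].
#' @slot threshold the index threshold that produced the mask.
#' @aliases VegetationMask
#' @exportClass VegetationMask
setClass("VegetationMask",
  representation(mask = "matrix", coverage = "numeric", threshold = "numeric")
)

setValidity("VegetationMask", function(object) {
  if (!is.logical(object@mask)) return("mask must be logical")
  nValid <- sum(!is.na(object@mask))
  if (nValid > 0) {
    cov <- sum(object@mask, na.rm = TRUE) / nValid
    if (abs(cov - object@coverage) > 1e-12)
      return("coverage must equal vegetation pixels / valid pixels")
  }
  if (object@coverage < 0 || object@coverage > 1)
    return("coverage must lie in [0, 1]")
  TRUE
})

#' HistogramFeature: normalized index-image histogram with soil/crop peaks
#'
#' Per-bin pixel percentages of an index raster over its fixed theoretical
#' range. Bins are right-open except the last (closed). When peaks have been
#' detected, \code{peakA} is the left (soil) mode and \code{peakB} the right
#' (vegetation) mode, as bin indices; either may be \code{NA}.
#'
#' @slot indexName index the histogram was computed from.
#' @slot binEdges numeric vector of \code{nBins + 1} ascending edges.
#' @slot percentages numeric vector of \code{nBins} nonnegative percentages
#'   summing to 100.
#' @slot smoothed moving-average smoothed percentages (length 0 before peak
#'   detection).
#' @slot peakA,peakB integer bin indices of the soil / vegetation peaks
#'   (\code{NA} when absent).
#' @slot flat \code{TRUE} when the histogram was flat and no peaks exist.
#' @aliases HistogramFeature
#' @exportClass HistogramFeature
setClass("HistogramFeature",
  representation(
    indexName = "character",
    binEdges = "numeric",
    percentages = "numeric",
    smoothed = "numeric",
    peakA = "integer",
    peakB = "integer",
    flat = "logical"
  ),
  prototype(smoothed = numeric(0), peakA = NA_integer_, peakB = NA_integer_,
            flat = FALSE)
)

setValidity("HistogramFeature", function(object) {
  n <- length(object@percentages)
  if (length(object@binEdges) != n + 1L)
    return("binEdges must have one more element than percentages")
  if (any(diff(object@binEdges) <= 0))
    return("binEdges must be strictly ascending")
  if (any(object@percentages < 0))
    return("percentages must be nonnegative")
  if (n > 0 && abs(sum(object@percentages) - 100) > 1e-9)
    return("percentages must sum to 100")
  if (!is.na(object@peakA) && !is.na(object@peakB) &&
      object@peakA >= object@peakB)
    return("peakA must lie left of peakB")
  TRUE
})

#' BinSelection: the histogram-bin recipe used as model input
#'
#' Records which bins of which index histogram feed the diagnosis model,
#' together with the per-bin Pearson correlations that selected them and the
#' exact bin edges, so a trained model can be reapplied bit-exactly.
#'
#' @slot indexName index whose histogram is sampled.
#' @slot binIndices strictly increasing bin indices.
#' @slot correlations Pearson r of each selected bin with the target.
#' @slot targetName \code{"leaf_n"} or \code{"yield"}.
#' @slot binEdges full edge vector of the histogram the indices refer to.
#' @slot policy selection policy used.
#' @slot params list of policy parameters (window, rMin, kMin, peak bins).
#' @aliases BinSelection
#' @exportClass BinSelection
setClass("BinSelection",
  representation(
    indexName = "character",
    binIndices = "integer",
    correlations = "numeric",
    targetName = "character",
    binEdges = "numeric",
    policy = "character",
    params = "list"
  )
)

setValidity("BinSelection", function(object) {
  if (length(object@binIndices) == 0L)
    return("at least one bin must be selected")
  if (any(diff(object@binIndices) <= 0))
    return("binIndices must be strictly increasing")
  if (length(object@correlations) != length(object@binIndices))
    return("correlations must align with binIndices")
  if (any(abs(object@correlations) > 1 + 1e-12))
    return("|correlation| cannot exceed 1")
  if (!object@targetName %in% c("leaf_n", "yield"))
    return("targetName must be 'leaf_n' or 'yield'")
  TRUE
})

#' FeatureMatrix: samples-by-features design matrix with diagnosis targets
#'
#' @slot values numeric matrix, rows = samples (rownames are sample ids),
#'   columns = features.
#' @slot targets data.frame with columns \code{leaf_n} and \code{yield}
#'   aligned to rows (\code{NA} for prediction-only samples).
#' @slot mode \code{"IIMV"} or \code{"IIH"}.
#' @slot recipe list describing how the features were built (index set or
#'   a \linkS4class{BinSelection}).
#' @aliases FeatureMatrix
#' @exportClass FeatureMatrix
setClass("FeatureMatrix",
  representation(values = "matrix", targets = "data.frame",
                 mode = "character", recipe = "list")
)

setValidity("FeatureMatrix", function(object) {
  if (ncol(object@values) < 1L) return("feature matrix must have >= 1 column")
  if (!all(is.finite(object@values))) return("feature values must be finite")
  if (is.null(rownames(object@values)) || is.null(colnames(object@values)))
    return("values must carry sample ids (rownames) and feature names")
  if (anyDuplicated(rownames(object@values)))
    return("sample ids must be unique")
  if (nrow(object@targets) != nrow(object@values))
    return("targets must align with sample rows")
  if (!object@mode %in% c("IIMV", "IIH"))
    return("mode must be 'IIMV' or 'IIH'")
  TRUE
})

#' MLPConfig: architecture and Levenberg-Marquardt schedule
#'
#' @slot nHidden hidden-layer width (logistic-sigmoid units).
#' @slot maxIter maximum number of accepted LM iterations.
#' @slot mu0 initial damping.
#' @slot muInc,muDec damping multipliers on rejected / accepted steps.
#' @slot gradTol stop when the gradient infinity-norm falls below this.
#' @slot lossTol stop when the sum-of-squares loss falls below this.
#' @slot seed RNG seed for weight initialization.
#' @slot inputScaling,outputScaling \code{"minmax"}, \code{"zscore"} or
#'   \code{"none"}.
#' @slot earlyStopFraction fraction of the training samples held out inside
#'   training to monitor generalization (0 disables early stopping).
#' @slot maxFail consecutive accepted steps without held-out improvement
#'   tolerated before stopping.
#' @aliases MLPConfig
#' @exportClass MLPConfig
setClass("MLPConfig",
  representation(
    nHidden = "integer", maxIter = "integer",
    mu0 = "numeric", muInc = "numeric", muDec = "numeric",
    gradTol = "numeric", lossTol = "numeric", seed = "integer",
    inputScaling = "character", outputScaling = "character",
    earlyStopFraction = "numeric", maxFail = "integer"
  )
)

setValidity("MLPConfig", function(object) {
  if (object@nHidden < 1L) return("nHidden must be positive")
  if (object@maxIter < 0L) return("maxIter must be nonnegative")
  if (object@mu0 <= 0) return("mu0 must be positive")
  if (object@muInc <= 1) return("muInc must exceed 1")
  if (object@muDec <= 0 || object@muDec >= 1)
    return("muDec must lie in (0, 1)")
  if (object@gradTol <= 0 || object@lossTol <= 0)
    return("tolerances must be positive")
  sc <- c(object@inputScaling, object@outputScaling)
  if (!all(sc %in% c("minmax", "zscore", "none")))
    return("scalings must be 'minmax', 'zscore' or 'none'")
  if (object@earlyStopFraction < 0 || object@earlyStopFraction >= 0.5)
    return("earlyStopFraction must lie in [0, 0.5)")
  if (object@maxFail < 1L) return("maxFail must be positive")
  TRUE
})

#' Create an MLP configuration
#'
#' Defaults follow the classic Levenberg-Marquardt MLP recipe: one hidden
#' layer of 10 logistic units, linear output, min-max scaling of inputs and
#' target onto \code{[-1, 1]}, damping schedule mu0 = 1e-3 with factors 10
#' and 0.1, and an inner early-stopping holdout of 15 percent of the
#' training samples with 6 tolerated failures, mirroring the standard
#' neural-network fitting-tool behavior (set
#' \code{earlyStopFraction = 0} to optimize the training loss to
#' convergence).
#'
#' @param nHidden,maxIter,mu0,muInc,muDec,gradTol,lossTol,seed,inputScaling,outputScaling,earlyStopFraction,maxFail
#'   see \linkS4class{MLPConfig}.
#' @return An \linkS4class{MLPConfig}.
#' @export
mlpConfig <- function(nHidden = 10L, maxIter = 200L, mu0 = 1e-3,
                      muInc = 10, muDec = 0.1, gradTol = 1e-7,
                      lossTol = 1e-10, seed = 1L,
                      inputScaling = "minmax", outputScaling = "minmax",
                      earlyStopFraction = 0.15, maxFail = 6L) {
  new("MLPConfig", nHidden = as.integer(nHidden), maxIter = as.integer(maxIter),
      mu0 = mu0, muInc = muInc, muDec = muDec, gradTol = gradTol,
      lossTol = lossTol, seed = as.integer(seed),
      inputScaling = inputScaling, outputScaling = outputScaling,
      earlyStopFraction = earlyStopFraction, maxFail = as.integer(maxFail))
}

#' DiagnosisModel: a trained (or initialized) LM-MLP with its feature recipe
#'
#' One hidden layer of logistic units and a single linear output. Carries the
#' input/output scaling fitted on the training data, the accepted-step loss
#' history, and the feature recipe (IIMV index list or IIH bin selection)
#' needed to apply the model to new images.
#'
#' @slot W1 hidden weights, \code{nHidden x nInputs}.
#' @slot b1 hidden biases, length \code{nHidden}.
#' @slot W2 output weights, length \code{nHidden}.
#' @slot b2 output bias (scalar).
#' @slot inputScale,outputScale lists with elements \code{kind}, \code{center},
#'   \code{scale} mapping raw values to the training space.
#' @slot history accepted sum-of-squares losses (scaled space), first entry is
#'   the pre-training loss.
#' @slot config the \linkS4class{MLPConfig} used.
#' @slot recipe list: \code{featureNames}, \code{mode}, \code{target}, and the
#'   serialized bin selection when mode is IIH.
#' @slot trained logical.
#' @slot chosenSeed initialization seed actually used (multi-start).
#' @aliases DiagnosisModel
#' @exportClass DiagnosisModel
setClass("DiagnosisModel",
  representation(
    W1 = "matrix", b1 = "numeric", W2 = "numeric", b2 = "numeric",
    inputScale = "list", outputScale = "list",
    history = "numeric", config = "MLPConfig", recipe = "list",
    trained = "logical", chosenSeed = "integer"
  )
)

setValidity("DiagnosisModel", function(object) {
  nh <- nrow(object@W1)
  if (length(object@b1) != nh || length(object@W2) != nh)
    return("b1 and W2 must match the hidden width")
  if (length(object@b2) != 1L) return("b2 must be scalar")
  w <- c(object@W1, object@b1, object@W2, object@b2)
  if (!all(is.finite(w))) return("all weights must be finite")
  TRUE
})

#' ScenarioConfig: synthetic canopy cohort description
#'
#' Defines the field-trial layout (cultivars x N rates x replicate images) and
#' the generative links from nitrogen supply to leaf N content, grain yield,
#' vegetation color, and fractional coverage used by
#' \code{\link{generateCohort}}. See the package vignette for the meaning and
#' calibration of each parameter.
#'
#' @slot cultivars cultivar labels.
#' @slot nLevels N application rates, kg N/ha.
#' @slot replicates images per cultivar x rate.
#' @slot imageSize c(height, width) in pixels.
#' @slot stagePreset \code{"reviving"}, \code{"jointing"} or
#'   \code{"color_only"} (constant coverage).
#' @slot soilRGB mean soil color (R, G, B, 0-255).
#' @slot soilSpread per-pixel soil color sd.
#' @slot leafN list: \code{baseline}, \code{gain}, \code{scale} of the
#'   saturating leaf-N response, plus \code{plotSd} and \code{measureSd}.
#' @slot vegetation list: \code{baseRGB} at the reference leaf N,
#'   \code{refLeafN}, \code{greennessGain}, \code{rednessLoss} (channel units
#'   per leaf-N percent).
#' @slot coverage list: \code{min}, \code{max}, \code{mid}, \code{scale} of
#'   the logistic coverage response to leaf N.
#' @slot yield list: \code{max}, \code{optN}, \code{curvature},
#'   \code{noiseSd}.
#' @slot cultivarSd list: \code{leafN}, \code{yield} offset sds.
#' @slot pixelNoiseSd per-channel pixel noise sd.
#' @slot wbJitterSd per-image white-balance (channel gain) log-sd.
#' @slot clusterSigma Gaussian smoothing sigma (px) of the coverage noise
#'   field (spatial patchiness).
#' @slot seed cohort seed.
#' @aliases ScenarioConfig
#' @exportClass ScenarioConfig
setClass("ScenarioConfig",
  representation(
    cultivars = "character", nLevels = "numeric", replicates = "integer",
    imageSize = "integer", stagePreset = "character",
    soilRGB = "numeric", soilSpread = "numeric",
    leafN = "list", vegetation = "list", coverage = "list",
    yield = "list", cultivarSd = "list",
    pixelNoiseSd = "numeric", wbJitterSd = "numeric",
    clusterSigma = "numeric", seed = "integer"
  )
)

setValidity("ScenarioConfig", function(object) {
  if (length(object@nLevels) < 1L || any(object@nLevels < 0))
    return("nLevels must be nonnegative rates")
  if (object@replicates < 1L) return("replicates must be >= 1")
  if (any(object@imageSize < 8L))
    return("imageSize must be at least 8 x 8")
  cv <- object@coverage
  if (cv$min <= 0 || cv$max >= 1 || cv$min > cv$max)
    return("coverage bounds must satisfy 0 < min <= max < 1")
  ln <- object@leafN
  if (ln$baseline <= 0) return("leaf-N baseline must be positive")
  # leaf_n(N) must stay positive over the configured rates
  if (ln$baseline + min(0, ln$gain) <= 0)
    return("leaf_n(N) must remain positive for all configured N")
  if (length(object@soilRGB) != 3L || any(object@soilRGB < 0) ||
      any(object@soilRGB > 255))
    return("soilRGB must be three channel means in [0, 255]")
  TRUE
})

#' EvaluationReport: IIMV-vs-IIH comparison errors and predictions
#'
#' @slot errors data.frame with one row per mode x stage x target and columns
#'   \code{mape_train}, \code{rmse_train}, \code{mape_validation},
#'   \code{rmse_validation}.
#' @slot predictions per-sample predicted-vs-measured table (1:1 plot data).
#' @slot splits list of train/validation sample-id manifests per stage.
#' @slot config snapshot of the protocol parameters.
#' @aliases EvaluationReport
#' @exportClass EvaluationReport
setClass("EvaluationReport",
  representation(errors = "data.frame", predictions = "data.frame",
                 splits = "list", config = "list")
)

setValidity("EvaluationReport", function(object) {
  need <- c("mode", "stage", "target", "mape_train", "rmse_train",
            "mape_validation", "rmse_validation")
  if (!all(need %in% names(object@errors)))
    return("errors must carry the report columns")
  err <- object@errors[, c("mape_train", "rmse_train",
                           "mape_validation", "rmse_validation")]
  if (any(unlist(err) < 0)) return("error metrics cannot be negative")
  for (sp in object@splits)
    if (length(intersect(sp$train, sp$validation)) > 0)
      return("train and validation sets must be disjoint")
  TRUE
})
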