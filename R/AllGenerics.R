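#' @include AllClasses.R
NULL

#' Accessors for canopyN classes
#'
#' Small accessor generics: slot access stays behind functions so internal
#' representations can change without breaking user code.
#'
#' @param object a canopyN S4 object.
#' @return The corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixelData", function(object) standardGeneric("pixelData"))
#' @rdname accessors
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setGeneric("stage", function(object) standardGeneric("stage"))
#' @rdname accessors
#' @export
setGeneric("indexName", function(object) standardGeneric("indexName"))
#' @rdname accessors
#' @export
setGeneric("indexValues", function(object) standardGeneric("indexValues"))
#' @rdname accessors
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))
#' @rdname accessors
#' @export
setGeneric("theoreticalRange", function(object) standardGeneric("theoreticalRange"))
#' @rdname accessors
#' @export
setGeneric("coverage", function(object) standardGeneric("coverage"))
#' @rdname accessors
#' @export
setGeneric("percentages", function(object) standardGeneric("percentages"))
#' @rdname accessors
#' @export
setGeneric("binEdges", function(object) standardGeneric("binEdges"))
#' @rdname accessors
#' @export
setGeneric("peakBins", function(object) standardGeneric("peakBins"))
#' @rdname accessors
#' @export
setGeneric("binIndices", function(object) standardGeneric("binIndices"))
#' @rdname accessors
#' @export
setGeneric("featureValues", function(object) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setGeneric("featureNames", function(object) standardGeneric("featureNames"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("targets", function(object) standardGeneric("targets"))
#' @rdname accessors
#' @export
setGeneric("trainingHistory", function(object) standardGeneric("trainingHistory"))
#' @rdname accessors
#' @export
setGeneric("modelWeights", function(object) standardGeneric("modelWeights"))
#' @rdname accessors
#' @export
setGeneric("reportErrors", function(object) standardGeneric("reportErrors"))
#' @rdname accessors
#' @export
setGeneric("reportPredictions", function(object) standardGeneric("reportPredictions"))

setMethod("pixelData", "CanopyImage", function(object) object@pixels)
setMethod("sampleId", "CanopyImage", function(object) object@sampleId)
setMethod("stage", "CanopyImage", function(object) object@stage)
setMethod("indexName", "IndexRaster", function(object) object@indexName)
setMethod("indexValues", "IndexRaster", function(object) object@values)
setMethod("validMask", "IndexRaster", function(object) object@validMask)
setMethod("theoreticalRange", "IndexRaster",
          function(object) object@theoreticalRange)
setMethod("coverage", "VegetationMask", function(object) object@coverage)
setMethod("validMask", "VegetationMask", function(object) object@mask)
setMethod("percentages", "HistogramFeature", function(object) object@percentages)
setMethod("binEdges", "HistogramFeature", function(object) object@binEdges)
setMethod("indexName", "HistogramFeature", function(object) object@indexName)
setMethod("peakBins", "HistogramFeature", function(object)
  c(a = object@peakA, b = object@peakB))
setMethod("binIndices", "BinSelection", function(object) object@binIndices)
setMethod("indexName", "BinSelection", function(object) object@indexName)
setMethod("featureValues", "FeatureMatrix", function(object) object@values)
setMethod("featureNames", "FeatureMatrix",
          function(object) colnames(object@values))
setMethod("sampleIds", "FeatureMatrix",
          function(object) rownames(object@values))
setMethod("targets", "FeatureMatrix", function(object) object@targets)
setMethod("trainingHistory", "DiagnosisModel", function(object) object@history)
setMethod("modelWeights", "DiagnosisModel", function(object)
  list(W1 = object@W1, b1 = object@b1, W2 = object@W2, b2 = object@b2))
setMethod("reportErrors", "EvaluationReport", function(object) object@errors)
setMethod("reportPredictions", "EvaluationReport",
          function(object) object@predictions)

setMethod("show", "CanopyImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("CanopyImage '%s': %d x %d px, cultivar=%s, stage=%s, N=%s\n",
              object@sampleId, d[1], d[2], object@cultivar, object@stage,
              format(object@nLevel)))
})

setMethod("show", "IndexRaster", function(object) {
  d <- dim(object@values)
  cat(sprintf("IndexRaster %s: %d x %d px, range [%g, %g], %.1f%% valid\n",
              object@indexName, d[1], d[2], object@theoreticalRange[1],
              object@theoreticalRange[2], 100 * mean(object@validMask)))
})

setMethod("show", "VegetationMask", function(object) {
  cat(sprintf("VegetationMask: coverage %.3f (threshold %.4f)\n",
              object@coverage, object@threshold))
})

setMethod("show", "HistogramFeature", function(object) {
  cat(sprintf("HistogramFeature %s: %d bins over [%g, %g]\n",
              object@indexName, length(object@percentages),
              min(object@binEdges), max(object@binEdges)))
  if (length(object@smoothed)) {
    cat(sprintf("  peaks: a=%s b=%s%s\n",
                ifelse(is.na(object@peakA), "absent", object@peakA),
                ifelse(is.na(object@peakB), "absent", object@peakB),
                if (object@flat) " [flat]" else ""))
  }
})

setMethod("show", "BinSelection", function(object) {
  cat(sprintf("BinSelection (%s, target %s, policy %s): %d bins [%s]\n",
              object@indexName, object@targetName, object@policy,
              length(object@binIndices),
              paste(range(object@binIndices), collapse = "..")))
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix (%s): %d samples x %d features\n",
              object@mode, nrow(object@values), ncol(object@values)))
})

setMethod("show", "DiagnosisModel", function(object) {
  cat(sprintf("DiagnosisModel (%s, target %s): %d inputs -> %d sigmoid -> 1 linear; %s\n",
              if (length(object@recipe$mode)) object@recipe$mode else "?",
              if (length(object@recipe$target)) object@recipe$target else "?",
              ncol(object@W1), nrow(object@W1),
              if (object@trained)
                sprintf("trained, final SSE %.4g (%d accepted steps, seed %d)",
                        object@history[length(object@history)],
                        length(object@history) - 1L, object@chosenSeed)
              else "untrained"))
})

setMethod("show", "ScenarioConfig", function(object) {
  cat(sprintf(paste0("ScenarioConfig '%s': %d cultivars x %d N levels x %d",
                     " replicates = %d images (%d x %d px), seed %d\n"),
              object@stagePreset, length(object@cultivars),
              length(object@nLevels), object@replicates,
              length(object@cultivars) * length(object@nLevels) *
                object@replicates,
              object@imageSize[1], object@imageSize[2], object@seed))
})

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport\n")
  err <- object@errors
  err$mape_train <- sprintf("%.1f%%", err$mape_train)
  err$mape_validation <- sprintf("%.1f%%", err$mape_validation)
  err$rmse_train <- sprintf("%.3f", err$rmse_train)
  err$rmse_validation <- sprintf("%.3f", err$rmse_validation)
  print(err, row.names = FALSE)
})
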