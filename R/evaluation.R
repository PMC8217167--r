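#' @include features.R nn-model.R
NULL

#' Error metrics: RMSE, MAPE and coefficient of variation
#'
#' \code{rmse} is \code{sqrt(mean((y - yhat)^2))} in target units;
#' \code{mape} is \code{100 * mean(|y - yhat| / |y|)} in percent (undefined
#' when any measured value is zero); \code{cvPercent} is the sample
#' coefficient of variation \code{100 * sd / mean} (n-1 denominator).
#'
#' @param y measured values.
#' @param yhat estimated values.
#' @return A scalar metric.
#' @export
rmse <- function(y, yhat) {
  y <- as.numeric(y); yhat <- as.numeric(yhat)
  if (length(y) == 0L || length(y) != length(yhat))
    stopf("y and yhat must be nonempty vectors of equal length")
  if (!all(is.finite(y)) || !all(is.finite(yhat)))
    stopf("rmse requires finite inputs")
  sqrt(mean((y - yhat)^2))
}

#' @rdname rmse
#' @export
mape <- function(y, yhat) {
  y <- as.numeric(y); yhat <- as.numeric(yhat)
  if (length(y) == 0L || length(y) != length(yhat))
    stopf("y and yhat must be nonempty vectors of equal length")
  if (!all(is.finite(y)) || !all(is.finite(yhat)))
    stopf("mape requires finite inputs")
  if (any(y == 0)) stopf("MAPE undefined: measured values contain zero")
  100 * mean(abs(y - yhat) / abs(y))
}

#' @rdname rmse
#' @param values numeric vector (>= 2 finite values, nonzero mean).
#' @export
cvPercent <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L || !all(is.finite(values)))
    stopf("cvPercent needs at least two finite values")
  m <- mean(values)
  if (m == 0) stopf("cvPercent undefined: mean is zero")
  100 * stats::sd(values) / m
}

#' Seeded stratified train/validation split
#'
#' Draws \code{nTrain} training samples, stratified by the given fields so
#' every stratum appears in training; allocation across strata is
#' proportional with largest-remainder rounding, and the draw within each
#' stratum is a seeded simple random sample. Strata smaller than 2 are pooled
#' (with a warning) into a single pseudo-stratum.
#'
#' @param samples sample table (see \code{\link{readSampleTable}}).
#' @param nTrain number of training samples (default 60 of a 90-sample
#'   cohort).
#' @param seed split seed.
#' @param stratifyBy column names to stratify on; \code{NULL} for a plain
#'   random split.
#' @return list with character vectors \code{train} and \code{validation}
#'   (disjoint, exhaustive).
#' @export
splitSamples <- function(samples, nTrain = 60L, seed = 1L,
                         stratifyBy = c("cultivar", "n_level")) {
  n <- nrow(samples)
  nTrain <- as.integer(nTrain)
  if (nTrain < 1L || nTrain >= n)
    stopf("nTrain must lie in [1, %d) so the validation set is nonempty", n)
  ids <- samples$sample_id
  if (is.null(stratifyBy) || !length(stratifyBy)) {
    strat <- rep("all", n)
  } else {
    strat <- do.call(paste, c(samples[stratifyBy], sep = "\r"))
    small <- names(which(table(strat) < 2L))
    if (length(small)) {
      warnf("%d strata have fewer than 2 samples; pooling them", length(small))
      strat[strat %in% small] <- ".pooled"
    }
  }
  groups <- split(seq_len(n), strat)
  sizes <- lengths(groups)
  quota <- nTrain * sizes / n
  base <- pmax(1L, floor(quota))           # every stratum reaches training
  base <- pmin(base, sizes)
  excess <- sum(base) - nTrain
  frac <- quota - floor(quota)
  if (excess < 0) {
    ord <- order(-frac, names(groups))
    for (j in ord) {
      if (excess == 0) break
      if (base[j] < sizes[j]) { base[j] <- base[j] + 1L; excess <- excess + 1L }
    }
    # still short (caps hit): fill wherever room remains
    j <- 1L
    while (excess < 0) {
      if (base[j] < sizes[j]) { base[j] <- base[j] + 1L; excess <- excess + 1L }
      j <- if (j == length(base)) 1L else j + 1L
    }
  } else if (excess > 0) {
    ord <- order(frac, names(groups))
    for (j in ord) {
      if (excess == 0) break
      if (base[j] > 1L) { base[j] <- base[j] - 1L; excess <- excess - 1L }
    }
  }
  train <- withSeed(seed, {
    unlist(lapply(seq_along(groups), function(j) {
      g <- groups[[j]]
      g[sample.int(length(g), base[j])]
    }), use.names = FALSE)
  })
  train <- sort(train)
  list(train = ids[train], validation = ids[setdiff(seq_len(n), train)])
}

.metricsRow <- function(y, yhat) c(mape = mape(y, yhat), rmse = rmse(y, yhat))

#' Run the IIMV-vs-IIH model comparison protocol
#'
#' For every growth stage present in the sample table and every requested
#' target, builds both feature families, trains one LM-MLP per
#' (mode, target), and reports training and validation MAPE/RMSE. The IIH
#' bin selection (template peaks and bin correlations) is fitted on the
#' training split only and frozen before validation, so no selection leakage
#' occurs. Per-sample predicted-vs-measured values are returned for 1:1
#' plots.
#'
#' @param samples sample table with targets present.
#' @param images named list of \linkS4class{CanopyImage} (entries missing
#'   from the list are read from \code{image_path}).
#' @param targets subset of \code{c("leaf_n", "yield")}.
#' @param modes subset of \code{c("IIMV", "IIH")}.
#' @param nTrain training-set size per stage (default 60).
#' @param seed split and training seed.
#' @param iihIndex color index whose histogram feeds the IIH model.
#' @param nBins histogram bin count.
#' @param window,rMin,kMin bin-selection parameters
#'   (\code{\link{selectRegion}}).
#' @param smoothWindow,minSeparation peak-detection parameters
#'   (\code{\link{detectPeaks}}).
#' @param config \linkS4class{MLPConfig} template (its seed is replaced by
#'   \code{seed}).
#' @param restarts LM restarts per fit (default 3).
#' @param useVegetationMask IIMV averaging domain (vegetation component vs
#'   whole frame).
#' @return An \linkS4class{EvaluationReport}; its \code{models} config entry
#'   holds the fitted models keyed \code{mode.stage.target}.
#' @export
runComparison <- function(samples, images = NULL,
                          targets = c("leaf_n", "yield"),
                          modes = c("IIMV", "IIH"),
                          nTrain = 60L, seed = 1L, iihIndex = "GMRN",
                          nBins = 256L, window = 41L, rMin = 0.5, kMin = 8L,
                          smoothWindow = 5L, minSeparation = 20L,
                          config = mlpConfig(), restarts = 3L,
                          useVegetationMask = TRUE) {
  targets <- match.arg(targets, several.ok = TRUE)
  modes <- match.arg(modes, several.ok = TRUE)
  if ("leaf_n" %in% targets && anyNA(samples$leaf_n))
    stopf("all samples need leaf_n for the comparison")
  if ("yield" %in% targets && anyNA(samples$yield))
    stopf("all samples need yield for the comparison")
  config@seed <- as.integer(seed)
  stages <- unique(samples$stage)
  errRows <- list(); predRows <- list(); splits <- list(); models <- list()
  for (st in stages) {
    sub <- samples[samples$stage == st, , drop = FALSE]
    sub <- sub[order(sub$sample_id), , drop = FALSE]  # row-order invariance
    imgs <- .resolveImages(sub, images)
    sp <- splitSamples(sub, nTrain = min(nTrain, nrow(sub) - 1L), seed = seed)
    splits[[st]] <- sp
    trIdx <- match(sp$train, sub$sample_id)
    vaIdx <- match(sp$validation, sub$sample_id)
    featByMode <- list()
    if ("IIMV" %in% modes)
      featByMode$IIMV <- list(all = buildFeatureMatrix(
        sub, imgs, mode = "IIMV", useVegetationMask = useVegetationMask))
    if ("IIH" %in% modes)
      histAll <- histogramMatrix(sub, imgs, indexName = iihIndex,
                                 nBins = nBins)
    for (tg in targets) {
      for (md in modes) {
        if (md == "IIMV") {
          fm <- featByMode$IIMV$all
          X <- featureValues(fm)
          fmFit <- fm
        } else {
          # selection fitted on the training split only
          trHist <- histAll[trIdx, , drop = FALSE]
          r <- binCorrelations(trHist, sub[[tg]][trIdx])
          template <- new("HistogramFeature", indexName = iihIndex,
                          binEdges = seq(.indexRegistry[[iihIndex]]$range[1],
                                         .indexRegistry[[iihIndex]]$range[2],
                                         length.out = nBins + 1L),
                          percentages = colMeans(trHist) /
                            sum(colMeans(trHist)) * 100)
          template <- detectPeaks(template, smoothWindow, minSeparation)
          sel <- selectRegion(r, template, targetName = tg,
                              window = window, rMin = rMin, kMin = kMin)
          X <- histAll[, sel@binIndices, drop = FALSE]
          colnames(X) <- sprintf("%s_bin%03d", iihIndex, sel@binIndices)
          fmFit <- new("FeatureMatrix", values = X,
                       targets = data.frame(leaf_n = sub$leaf_n,
                                            yield = sub$yield),
                       mode = "IIH", recipe = list(selection = sel))
        }
        Xtr <- featureValues(fmFit)[trIdx, , drop = FALSE]
        fmTr <- new("FeatureMatrix", values = Xtr,
                    targets = fmFit@targets[trIdx, , drop = FALSE],
                    mode = fmFit@mode, recipe = fmFit@recipe)
        fit <- fitDiagnosisModel(fmTr, target = tg, config = config,
                                 restarts = restarts)
        yhat <- forward(fit, featureValues(fmFit))
        yAll <- sub[[tg]]
        trM <- .metricsRow(yAll[trIdx], yhat[trIdx])
        vaM <- .metricsRow(yAll[vaIdx], yhat[vaIdx])
        errRows[[length(errRows) + 1L]] <- data.frame(
          mode = md, stage = st, target = tg,
          mape_train = trM["mape"], rmse_train = trM["rmse"],
          mape_validation = vaM["mape"], rmse_validation = vaM["rmse"],
          n_features = ncol(Xtr), row.names = NULL)
        predRows[[length(predRows) + 1L]] <- data.frame(
          sample_id = sub$sample_id, stage = st, mode = md, target = tg,
          measured = yAll, estimated = yhat,
          split = ifelse(sub$sample_id %in% sp$train, "train", "validation"),
          row.names = NULL)
        models[[paste(md, st, tg, sep = ".")]] <- fit
      }
    }
  }
  new("EvaluationReport",
      errors = do.call(rbind, errRows),
      predictions = do.call(rbind, predRows),
      splits = splits,
      config = list(targets = targets, modes = modes, nTrain = nTrain,
                    seed = seed, iihIndex = iihIndex, nBins = nBins,
                    window = window, rMin = rMin, kMin = kMin,
                    smoothWindow = smoothWindow,
                    minSeparation = minSeparation, restarts = restarts,
                    useVegetationMask = useVegetationMask,
                    nHidden = config@nHidden, maxIter = config@maxIter,
                    models = models))
}

#' Write an evaluation report to CSV
#'
#' Emits \code{<prefix>_errors.csv} (one row per mode x stage x target,
#' MAPE/RMSE for training and validation) and
#' \code{<prefix>_predictions.csv} (per-sample measured vs estimated, for
#' 1:1 plots), at full precision.
#'
#' @param report an \linkS4class{EvaluationReport}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Character vector of the two paths, invisibly.
#' @export
writeEvaluationReport <- function(report, dir, prefix = "report") {
  stopifnot(is(report, "EvaluationReport"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pErr <- file.path(dir, paste0(prefix, "_errors.csv"))
  pPred <- file.path(dir, paste0(prefix, "_predictions.csv"))
  writeCsv(report@errors, pErr)
  writeCsv(report@predictions, pPred)
  invisible(c(pErr, pPred))
}
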