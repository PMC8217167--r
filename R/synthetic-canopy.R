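#' @include image-io.R color-index.R
NULL

.coveragePresets <- list(
  reviving   = list(min = 0.20, max = 0.65, mid = 3.4, scale = 0.5),
  jointing   = list(min = 0.50, max = 0.92, mid = 3.4, scale = 0.5),
  color_only = list(min = 0.45, max = 0.45, mid = 3.4, scale = 0.5)
)

#' Build a synthetic-cohort scenario configuration
#'
#' The generator paints nadir canopy photographs as two-population pixel
#' mixtures (soil vs vegetation). A latent leaf-N level per plot follows a
#' saturating response to the N application rate plus cultivar and plot
#' effects; vegetation greenness, redness loss and fractional coverage all
#' increase with that latent level, yield follows a quadratic response
#' peaking at an intermediate rate, and each image gets a random
#' white-balance perturbation emulating phone auto color tuning. Defaults
#' emulate a winter-wheat trial: 6 cultivars x 5 N rates
#' (0/120/180/240/360 kg N/ha) x 3 replicate images = 90 samples per stage,
#' with leaf N spanning roughly 2.3-4.5 percent and yields roughly
#' 5000-7500 kg/ha. The \code{"reviving"} preset is a low-coverage canopy,
#' \code{"jointing"} high-coverage, and \code{"color_only"} holds coverage
#' constant so only hue carries information.
#'
#' @param stagePreset \code{"reviving"}, \code{"jointing"} or
#'   \code{"color_only"}.
#' @param seed cohort seed.
#' @param cultivars,nLevels,replicates,imageSize trial layout.
#' @param soilRGB,soilSpread soil color model (0-255 channel units).
#' @param leafN,vegetation,coverage,yield,cultivarSd response-curve
#'   parameter lists; any element supplied overrides the default
#'   (see \linkS4class{ScenarioConfig}).
#' @param pixelNoiseSd,wbJitterSd,clusterSigma image noise model.
#' @return A \linkS4class{ScenarioConfig}.
#' @export
scenarioConfig <- function(stagePreset = c("reviving", "jointing",
                                           "color_only"),
                           seed = 1L,
                           cultivars = paste0("cv", LETTERS[1:6]),
                           nLevels = c(0, 120, 180, 240, 360),
                           replicates = 3L,
                           imageSize = c(96L, 96L),
                           soilRGB = c(130, 105, 85), soilSpread = 10,
                           leafN = list(), vegetation = list(),
                           coverage = list(), yield = list(),
                           cultivarSd = list(),
                           pixelNoiseSd = 8, wbJitterSd = 0.04,
                           clusterSigma = 4) {
  stagePreset <- match.arg(stagePreset)
  leafN <- utils::modifyList(
    list(baseline = 3.0, gain = 0.95, scale = 150,
         plotSd = 0.15, measureSd = 0.10), leafN)
  vegetation <- utils::modifyList(
    list(baseRGB = c(80, 125, 65), refLeafN = 3.5,
         greennessGain = 12, rednessLoss = 8), vegetation)
  coverage <- utils::modifyList(.coveragePresets[[stagePreset]], coverage)
  yield <- utils::modifyList(
    list(max = 6800, optN = 225, curvature = 0.016, noiseSd = 200), yield)
  cultivarSd <- utils::modifyList(list(leafN = 0.25, yield = 300), cultivarSd)
  new("ScenarioConfig", cultivars = cultivars, nLevels = nLevels,
      replicates = as.integer(replicates),
      imageSize = as.integer(imageSize), stagePreset = stagePreset,
      soilRGB = soilRGB, soilSpread = soilSpread,
      leafN = leafN, vegetation = vegetation, coverage = coverage,
      yield = yield, cultivarSd = cultivarSd,
      pixelNoiseSd = pixelNoiseSd, wbJitterSd = wbJitterSd,
      clusterSigma = clusterSigma, seed = as.integer(seed))
}

.leafNCurve <- function(N, p) p$baseline + p$gain * (1 - exp(-N / p$scale))

.coverageCurve <- function(leafn, p) {
  if (p$min == p$max) return(rep(p$min, length(leafn)))
  p$min + (p$max - p$min) * stats::plogis((leafn - p$mid) / p$scale)
}

# Spatially clustered vegetation mask: threshold a Gaussian-smoothed white
# noise field at the coverage quantile, so canopies are patchy rather than
# salt-and-pepper.
.vegetationField <- function(h, w, cover, sigma) {
  z <- matrix(stats::rnorm(h * w), h, w)
  if (sigma > 0) z <- EBImage::gblur(z, sigma = sigma)
  z <= stats::quantile(z, cover)
}

.clip255 <- function(x) pmin(pmax(round(x), 0), 255)

#' Generate a synthetic canopy cohort
#'
#' Draws one image plus ground truth per cultivar x N rate x replicate
#' under the scenario's response curves (see \code{\link{scenarioConfig}}).
#' Fully reproducible: the same (config, seed) yields bit-identical images
#' and tables.
#'
#' @param config a \linkS4class{ScenarioConfig}.
#' @param dir optional output directory; when given, PNG images, the sample
#'   CSV, the ground-truth CSV and a YAML scenario snapshot are written
#'   there.
#' @return list with \code{images} (named \linkS4class{CanopyImage} list),
#'   \code{samples} (sample table in the \code{\link{readSampleTable}}
#'   schema), \code{truth} (per-sample latent values) and \code{config}.
#' @export
generateCohort <- function(config, dir = NULL) {
  stopifnot(is(config, "ScenarioConfig"))
  stageLabel <- if (config@stagePreset == "jointing") "jointing" else "reviving"
  h <- config@imageSize[1]; w <- config@imageSize[2]
  nc <- length(config@cultivars)
  out <- withSeed(config@seed, {
    cOffL <- stats::rnorm(nc, 0, config@cultivarSd$leafN)
    cOffY <- stats::rnorm(nc, 0, config@cultivarSd$yield)
    images <- list(); samp <- list(); truth <- list()
    for (ci in seq_len(nc)) {
      for (N in config@nLevels) {
        for (rep_ in seq_len(config@replicates)) {
          latent <- .leafNCurve(N, config@leafN) + cOffL[ci] +
            stats::rnorm(1, 0, config@leafN$plotSd)
          latent <- max(latent, 0.3)
          obs <- max(latent + stats::rnorm(1, 0, config@leafN$measureSd), 0.2)
          yld <- config@yield$max -
            config@yield$curvature * (N - config@yield$optN)^2 +
            cOffY[ci] + stats::rnorm(1, 0, config@yield$noiseSd)
          yld <- max(yld, 500)
          cover <- .coverageCurve(latent, config@coverage)
          veg <- .vegetationField(h, w, cover, config@clusterSigma)
          vg <- config@vegetation
          dLN <- latent - vg$refLeafN
          vegRGB <- c(vg$baseRGB[1] - vg$rednessLoss * dLN,
                      vg$baseRGB[2] + vg$greennessGain * dLN,
                      vg$baseRGB[3])
          gains <- exp(stats::rnorm(3, 0, config@wbJitterSd))
          px <- array(0L, dim = c(h, w, 3L))
          for (ch in 1:3) {
            base <- matrix(config@soilRGB[ch], h, w) +
              matrix(stats::rnorm(h * w, 0, config@soilSpread), h, w)
            vnoise <- vegRGB[ch] + stats::rnorm(h * w, 0, config@pixelNoiseSd)
            base[veg] <- matrix(vnoise, h, w)[veg]
            px[, , ch] <- .clip255(base * gains[ch])
          }
          sid <- sprintf("%s_N%03d_r%d", config@cultivars[ci], N, rep_)
          images[[sid]] <- CanopyImage(px, sampleId = sid,
                                       cultivar = config@cultivars[ci],
                                       stage = stageLabel, nLevel = N)
          samp[[sid]] <- data.frame(
            sample_id = sid, image_path = NA_character_,
            cultivar = config@cultivars[ci], stage = stageLabel,
            n_level = N, leaf_n = obs, yield = yld)
          truth[[sid]] <- data.frame(
            sample_id = sid, latent_leaf_n = latent, leaf_n = obs,
            yield = yld, true_coverage = mean(veg),
            cultivar_leafn_offset = cOffL[ci],
            cultivar_yield_offset = cOffY[ci],
            wb_gain_r = gains[1], wb_gain_g = gains[2], wb_gain_b = gains[3],
            camera = "default")
        }
      }
    }
    list(images = images, samples = do.call(rbind, samp),
         truth = do.call(rbind, truth))
  })
  rownames(out$samples) <- NULL
  rownames(out$truth) <- NULL
  out$samples$has_targets <- TRUE
  out$config <- config
  if (!is.null(dir)) {
    imgDir <- file.path(dir, "images")
    dir.create(imgDir, recursive = TRUE, showWarnings = FALSE)
    for (sid in names(out$images)) {
      p <- file.path(imgDir, paste0(sid, ".png"))
      writeCanopyImage(out$images[[sid]], p)
      out$samples$image_path[out$samples$sample_id == sid] <- p
    }
    # the CSV stores paths relative to itself so run directories are portable
    # (and byte-identical across reruns in different locations)
    onDisk <- out$samples
    onDisk$image_path <- file.path("images",
                                   paste0(onDisk$sample_id, ".png"))
    writeSampleTable(onDisk, file.path(dir, "samples.csv"))
    writeCsv(out$truth, file.path(dir, "ground_truth.csv"))
    yaml::write_yaml(scenarioToList(config), file.path(dir, "scenario.yaml"))
  }
  out
}

#' Serialize a scenario configuration to a plain list (for YAML snapshots)
#' @param config a \linkS4class{ScenarioConfig}.
#' @return A named list mirroring the slots.
#' @export
scenarioToList <- function(config) {
  list(stagePreset = config@stagePreset, seed = config@seed,
       cultivars = config@cultivars, nLevels = config@nLevels,
       replicates = config@replicates, imageSize = config@imageSize,
       soilRGB = config@soilRGB, soilSpread = config@soilSpread,
       leafN = config@leafN, vegetation = config@vegetation,
       coverage = config@coverage, yield = config@yield,
       cultivarSd = config@cultivarSd, pixelNoiseSd = config@pixelNoiseSd,
       wbJitterSd = config@wbJitterSd, clusterSigma = config@clusterSigma)
}

#' Apply a camera color transform (phone-brand emulation)
#'
#' Per channel: \code{clip(round(255 * (gain * v/255)^gamma + offset))}.
#' The identity transform (unit gains, gamma 1, zero offset) returns the
#' image pixel-identically.
#'
#' @param image a \linkS4class{CanopyImage}.
#' @param gains positive per-channel gains (R, G, B).
#' @param gamma positive gamma exponent.
#' @param offset per-channel additive offsets (0-255 units).
#' @return The transformed \linkS4class{CanopyImage}.
#' @export
applyCameraTransform <- function(image, gains = c(1, 1, 1), gamma = 1,
                                 offset = c(0, 0, 0)) {
  stopifnot(is(image, "CanopyImage"))
  if (any(gains <= 0) || gamma <= 0)
    stopf("gains and gamma must be positive")
  gains <- rep_len(gains, 3); offset <- rep_len(offset, 3)
  px <- image@pixels
  out <- array(0L, dim = dim(px))
  for (ch in 1:3)
    out[, , ch] <- .clip255(255 * (gains[ch] * px[, , ch] / 255)^gamma +
                              offset[ch])
  CanopyImage(out, sampleId = image@sampleId, cultivar = image@cultivar,
              stage = image@stage, nLevel = image@nLevel)
}

#' Construct two images with equal whole-frame GMRN mean but different
#' coverage
#'
#' The constructive core of the histogram-vs-mean argument: the whole-frame
#' mean of a color index cannot separate a sparse, very green canopy from a
#' dense, paler one, while the histogram can. Vegetation greenness is solved
#' analytically to compensate the coverage difference (soil pixels share one
#' fixed color; vegetation pixels mix two adjacent achievable green-minus-red
#' levels so the target mean is hit to well under 1e-3), then the result is
#' verified numerically.
#'
#' @param coverages two vegetation coverages differing by at least 0.2.
#' @param size image height and width in pixels.
#' @param targetMean the common whole-frame GMRN mean.
#' @return list with \code{images} (two \linkS4class{CanopyImage}),
#'   \code{gmrnMeans} (achieved whole-frame means) and \code{coverages}
#'   (achieved coverages).
#' @export
equalMeanDistinctCoveragePair <- function(coverages = c(0.3, 0.6),
                                          size = c(64L, 64L),
                                          targetMean = 0.05) {
  if (length(coverages) != 2L || any(coverages <= 0) || any(coverages >= 1))
    stopf("coverages must be two fractions in (0, 1)")
  if (abs(diff(coverages)) < 0.2)
    stopf("degenerate request: coverages must differ by at least 0.2")
  h <- size[1]; w <- size[2]; npix <- h * w
  soil <- c(210, 200, 190)                     # sum 600, GMRN = -1/60
  gSoil <- (soil[2] - soil[1]) / sum(soil)
  S <- 450; Bv <- 150                          # veg: R+G = 300, B = 150
  mkImage <- function(cov, sid) {
    nVeg <- round(cov * npix)
    covAch <- nVeg / npix
    gVeg <- (targetMean - (1 - covAch) * gSoil) / covAch
    dStar <- gVeg * S
    dLo <- 2 * floor(dStar / 2); dHi <- dLo + 2
    glo <- (300 + dLo) / 2; ghi <- (300 + dHi) / 2
    if (glo < 0 || ghi > 255 || 300 - glo > 255 || 300 - ghi < 0)
      stopf("infeasible greenness compensation for coverage %.2f", cov)
    kHi <- round(nVeg * (dStar - dLo) / 2)
    dVals <- c(rep(dHi, kHi), rep(dLo, nVeg - kHi))
    R <- rep(soil[1], npix); G <- rep(soil[2], npix); B <- rep(soil[3], npix)
    if (nVeg > 0) {
      idx <- seq_len(nVeg)                     # contiguous block; no RNG
      G[idx] <- (300 + dVals) / 2
      R[idx] <- (300 - dVals) / 2
      B[idx] <- Bv
    }
    px <- array(0L, dim = c(h, w, 3L))
    px[, , 1] <- matrix(as.integer(R), h, w)
    px[, , 2] <- matrix(as.integer(G), h, w)
    px[, , 3] <- matrix(as.integer(B), h, w)
    list(image = CanopyImage(px, sampleId = sid), coverage = covAch)
  }
  a <- mkImage(coverages[1], "pair_lowcov")
  b <- mkImage(coverages[2], "pair_highcov")
  gm <- function(im) mean(indexValues(computeIndex(im, "GMRN")),
                          na.rm = TRUE)
  list(images = list(a$image, b$image),
       gmrnMeans = c(gm(a$image), gm(b$image)),
       coverages = c(a$coverage, b$coverage))
}
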