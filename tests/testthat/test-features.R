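test_that("segmentation splits a separable two-color image exactly", {
  triples <- c(rep(list(c(0, 255, 0)), 8), rep(list(c(255, 0, 0)), 8))
  im <- makeImage(triples, 4, 4)
  m <- segmentVegetation(im)
  expect_equal(coverage(m), 0.5)
  gm <- indexValues(computeIndex(im, "GMRN"))
  expect_identical(validMask(m), gm > m@threshold)
  expect_true(all(validMask(m)[gm == 1]))     # exactly the green pixels
  expect_false(any(validMask(m)[gm == -1]))
})

test_that("fixed-threshold overrides behave at the extremes", {
  green <- uniformImage(c(0, 255, 0), 4, 4)
  expect_equal(coverage(segmentVegetation(green, threshold = 0)), 1.0)
  expect_equal(coverage(segmentVegetation(green, threshold = 1.01)), 0.0)
  black <- uniformImage(c(0, 0, 0), 2, 2)
  expect_error(segmentVegetation(black), "no valid pixels")
})

test_that("IIMV equals the masked-mean oracle and falls back gracefully", {
  im <- randomImage(16, 16, seed = 3, lo = 1L)
  r <- computeIndex(im, "GMRN")
  set.seed(8)
  mask <- matrix(runif(256) > 0.5, 16, 16)
  got <- iimv(r, mask)
  expect_equal(got, oracleMaskedMean(as.vector(indexValues(r)),
                                     as.vector(mask)), tolerance = 1e-12)
  # constant raster: mean is the constant under any nonempty mask
  gray <- uniformImage(c(60, 90, 50), 4, 4)     # GMRN = 30/200 = 0.15
  expect_equal(iimv(computeIndex(gray, "GMRN"), mask = NULL), 0.15)
  # empty vegetation mask: falls back to all valid pixels, with a message
  empty <- matrix(FALSE, 4, 4)
  expect_message(v <- iimv(computeIndex(gray, "GMRN"), empty), "falling back")
  expect_equal(v, 0.15)
})

test_that("IIMV with a vegetation mask isolates the vegetation population", {
  triples <- c(rep(list(c(40, 110, 50)), 8),     # veg: GMRN = 70/200 = 0.35
               rep(list(c(120, 100, 80)), 8))    # soil: GMRN = -20/300
  im <- makeImage(triples, 4, 4)
  m <- segmentVegetation(im)
  expect_equal(iimv(computeIndex(im, "GMRN"), m), 0.35, tolerance = 1e-12)
})

test_that("histograms match the counting-loop oracle and sum to 100", {
  for (seed in 1:3) {
    im <- randomImage(32, 32, seed = seed)
    for (nm in c("GMRN", "NGI", "GR")) {
      r <- computeIndex(im, nm)
      h <- indexHistogram(r, nBins = 64L)
      want <- oracleHistogram(indexValues(r)[validMask(r)],
                              theoreticalRange(r)[1], theoreticalRange(r)[2],
                              64L)
      expect_equal(percentages(h), want, tolerance = 1e-12)
      expect_equal(sum(percentages(h)), 100, tolerance = 1e-9)
    }
  }
})

test_that("histogram bin placement: constants, halves and clipping", {
  gray <- uniformImage(c(50, 50, 50), 4, 4)     # GMRN = 0
  h <- indexHistogram(computeIndex(gray, "GMRN"), nBins = 256L)
  expect_equal(max(percentages(h)), 100)
  expect_equal(which.max(percentages(h)), 129)  # 0 falls in bin 129 of [-1,1]
  expect_equal(sum(percentages(h) > 0), 1L)

  half <- makeImage(c(rep(list(c(30, 90, 60)), 8),    # GMRN = +1/3
                      rep(list(c(90, 30, 60)), 8)),   # GMRN = -1/3
                    4, 4)
  h2 <- indexHistogram(computeIndex(half, "GMRN"), nBins = 4L)
  expect_equal(percentages(h2), c(0, 50, 50, 0))

  # G/B = 16 exceeds the fixed [0, 5] range: clipped into the last bin
  bright <- uniformImage(c(10, 240, 15), 2, 2)
  h3 <- indexHistogram(computeIndex(bright, "GB"), nBins = 10L)
  expect_equal(percentages(h3)[10], 100)
})

test_that("peak detection finds well-separated soil and crop modes", {
  bump <- function(center, height, width, n = 256) {
    x <- seq_len(n)
    height * exp(-(x - center)^2 / (2 * width^2))
  }
  p <- bump(60, 3, 6) + bump(180, 5, 8)
  p <- p / sum(p) * 100
  h <- new("HistogramFeature", indexName = "GMRN",
           binEdges = seq(-1, 1, length.out = 257), percentages = p)
  h <- detectPeaks(h, smoothWindow = 5L, minSeparation = 20L)
  pk <- peakBins(h)
  expect_equal(unname(pk["a"]), 60L)
  expect_equal(unname(pk["b"]), 180L)

  # single mode right of the midpoint: peak b only
  p1 <- bump(200, 4, 8); p1 <- p1 / sum(p1) * 100
  h1 <- detectPeaks(new("HistogramFeature", indexName = "GMRN",
                        binEdges = seq(-1, 1, length.out = 257),
                        percentages = p1))
  expect_true(is.na(peakBins(h1)["a"]))
  expect_equal(unname(peakBins(h1)["b"]), 200L)

  # flat histogram: flagged, no peaks
  hf <- detectPeaks(new("HistogramFeature", indexName = "GMRN",
                        binEdges = seq(-1, 1, length.out = 257),
                        percentages = rep(100 / 256, 256)))
  expect_true(hf@flat)
  expect_true(all(is.na(peakBins(hf))))
})

test_that("bin correlations follow the Pearson definition and conventions", {
  set.seed(21)
  target <- rnorm(12, 3.5, 0.5)
  hm <- matrix(rnorm(12 * 20), 12, 20)
  hm[, 3] <- 2 * target + 1
  hm[, 7] <- -target
  hm[, 11] <- 5                       # constant bin
  r <- binCorrelations(hm, target)
  expect_equal(r[3], 1.0, tolerance = 1e-12)
  expect_equal(r[7], -1.0, tolerance = 1e-12)
  expect_identical(r[11], 0)
  for (j in c(1, 5, 20))
    expect_equal(r[j], oraclePearson(hm[, j], target), tolerance = 1e-12)
  expect_error(binCorrelations(hm[1:2, ], target[1:2]), "3 samples")
  expect_error(binCorrelations(hm, rep(1, 12)), "zero variance")
})

test_that("region selection honors window, threshold and fallback", {
  mkTemplate <- function(pb = 180L) {
    h <- new("HistogramFeature", indexName = "GMRN",
             binEdges = seq(-1, 1, length.out = 257),
             percentages = rep(100 / 256, 256))
    h@peakA <- 100L; h@peakB <- pb; h@smoothed <- h@percentages
    h
  }
  tmpl <- mkTemplate()
  # all bins strongly correlated: the full 41-bin window survives
  r <- rep(0.9, 256)
  sel <- selectRegion(r, tmpl, "leaf_n", window = 41L, rMin = 0.5, kMin = 8L)
  expect_identical(binIndices(sel), 160:200)
  # only four bins pass rMin with kMin = 4: exactly those
  r2 <- rep(0.1, 256); r2[175:178] <- c(0.7, -0.8, 0.65, 0.9)
  sel2 <- selectRegion(r2, tmpl, "leaf_n", window = 41L, rMin = 0.6, kMin = 4L)
  expect_identical(binIndices(sel2), 175:178)
  expect_equal(sel2@correlations, r2[175:178])
  # nothing passes rMin: top-kMin |r| inside the window (sort oracle)
  set.seed(5)
  r3 <- runif(256, -0.4, 0.4)
  sel3 <- selectRegion(r3, tmpl, "leaf_n", window = 41L, rMin = 0.5, kMin = 5L)
  win <- 160:200
  want <- sort(win[order(-abs(r3[win]))][1:5])
  expect_identical(binIndices(sel3), as.integer(want))
  # no template peak b: advisory error; global_corr policy still works
  noPk <- mkTemplate(); noPk@peakB <- NA_integer_
  expect_error(selectRegion(r3, noPk, "leaf_n"), "global_corr")
  selG <- selectRegion(r3, noPk, "leaf_n", policy = "global_corr", kMin = 6L)
  expect_identical(binIndices(selG),
                   as.integer(sort(order(-abs(r3))[1:6])))
})

test_that("feature matrices have the contracted shapes and are deterministic", {
  co <- smallCohort(seed = 2)
  fm <- buildFeatureMatrix(co$samples, co$images, mode = "IIMV")
  expect_equal(dim(featureValues(fm)), c(18L, 6L))
  expect_identical(sampleIds(fm), co$samples$sample_id)

  hm <- histogramMatrix(co$samples, co$images, "GMRN", 256L)
  expect_equal(dim(hm), c(18L, 256L))
  tmpl <- detectPeaks(new("HistogramFeature", indexName = "GMRN",
                          binEdges = seq(-1, 1, length.out = 257),
                          percentages = colMeans(hm) / sum(colMeans(hm)) * 100))
  sel <- selectRegion(binCorrelations(hm, co$samples$leaf_n), tmpl, "leaf_n")
  fih <- buildFeatureMatrix(co$samples, co$images, mode = "IIH",
                            selection = sel)
  expect_equal(nrow(featureValues(fih)), 18L)
  expect_equal(ncol(featureValues(fih)), length(binIndices(sel)))
  fih2 <- buildFeatureMatrix(co$samples, co$images, mode = "IIH",
                             selection = sel)
  expect_identical(featureValues(fih), featureValues(fih2))

  expect_error(buildFeatureMatrix(co$samples, co$images[-3], mode = "IIMV"),
               co$samples$sample_id[3])
  expect_error(buildFeatureMatrix(co$samples, co$images, mode = "IIH"),
               "BinSelection")
})

test_that("histogram features separate equal-mean rasters that IIMV cannot", {
  pair <- equalMeanDistinctCoveragePair()
  r1 <- computeIndex(pair$images[[1]], "GMRN")
  r2 <- computeIndex(pair$images[[2]], "GMRN")
  expect_lt(abs(iimv(r1) - iimv(r2)), 1e-3)      # whole-frame means agree
  h1 <- percentages(indexHistogram(r1))
  h2 <- percentages(indexHistogram(r2))
  expect_gt(max(abs(h1 - h2)), 1)                # histograms clearly differ
})

test_that("bin selections serialize to JSON and reload bit-exactly", {
  co <- smallCohort(seed = 9)
  hm <- histogramMatrix(co$samples, co$images, "GMRN", 256L)
  tmpl <- detectPeaks(new("HistogramFeature", indexName = "GMRN",
                          binEdges = seq(-1, 1, length.out = 257),
                          percentages = colMeans(hm) / sum(colMeans(hm)) * 100))
  sel <- selectRegion(binCorrelations(hm, co$samples$leaf_n), tmpl, "leaf_n")
  f <- withr::local_tempfile(fileext = ".json")
  writeBinSelection(sel, f)
  back <- readBinSelection(f)
  expect_identical(binIndices(back), binIndices(sel))
  expect_identical(back@correlations, sel@correlations)
  expect_identical(back@binEdges, sel@binEdges)
  expect_identical(back@params$peakB, sel@params$peakB)
})
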