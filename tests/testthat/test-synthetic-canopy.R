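test_that("the default trial layout yields 90 samples and is reproducible", {
  co1 <- generateCohort(scenarioConfig(seed = 2))
  expect_equal(nrow(co1$samples), 90L)
  expect_equal(length(co1$images), 90L)
  expect_equal(nrow(co1$truth), 90L)
  co2 <- generateCohort(scenarioConfig(seed = 2))
  expect_identical(co1$samples, co2$samples)
  expect_identical(co1$truth, co2$truth)
  for (sid in names(co1$images)[c(1, 45, 90)])
    expect_identical(pixelData(co1$images[[sid]]),
                     pixelData(co2$images[[sid]]))
  co3 <- generateCohort(scenarioConfig(seed = 3))
  expect_false(identical(co1$samples$leaf_n, co3$samples$leaf_n))
})

test_that("generated leaf N and yields stay in the field-realistic spans", {
  for (s in 1:3) {
    co <- generateCohort(scenarioConfig(seed = s))
    expect_true(all(co$samples$leaf_n > 2.2 & co$samples$leaf_n < 4.6))
    expect_true(all(co$samples$yield > 3500 & co$samples$yield < 7600))
    expect_true(all(co$truth$true_coverage > 0 & co$truth$true_coverage < 1))
  }
})

test_that("coverage rises monotonically with nitrogen supply", {
  rhos <- vapply(1:5, function(s) {
    co <- generateCohort(scenarioConfig(seed = s))
    cor(co$truth$true_coverage, co$truth$leaf_n, method = "spearman")
  }, numeric(1))
  expect_gt(median(rhos), 0.5)
  # coverage increases across N levels in expectation (averaged over seeds)
  lev <- c(0, 120, 180, 240, 360)
  med <- rowMeans(vapply(1:5, function(s) {
    co <- generateCohort(scenarioConfig(seed = s))
    vapply(lev, function(L)
      mean(co$truth$true_coverage[co$samples$n_level == L]), numeric(1))
  }, numeric(5)))
  expect_true(all(diff(med) > 0))
})

test_that("a no-signal scenario produces near-null bin correlations", {
  p95 <- vapply(1:5, function(s) {
    co <- generateCohort(scenarioConfig(
      stagePreset = "color_only", seed = s,
      vegetation = list(greennessGain = 0, rednessLoss = 0)))
    hm <- histogramMatrix(co$samples, co$images)
    r <- binCorrelations(hm, co$samples$leaf_n)
    quantile(abs(r), 0.95)
  }, numeric(1))
  expect_lt(median(p95), 0.4)
})

test_that("camera transforms follow the gain-gamma-offset formula", {
  im <- randomImage(12, 12, seed = 5)
  expect_identical(pixelData(applyCameraTransform(im)), pixelData(im))
  gray <- uniformImage(c(100, 100, 100), 2, 2)
  out <- pixelData(applyCameraTransform(gray, gains = c(1.1, 1.0, 0.9)))
  expect_equal(out[1, 1, ], c(110L, 100L, 90L))
  # gamma brightens midtones; clipping absorbs overflow
  g2 <- applyCameraTransform(gray, gamma = 0.5)
  expect_equal(pixelData(g2)[1, 1, 1], round(255 * sqrt(100 / 255)))
  sat <- applyCameraTransform(uniformImage(c(250, 250, 250), 1, 1),
                              gains = c(2, 2, 2))
  expect_equal(pixelData(sat)[1, 1, ], c(255L, 255L, 255L))
  expect_error(applyCameraTransform(im, gains = c(0, 1, 1)), "positive")
})

test_that("a model carries across emulated phone brands with finite error", {
  co <- smallCohort(seed = 31)
  brandA <- lapply(co$images, applyCameraTransform,
                   gains = c(1.05, 1.0, 0.95), gamma = 1.02)
  brandB <- lapply(co$images, applyCameraTransform,
                   gains = c(0.95, 1.02, 1.05), gamma = 0.97,
                   offset = c(2, 0, -2))
  hm <- histogramMatrix(co$samples, brandA)
  tmpl <- detectPeaks(new("HistogramFeature", indexName = "GMRN",
                          binEdges = seq(-1, 1, length.out = 257),
                          percentages = colMeans(hm) / sum(colMeans(hm)) * 100))
  sel <- selectRegion(binCorrelations(hm, co$samples$leaf_n), tmpl, "leaf_n")
  fmA <- buildFeatureMatrix(co$samples, brandA, mode = "IIH", selection = sel)
  fit <- fitDiagnosisModel(fmA, "leaf_n", config = mlpConfig(seed = 1L),
                           restarts = 2L)
  fmB <- buildFeatureMatrix(co$samples, brandB, mode = "IIH", selection = sel)
  mB <- mape(co$samples$leaf_n, predict(fit, fmB))
  expect_true(is.finite(mB))
  expect_gt(mB, 0)
})

test_that("equal-mean pairs separate coverage from hue by construction", {
  pair <- equalMeanDistinctCoveragePair(coverages = c(0.3, 0.6))
  expect_lt(abs(diff(pair$gmrnMeans)), 1e-3)
  expect_gte(abs(diff(pair$coverages)), 0.2)
  pair2 <- equalMeanDistinctCoveragePair(coverages = c(0.25, 0.7),
                                         targetMean = 0.03)
  expect_lt(abs(diff(pair2$gmrnMeans)), 1e-3)
  expect_error(equalMeanDistinctCoveragePair(coverages = c(0.4, 0.4)),
               "degenerate")
  expect_error(equalMeanDistinctCoveragePair(coverages = c(0.05, 0.95),
                                             targetMean = 0.4),
               "infeasible")
})

test_that("cohorts written to disk round-trip through the sample table", {
  d <- withr::local_tempdir()
  co <- generateCohort(scenarioConfig(
    seed = 17, cultivars = c("cvA", "cvB"), nLevels = c(0, 240),
    replicates = 2L, imageSize = c(32L, 32L)), dir = d)
  expect_true(file.exists(file.path(d, "samples.csv")))
  expect_true(file.exists(file.path(d, "ground_truth.csv")))
  expect_true(file.exists(file.path(d, "scenario.yaml")))
  df <- readSampleTable(file.path(d, "samples.csv"))
  expect_equal(nrow(df), 8L)
  im <- readCanopyImage(df$image_path[3])
  expect_identical(pixelData(im), pixelData(co$images[[df$sample_id[3]]]))
})
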