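# pure-optimizer configs: early stopping off isolates the LM machinery
lmOnly <- function(...) mlpConfig(..., earlyStopFraction = 0)

test_that("weight initialization is seeded, shaped and Nguyen-Widrow scaled", {
  cfg <- mlpConfig(nHidden = 10L, seed = 42L)
  m1 <- initWeights(cfg, 6L)
  m2 <- initWeights(cfg, 6L)
  expect_identical(modelWeights(m1), modelWeights(m2))
  expect_equal(dim(modelWeights(m1)$W1), c(10L, 6L))
  cfg2 <- mlpConfig(nHidden = 10L, seed = 43L)
  expect_false(identical(modelWeights(m1), modelWeights(initWeights(cfg2, 6L))))
  beta <- 0.7 * 10^(1 / 6)
  expect_equal(sqrt(rowSums(modelWeights(m1)$W1^2)), rep(beta, 10),
               tolerance = 1e-12)
})

test_that("forward pass matches hand arithmetic and a loop oracle", {
  cfg <- lmOnly(nHidden = 1L, inputScaling = "none", outputScaling = "none")
  m <- initWeights(cfg, 1L)
  m@W1 <- matrix(0, 1, 1); m@b1 <- 0; m@W2 <- 0; m@b2 <- 0
  expect_equal(forward(m, matrix(c(-3, 0, 7))), c(0, 0, 0))
  m@W2 <- 2; m@b2 <- 1
  expect_equal(forward(m, matrix(0)), 2)          # 2 * sigmoid(0) + 1

  cfg2 <- lmOnly(nHidden = 2L, seed = 5L,
                 inputScaling = "none", outputScaling = "none")
  m2 <- initWeights(cfg2, 2L)
  set.seed(31)
  X <- matrix(rnorm(20), 10, 2)
  w <- modelWeights(m2)
  expect_equal(forward(m2, X), oracleForward(X, w$W1, w$b1, w$W2, w$b2),
               tolerance = 1e-12)
  expect_error(forward(m2, matrix(rnorm(30), 10, 3)), "mismatch")
})

test_that("predictions enforce the stored feature recipe", {
  set.seed(4)
  X <- matrix(runif(60, 1, 2), 20, 3,
              dimnames = list(NULL, c("fA", "fB", "fC")))
  y <- X[, 1] + 2 * X[, 2] + rnorm(20, 0, 0.01)
  fit <- fitDiagnosisModel(X, y, config = lmOnly(maxIter = 50L), restarts = 1L)
  p1 <- predict(fit, X)
  expect_identical(predict(fit, X), p1)           # bit-stable rescoring
  Xperm <- X[, c(2, 1, 3)]
  expect_error(forward(fit, Xperm), "recipe")
})

test_that("analytic Jacobian matches central finite differences", {
  cfg <- lmOnly(nHidden = 3L, seed = 7L,
                inputScaling = "none", outputScaling = "none")
  m <- initWeights(cfg, 2L)
  set.seed(11)
  X <- matrix(rnorm(12), 6, 2)
  theta <- canopyN:::.packWeights(m)
  fwd <- function(th) {
    w <- canopyN:::.unpackWeights(th, 3L, 2L)
    canopyN:::.forwardScaled(X, w$W1, w$b1, w$W2, w$b2)$yhat
  }
  out <- canopyN:::.forwardScaled(X, m@W1, m@b1, m@W2, m@b2)
  J <- canopyN:::.mlpJacobian(X, out$H, m@W2)
  eps <- 1e-6
  Jfd <- matrix(0, 6, length(theta))
  for (k in seq_along(theta)) {
    tp <- theta; tp[k] <- tp[k] + eps
    tm <- theta; tm[k] <- tm[k] - eps
    Jfd[, k] <- (fwd(tp) - fwd(tm)) / (2 * eps)
  }
  expect_lt(max(abs(J - Jfd)) / max(abs(Jfd)), 1e-6)
})

test_that("the LM step interpolates between Gauss-Newton and gradient descent", {
  cfg <- lmOnly(nHidden = 1L, seed = 3L,
                inputScaling = "none", outputScaling = "none")
  m <- initWeights(cfg, 1L)
  set.seed(2)
  X <- matrix(rnorm(8), 8, 1)
  y <- sin(X[, 1])
  out <- canopyN:::.forwardScaled(X, m@W1, m@b1, m@W2, m@b2)
  r <- out$yhat - y
  J <- canopyN:::.mlpJacobian(X, out$H, m@W2)
  A <- crossprod(J); g <- as.numeric(crossprod(J, r))
  step <- function(mu) solve(A + diag(mu, ncol(J)), g)
  gn <- solve(A, g)
  expect_equal(step(1e-12), gn, tolerance = 1e-6)
  big <- 1e10
  sgd <- step(big)
  expect_equal(sgd * big, g, tolerance = 1e-4)    # scaled gradient direction
  cosang <- sum(sgd * g) / sqrt(sum(sgd^2) * sum(g^2))
  expect_gt(cosang, 1 - 1e-9)
})

test_that("accepted-step losses decrease monotonically and maxIter=0 is a no-op", {
  set.seed(9)
  X <- matrix(rnorm(80), 40, 2)
  y <- X[, 1]^2 + 0.5 * X[, 2] + rnorm(40, 0, 0.05)
  cfg <- lmOnly(seed = 2L, maxIter = 100L)
  fit <- trainLM(initWeights(cfg, 2L), X, y)
  h <- trainingHistory(fit)
  expect_gt(length(h), 1L)
  expect_true(all(diff(h) < 0))

  cfg0 <- lmOnly(seed = 2L, maxIter = 0L)
  init <- initWeights(cfg0, 2L)
  fit0 <- trainLM(init, X, y)
  expect_identical(modelWeights(fit0), modelWeights(init))
  expect_length(trainingHistory(fit0), 1L)
})

test_that("LM drives realizable targets to the stated floors", {
  # noiseless affine map y = 3x + 1
  set.seed(13)
  x <- matrix(seq(-1, 1, length.out = 50), ncol = 1)
  y <- 3 * x[, 1] + 1
  fit <- fitDiagnosisModel(x, y, config = lmOnly(seed = 1L), restarts = 3L)
  expect_lt(rmse(y, predict(fit, x)), 1e-3)

  # target generated by a 1-hidden-unit teacher net: exactly realizable
  xt <- matrix(seq(-3, 3, length.out = 60), ncol = 1)
  yt <- 1 / (1 + exp(-xt[, 1]))
  cfgT <- lmOnly(seed = 1L, nHidden = 10L, maxIter = 300L,
                 inputScaling = "none", outputScaling = "none")
  fitT <- fitDiagnosisModel(xt, yt, config = cfgT, restarts = 3L)
  hT <- trainingHistory(fitT)
  expect_lt(hT[length(hT)], 1e-6)
  expect_lt(rmse(yt, predict(fitT, xt)), 1e-3)
})

test_that("training is deterministic end to end for a fixed config", {
  set.seed(77)
  X <- matrix(runif(90, 0, 1), 30, 3)
  y <- 2 + X %*% c(1, -2, 0.5) + rnorm(30, 0, 0.1)
  cfg <- mlpConfig(seed = 11L, maxIter = 60L)
  f1 <- fitDiagnosisModel(X, as.numeric(y), config = cfg, restarts = 2L)
  f2 <- fitDiagnosisModel(X, as.numeric(y), config = cfg, restarts = 2L)
  expect_identical(modelWeights(f1), modelWeights(f2))
  expect_identical(f1@chosenSeed, f2@chosenSeed)
})

test_that("models serialize to JSON and reload to identical predictions", {
  set.seed(19)
  X <- matrix(runif(60, 1, 3), 20, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  y <- X[, 1] * 2 + sqrt(X[, 2]) + rnorm(20, 0, 0.05)
  fit <- fitDiagnosisModel(X, y, config = mlpConfig(seed = 8L, maxIter = 80L),
                           restarts = 2L)
  f <- withr::local_tempfile(fileext = ".json")
  writeDiagnosisModel(fit, f)
  back <- readDiagnosisModel(f)
  expect_identical(predict(back, X), predict(fit, X))
  expect_identical(modelWeights(back), modelWeights(fit))
  expect_identical(back@config@nHidden, fit@config@nHidden)
})
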