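#' @include AllClasses.R
NULL

# --- scaling -----------------------------------------------------------------
# A scale recipe maps raw values onto the training space: x' = (x - center)/scale.
# minmax targets [-1, 1] (the classic companion of LM-MLP training); constant
# columns get scale 1 so they pass through unchanged.

.fitScale <- function(x, kind) {
  x <- as.matrix(x)
  if (kind == "none")
    return(list(kind = kind, center = rep(0, ncol(x)), scale = rep(1, ncol(x))))
  if (kind == "minmax") {
    lo <- apply(x, 2, min); hi <- apply(x, 2, max)
    center <- (lo + hi) / 2
    scale <- (hi - lo) / 2
  } else {                       # zscore
    center <- colMeans(x)
    scale <- apply(x, 2, stats::sd)
  }
  scale[scale == 0] <- 1
  list(kind = kind, center = center, scale = scale)
}

.applyScale <- function(x, sc) sweep(sweep(as.matrix(x), 2, sc$center), 2,
                                     sc$scale, "/")
.invertScale <- function(x, sc) x * sc$scale[1] + sc$center[1]

.sigmoid <- function(z) 1 / (1 + exp(-z))

.identityScale <- function(n) list(kind = "none", center = rep(0, n),
                                   scale = rep(1, n))

# --- initialization ----------------------------------------------------------

#' Initialize an untrained diagnosis MLP
#'
#' Draws hidden weights by the Nguyen-Widrow-style scaled-uniform scheme
#' (rows rescaled to norm \code{0.7 * nHidden^(1/nInputs)}, biases spread
#' over the active range) so sigmoid units start spread across the input
#' space. Deterministic for a given config seed; the caller's RNG stream is
#' left untouched.
#'
#' @param config an \linkS4class{MLPConfig}.
#' @param nInputs number of input features.
#' @return An untrained \linkS4class{DiagnosisModel} with identity scaling.
#' @export
initWeights <- function(config, nInputs) {
  stopifnot(is(config, "MLPConfig"))
  nInputs <- as.integer(nInputs)
  if (nInputs < 1L) stopf("nInputs must be >= 1")
  nh <- config@nHidden
  withSeed(config@seed, {
    W1 <- matrix(stats::runif(nh * nInputs, -0.5, 0.5), nh, nInputs)
    beta <- 0.7 * nh^(1 / nInputs)
    norms <- sqrt(rowSums(W1^2))
    norms[norms == 0] <- 1
    W1 <- W1 * (beta / norms)
    b1 <- stats::runif(nh, -beta, beta)
    W2 <- stats::runif(nh, -0.5, 0.5)
    b2 <- stats::runif(1, -0.5, 0.5)
  })
  new("DiagnosisModel", W1 = W1, b1 = b1, W2 = W2, b2 = b2,
      inputScale = .identityScale(nInputs), outputScale = .identityScale(1L),
      history = numeric(0), config = config, recipe = list(),
      trained = FALSE, chosenSeed = config@seed)
}

# --- forward pass and Jacobian ----------------------------------------------

.forwardScaled <- function(Xs, W1, b1, W2, b2) {
  H <- .sigmoid(sweep(Xs %*% t(W1), 2, b1, "+"))
  list(H = H, yhat = as.numeric(H %*% W2 + b2))
}

# Jacobian of per-sample outputs w.r.t. theta = c(vec(W1), b1, W2, b2)
# (column-major vec). Analytic backprop derivatives.
.mlpJacobian <- function(Xs, H, W2) {
  m <- nrow(Xs); nh <- ncol(H); ni <- ncol(Xs)
  Dw <- H * (1 - H) * matrix(W2, m, nh, byrow = TRUE)
  JW1 <- Dw[, rep(seq_len(nh), times = ni), drop = FALSE] *
    Xs[, rep(seq_len(ni), each = nh), drop = FALSE]
  cbind(JW1, Dw, H, rep(1, m))
}

.packWeights <- function(model) c(as.numeric(model@W1), model@b1,
                                  model@W2, model@b2)

.unpackWeights <- function(theta, nh, ni) {
  list(W1 = matrix(theta[seq_len(nh * ni)], nh, ni),
       b1 = theta[nh * ni + seq_len(nh)],
       W2 = theta[nh * ni + nh + seq_len(nh)],
       b2 = theta[nh * ni + 2L * nh + 1L])
}

#' Forward pass of a diagnosis MLP
#'
#' Computes \code{y = W2 . sigmoid(W1 x + b1) + b2} per sample in original
#' target units: the stored input scaling is applied to the raw features and
#' the inverse output scaling to the network output.
#'
#' @param model a \linkS4class{DiagnosisModel}.
#' @param X numeric matrix, samples x inputs; column count must match the
#'   model.
#' @return Numeric vector of predictions.
#' @export
forward <- function(model, X) {
  stopifnot(is(model, "DiagnosisModel"))
  X <- as.matrix(X)
  if (ncol(X) != ncol(model@W1))
    stopf("feature count mismatch: model expects %d inputs, got %d",
          ncol(model@W1), ncol(X))
  if (!all(is.finite(X))) stopf("inputs must be finite")
  fn <- model@recipe$featureNames
  if (!is.null(fn) && !is.null(colnames(X)) && !identical(colnames(X), fn))
    stopf("feature columns do not match the model's recipe (order matters): %s",
          paste(fn, collapse = ", "))
  Xs <- .applyScale(X, model@inputScale)
  out <- .forwardScaled(Xs, model@W1, model@b1, model@W2, model@b2)
  .invertScale(out$yhat, model@outputScale)
}

#' @describeIn forward S4 predict method; \code{newdata} may be a raw
#'   feature matrix or a \linkS4class{FeatureMatrix}.
#' @param object a \linkS4class{DiagnosisModel}.
#' @param newdata features to score.
#' @param ... ignored.
#' @export
setMethod("predict", "DiagnosisModel", function(object, newdata, ...) {
  if (is(newdata, "FeatureMatrix")) newdata <- featureValues(newdata)
  forward(object, newdata)
})

# --- Levenberg-Marquardt training -------------------------------------------

#' Train a diagnosis MLP by Levenberg-Marquardt least squares
#'
#' Fits input/output scaling on the training data, then iterates damped
#' Gauss-Newton steps on the sum-of-squares loss: solve
#' \code{(J'J + mu I) delta = J'r} with the analytic Jacobian \code{J} of the
#' residuals; a step is accepted (and \code{mu} multiplied by \code{muDec})
#' when it lowers the loss, otherwise \code{mu} is multiplied by
#' \code{muInc} and the step retried. Stops on the gradient tolerance, loss
#' tolerance, iteration cap, or damping overflow (\code{mu > 1e10}). The
#' history records the initial loss followed by every accepted loss, a
#' strictly nonincreasing sequence.
#'
#' When \code{earlyStopFraction > 0} (the default), a seeded holdout of that
#' fraction of the training samples is kept out of the optimized loss and
#' monitored after every accepted step; training stops after \code{maxFail}
#' consecutive accepted steps without holdout improvement and the weights
#' with the best holdout loss are returned. This mirrors the generalization
#' control of standard neural-network fitting tools and prevents the
#' interpolating nets an unregularized 10-unit LM fit produces on small
#' cohorts. The holdout is disabled automatically for tiny samples
#' (fewer than 12), and the accepted-loss history still refers to the
#' optimized subset.
#'
#' @param model an initialized \linkS4class{DiagnosisModel}
#'   (\code{\link{initWeights}}).
#' @param X training features, samples x inputs (raw units).
#' @param y training target (raw units), positive variance.
#' @return The trained \linkS4class{DiagnosisModel}.
#' @export
trainLM <- function(model, X, y) {
  stopifnot(is(model, "DiagnosisModel"))
  X <- as.matrix(X); y <- as.numeric(y)
  cfg <- model@config
  m <- nrow(X); ni <- ncol(model@W1); nh <- cfg@nHidden
  if (ncol(X) != ni) stopf("X has %d columns, model expects %d", ncol(X), ni)
  if (length(y) != m) stopf("y length must match nrow(X)")
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stopf("training data must be finite")
  if (stats::var(y) == 0) stopf("training target has zero variance")
  if (m < ni + 2L)
    warnf("only %d training samples for %d inputs; fit may be degenerate",
          m, ni)
  model@inputScale <- .fitScale(X, cfg@inputScaling)
  model@outputScale <- .fitScale(matrix(y, ncol = 1), cfg@outputScaling)
  if (!is.null(colnames(X)) && is.null(model@recipe$featureNames))
    model@recipe$featureNames <- colnames(X)
  XsAll <- .applyScale(X, model@inputScale)
  ysAll <- as.numeric(.applyScale(matrix(y, ncol = 1), model@outputScale))

  nHold <- round(cfg@earlyStopFraction * m)
  useES <- cfg@earlyStopFraction > 0 && nHold >= 2L && m >= 12L
  if (useES) {
    holdIdx <- withSeed(cfg@seed + 7919L, sort(sample.int(m, nHold)))
    fitIdx <- setdiff(seq_len(m), holdIdx)
  } else {
    fitIdx <- seq_len(m)
  }
  Xs <- XsAll[fitIdx, , drop = FALSE]; ys <- ysAll[fitIdx]

  theta <- .packWeights(model)
  np <- length(theta)
  evalLoss <- function(th) {
    w <- .unpackWeights(th, nh, ni)
    out <- .forwardScaled(Xs, w$W1, w$b1, w$W2, w$b2)
    r <- out$yhat - ys
    list(w = w, H = out$H, r = r, loss = sum(r * r))
  }
  holdLoss <- function(th) {
    w <- .unpackWeights(th, nh, ni)
    out <- .forwardScaled(XsAll[holdIdx, , drop = FALSE],
                          w$W1, w$b1, w$W2, w$b2)
    sum((out$yhat - ysAll[holdIdx])^2)
  }
  cur <- evalLoss(theta)
  if (!is.finite(cur$loss))
    stopf("non-finite loss at initialization; check scaling and inputs")
  history <- cur$loss
  bestTheta <- theta
  bestHold <- if (useES) holdLoss(theta) else Inf
  fails <- 0L
  mu <- cfg@mu0
  muMax <- 1e10
  iter <- 0L
  while (iter < cfg@maxIter && cur$loss >= cfg@lossTol) {
    J <- .mlpJacobian(Xs, cur$H, cur$w$W2)
    g <- as.numeric(crossprod(J, cur$r))
    if (max(abs(2 * g)) < cfg@gradTol) break
    A <- crossprod(J)
    accepted <- FALSE
    while (!accepted && mu <= muMax) {
      delta <- tryCatch({
        R <- chol(A + diag(mu, np))
        backsolve(R, forwardsolve(t(R), g))
      }, error = function(e) NULL)
      if (is.null(delta)) { mu <- mu * cfg@muInc; next }  # singular: damp more
      cand <- evalLoss(theta - delta)
      if (is.finite(cand$loss) && cand$loss < cur$loss) {
        theta <- theta - delta
        cur <- cand
        mu <- mu * cfg@muDec
        history <- c(history, cur$loss)
        accepted <- TRUE
      } else {
        mu <- mu * cfg@muInc
      }
    }
    if (!accepted) break                     # damping overflow: converged
    iter <- iter + 1L
    if (useES) {
      hl <- holdLoss(theta)
      if (hl < bestHold) {
        bestHold <- hl
        bestTheta <- theta
        fails <- 0L
      } else {
        fails <- fails + 1L
        if (fails >= cfg@maxFail) break
      }
    }
  }
  if (useES) {
    theta <- bestTheta
    attr(history, "holdoutLoss") <- bestHold
  }
  w <- .unpackWeights(theta, nh, ni)
  model@W1 <- w$W1; model@b1 <- w$b1; model@W2 <- w$W2; model@b2 <- w$b2
  model@history <- history
  model@trained <- TRUE
  model
}

#' Fit a diagnosis model with multi-start Levenberg-Marquardt
#'
#' LM on a nonconvex loss is sensitive to initialization, so the network is
#' trained from \code{restarts} seeded initializations
#' (seeds \code{config seed + 0:(restarts-1)}) and the fit with the lowest
#' final training loss is kept; the chosen seed is recorded in the model.
#'
#' @param features a \linkS4class{FeatureMatrix} or a raw numeric matrix.
#' @param target \code{"leaf_n"} or \code{"yield"} when \code{features} is a
#'   \linkS4class{FeatureMatrix}; otherwise a numeric vector of targets.
#' @param config an \linkS4class{MLPConfig}.
#' @param restarts number of seeded restarts (default 5).
#' @return The best trained \linkS4class{DiagnosisModel}.
#' @export
fitDiagnosisModel <- function(features, target = "leaf_n",
                              config = mlpConfig(), restarts = 5L) {
  if (is(features, "FeatureMatrix")) {
    tn <- match.arg(target, c("leaf_n", "yield"))
    X <- featureValues(features)
    y <- targets(features)[[tn]]
    if (anyNA(y))
      stopf("target '%s' is missing for samples: %s", tn,
            paste(rownames(X)[is.na(y)], collapse = ", "))
    recipe <- list(featureNames = colnames(X), mode = features@mode,
                   target = tn)
    if (features@mode == "IIH") {
      recipe$selection <- features@recipe$selection
    } else {
      recipe$indexSet <- features@recipe$indexSet
      recipe$useVegetationMask <- features@recipe$useVegetationMask
    }
  } else {
    X <- as.matrix(features)
    y <- as.numeric(target)
    recipe <- list(featureNames = colnames(X), mode = "raw", target = "y")
  }
  score <- function(fit) {
    hl <- attr(fit@history, "holdoutLoss")
    if (!is.null(hl)) hl else fit@history[length(fit@history)]
  }
  best <- NULL
  for (k in seq_len(max(1L, as.integer(restarts)))) {
    cfgK <- config
    cfgK@seed <- config@seed + k - 1L
    fit <- trainLM(initWeights(cfgK, ncol(X)), X, y)
    if (is.null(best) || score(fit) < score(best)) {
      best <- fit
      best@chosenSeed <- cfgK@seed
    }
  }
  best@recipe <- recipe
  best
}

# --- serialization -----------------------------------------------------------

.selectionToList <- function(sel) {
  if (is.null(sel)) return(NULL)
  list(indexName = sel@indexName, binIndices = sel@binIndices,
       correlations = sel@correlations, targetName = sel@targetName,
       binEdges = sel@binEdges, policy = sel@policy, params = sel@params)
}

.selectionFromList <- function(obj) {
  if (is.null(obj)) return(NULL)
  pk <- function(x) if (is.null(x) || is.na(x)) NA_integer_ else as.integer(x)
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

#' Save / load a diagnosis model as JSON
#'
#' Weights, scalings, config, training history and the feature recipe are
#' serialized with 17 significant digits, so a reloaded model reproduces
#' predictions bit-identically.
#'
#' @param model a \linkS4class{DiagnosisModel}.
#' @param path .json path.
#' @return \code{writeDiagnosisModel}: the path, invisibly;
#'   \code{readDiagnosisModel}: the model.
#' @export
writeDiagnosisModel <- function(model, path) {
  stopifnot(is(model, "DiagnosisModel"))
  cfg <- model@config
  recipe <- model@recipe
  if (!is.null(recipe$selection))
    recipe$selection <- .selectionToList(recipe$selection)
  obj <- list(
    W1 = model@W1, b1 = model@b1, W2 = model@W2, b2 = model@b2,
    inputScale = model@inputScale, outputScale = model@outputScale,
    history = model@history,
    config = list(nHidden = cfg@nHidden, maxIter = cfg@maxIter, mu0 = cfg@mu0,
                  muInc = cfg@muInc, muDec = cfg@muDec, gradTol = cfg@gradTol,
                  lossTol = cfg@lossTol, seed = cfg@seed,
                  inputScaling = cfg@inputScaling,
                  outputScaling = cfg@outputScaling,
                  earlyStopFraction = cfg@earlyStopFraction,
                  maxFail = cfg@maxFail),
    recipe = recipe, trained = model@trained, chosenSeed = model@chosenSeed)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor", null = "null", na = "null")
  invisible(path)
}

#' @rdname writeDiagnosisModel
#' @export
readDiagnosisModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- mlpConfig(nHidden = obj$config$nHidden, maxIter = obj$config$maxIter,
                   mu0 = obj$config$mu0, muInc = obj$config$muInc,
                   muDec = obj$config$muDec, gradTol = obj$config$gradTol,
                   lossTol = obj$config$lossTol, seed = obj$config$seed,
                   inputScaling = obj$config$inputScaling,
                   outputScaling = obj$config$outputScaling,
                   earlyStopFraction = obj$config$earlyStopFraction,
                   maxFail = obj$config$maxFail)
  recipe <- obj$recipe
  if (!is.null(recipe$selection))
    recipe$selection <- .selectionFromList(recipe$selection)
  asScale <- function(s) list(kind = s$kind, center = as.numeric(s$center),
                              scale = as.numeric(s$scale))
  W1 <- obj$W1
  if (!is.matrix(W1)) W1 <- matrix(W1, nrow = cfg@nHidden)
  new("DiagnosisModel", W1 = W1, b1 = as.numeric(obj$b1),
      W2 = as.numeric(obj$W2), b2 = as.numeric(obj$b2),
      inputScale = asScale(obj$inputScale),
      outputScale = asScale(obj$outputScale),
      history = as.numeric(obj$history), config = cfg, recipe = recipe,
      trained = isTRUE(obj$trained), chosenSeed = as.integer(obj$chosenSeed))
}
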