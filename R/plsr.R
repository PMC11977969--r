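# NIPALS PLS1 core. For a univariate response the inner NIPALS loop
# converges in a single pass (w = E'u / ||E'u|| with u = y), so each
# component reduces to closed-form cross-products; the generic iterative
# form is kept with a tight tolerance for robustness.
.pls1 <- function(X, y, nLV, tol = 1e-12, maxInner = 500L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  xMean <- colMeans(X)
  yMean <- mean(y)
  E <- sweep(X, 2, xMean)
  f <- y - yMean
  W <- matrix(0, p, nLV); P <- matrix(0, p, nLV)
  q <- numeric(nLV); Tm <- matrix(0, n, nLV)
  a <- 0L
  for (comp in seq_len(nLV)) {
    u <- f
    w <- crossprod(E, u)[, 1]
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break              # residual X information exhausted
    w <- w / nw
    tvec <- E %*% w
    for (it in seq_len(maxInner)) {    # converges immediately for PLS1
      tt <- sum(tvec^2)
      if (tt < 1e-300) break
      qa <- sum(f * tvec) / tt
      uNew <- f * qa
      wNew <- crossprod(E, uNew)[, 1]
      nwn <- sqrt(sum(wNew^2))
      if (nwn < 1e-12) break
      wNew <- wNew / nwn
      tNew <- E %*% wNew
      if (sum((tNew - tvec)^2) / max(sum(tvec^2), 1e-300) < tol^2) {
        w <- wNew; tvec <- tNew; break
      }
      w <- wNew; tvec <- tNew
    }
    tt <- sum(tvec^2)
    if (tt < 1e-300) break
    pv <- crossprod(E, tvec)[, 1] / tt
    qa <- sum(f * tvec) / tt
    E <- E - tcrossprod(tvec, pv)
    f <- f - qa * tvec
    a <- comp
    W[, a] <- w; P[, a] <- pv; q[a] <- qa; Tm[, a] <- tvec
  }
  if (a == 0L) stop("degenerate error: X has no variance to model")
  W <- W[, seq_len(a), drop = FALSE]; P <- P[, seq_len(a), drop = FALSE]
  q <- q[seq_len(a)]; Tm <- Tm[, seq_len(a), drop = FALSE]
  # regression vectors in original X space for every truncation 1..a
  coefPath <- matrix(0, p, a)
  for (k in seq_len(a)) {
    Rk <- W[, seq_len(k), drop = FALSE] %*%
      solve(crossprod(P[, seq_len(k), drop = FALSE], W[, seq_len(k), drop = FALSE]),
            diag(k))
    coefPath[, k] <- Rk %*% q[seq_len(k)]
  }
  list(nLV = a, xMean = xMean, yMean = yMean, W = W, P = P, q = q,
       scores = Tm, coefPath = coefPath)
}

#' Fit a PLSR calibration model (NIPALS)
#'
#' Mean-centers X and y, extracts `nLV` latent variables by NIPALS with
#' deflation, and assembles the regression vector in the original X space.
#' If the X residual is exhausted before `nLV` components (exact low-rank
#' data) the model retains the achievable number.
#'
#' @param X n x p matrix (samples x channels).
#' @param y length-n response vector.
#' @param nLV number of latent variables, 1 <= nLV <= min(n - 1, p).
#' @return A [PLSRModel-class].
#' @export
plsFit <- function(X, y, nLV) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n < 2) stop("size error: need n >= 2")
  if (length(y) != n) stop("shape error: length(y) must equal nrow(X)")
  nLV <- as.integer(nLV)
  if (is.na(nLV) || nLV < 1 || nLV > min(n - 1, p))
    stop("parameter error: nLV must satisfy 1 <= nLV <= min(n - 1, p)")
  if (var(y) == 0) stop("degenerate error: zero-variance response")
  fit <- .pls1(X, y, nLV)
  methods::new("PLSRModel",
               nLV = as.integer(fit$nLV), xMean = fit$xMean, yMean = fit$yMean,
               weights = fit$W, xLoadings = fit$P, yLoadings = fit$q,
               coefficients = as.numeric(fit$coefPath[, fit$nLV]),
               coefPath = fit$coefPath, scores = fit$scores)
}

#' Predict from a fitted PLSR model
#'
#' @param model a [PLSRModel-class].
#' @param X m x p matrix with the training channel count.
#' @param nLV optionally predict with a truncated model (1..model nLV).
#' @return numeric vector of m predictions,
#'   yhat = (X - xMean) b + yMean.
#' @export
plsPredict <- function(model, X, nLV = NULL) {
  stopifnot(is(model, "PLSRModel"))
  X <- as.matrix(X)
  if (ncol(X) != length(model@xMean))
    stop("shape error: X has ", ncol(X), " columns; model expects ",
         length(model@xMean))
  b <- if (is.null(nLV)) model@coefficients else {
    nLV <- as.integer(nLV)
    if (nLV < 1 || nLV > model@nLV) stop("parameter error: nLV out of range")
    model@coefPath[, nLV]
  }
  as.numeric(sweep(X, 2, model@xMean) %*% b + model@yMean)
}

#' k-fold cross-validated RMSE over a latent-variable grid
#'
#' Samples are partitioned into k seeded random folds of near-equal size;
#' for each fold a model is fitted on the remainder and held-out predictions
#' are pooled. RMSECV(L) is reported for L = 1..nLV and the minimiser is
#' returned (ties broken toward fewer latent variables).
#'
#' @param X n x p matrix; @param y length-n response.
#' @param nLV largest latent-variable count to evaluate.
#' @param k number of folds (default 5).
#' @param seed RNG seed for the fold assignment.
#' @param folds optional explicit fold labels (overrides `seed`).
#' @return list of class `"CVResult"`: `rmsecvPerLV`, `bestLV`, `seed`,
#'   `folds`.
#' @export
kfoldRMSECV <- function(X, y, nLV, k = 5L, seed = 1L, folds = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (is.null(folds)) folds <- foldAssignment(n, k, seed)
  k <- max(folds)
  minTrain <- n - max(tabulate(folds, k))
  maxA <- min(as.integer(nLV), minTrain - 1L, ncol(X))
  if (maxA < 1)
    stop("parameter error: nLV too large for the smallest training fold")
  sse <- numeric(maxA)
  used <- rep(TRUE, maxA)
  for (fold in seq_len(k)) {
    test <- folds == fold
    fit <- .pls1(X[!test, , drop = FALSE], y[!test], maxA)
    for (L in seq_len(maxA)) {
      Lf <- min(L, fit$nLV)
      pred <- sweep(X[test, , drop = FALSE], 2, fit$xMean) %*%
        fit$coefPath[, Lf] + fit$yMean
      sse[L] <- sse[L] + sum((y[test] - pred)^2)
    }
  }
  rmsecv <- sqrt(sse / n)
  best <- which.min(rmsecv)            # which.min takes the first minimum
  structure(list(rmsecvPerLV = rmsecv, bestLV = as.integer(best),
                 seed = as.integer(seed), folds = folds),
            class = "CVResult")
}

#' Calibration performance metrics: RMSE, R-squared, RPD
#'
#' RMSE = sqrt(mean((y - yhat)^2)); R2 = 1 - SSres/SStot. The ratio of
#' performance to deviation follows the chemometrics convention
#' RPD = sd(y) / RMSE with the sample (n - 1) standard deviation
#' (`rpdMode = "sd_ratio"`, default); `"closed_form"` gives the algebraic
#' variant 1 / sqrt(1 - R2). A perfect fit reports RPD = Inf rather than
#' erroring.
#'
#' @param yTrue,yPred numeric vectors of equal length >= 2.
#' @param rpdMode `"sd_ratio"` or `"closed_form"`.
#' @return list of class `"calibrationMetrics"` with `rmse`, `r2`, `rpd`, `n`.
#' @export
calibrationMetrics <- function(yTrue, yPred, rpdMode = c("sd_ratio", "closed_form")) {
  rpdMode <- match.arg(rpdMode)
  yTrue <- as.numeric(yTrue); yPred <- as.numeric(yPred)
  n <- length(yTrue)
  if (length(yPred) != n) stop("shape error: length mismatch")
  if (n < 2) stop("size error: need n >= 2")
  rmse <- sqrt(mean((yTrue - yPred)^2))
  sstot <- sum((yTrue - mean(yTrue))^2)
  if (sstot == 0) stop("degenerate error: zero variance in yTrue; R2/RPD undefined")
  r2 <- 1 - sum((yTrue - yPred)^2) / sstot
  rpd <- if (rmse == 0) Inf
  else if (rpdMode == "sd_ratio") sd(yTrue) / rmse
  else if (r2 >= 1) Inf
  else 1 / sqrt(1 - r2)
  structure(list(rmse = rmse, r2 = r2, rpd = rpd, n = n, rpdMode = rpdMode),
            class = "calibrationMetrics")
}

#' @export
print.calibrationMetrics <- function(x, ...) {
  cat(sprintf("RMSE %.4g | R2 %.4f | RPD %s (n = %d, %s)\n",
              x$rmse, x$r2, format(round(x$rpd, 4)), x$n, x$rpdMode))
  invisible(x)
}

#' Serialize / restore a PLSRModel as JSON
#'
#' @param model a [PLSRModel-class]; @param path JSON file path.
#' @return `writePLSRModel`: `path` invisibly; `readPLSRModel`: the model.
#' @export
writePLSRModel <- function(model, path) {
  stopifnot(is(model, "PLSRModel"))
  obj <- list(nLV = model@nLV, xMean = model@xMean, yMean = model@yMean,
              weights = model@weights, xLoadings = model@xLoadings,
              yLoadings = model@yLoadings, coefficients = model@coefficients,
              coefPath = model@coefPath)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, matrix = "columnmajor")
  invisible(path)
}

#' @rdname writePLSRModel
#' @export
readPLSRModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  asMat <- function(m, p) matrix(as.numeric(m), nrow = p)
  p <- length(obj$xMean)
  methods::new("PLSRModel",
               nLV = as.integer(obj$nLV), xMean = as.numeric(obj$xMean),
               yMean = as.numeric(obj$yMean),
               weights = asMat(obj$weights, p), xLoadings = asMat(obj$xLoadings, p),
               yLoadings = as.numeric(obj$yLoadings),
               coefficients = as.numeric(obj$coefficients),
               coefPath = asMat(obj$coefPath, p),
               scores = matrix(numeric(0), 0, 0))
}
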