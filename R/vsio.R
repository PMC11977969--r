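#' Configuration for the HSIC-VSIO wavelength selector
#'
#' @param M rows of the weighted binary sampling matrix (candidate channel
#'   subsets per iteration); the reference setting is 1000.
#' @param sigma fraction in (0, 1] of top-ranked models that define the
#'   occurrence frequencies; reference setting 0.10.
#' @param K number of channels finally selected (reference setting 20).
#' @param nLV PLSR latent variables used when scoring subsets (reference 10;
#'   automatically capped by fold training size and subset width).
#' @param cvFolds folds for RMSECV scoring (reference 5).
#' @param kernel [kernelSpec()] for the HSIC importances.
#' @param importanceLV latent variables of the full-spectrum model used for
#'   the leave-one-channel-out importances. A parsimonious model (default 4)
#'   is deliberate: with a generous dimensionality the refit reabsorbs the
#'   removed channel's information through correlated neighbours and the
#'   contrast vanishes.
#' @param importanceTransform how raw importances become the \[0, 1\] vector
#'   T' blended into the weights: `"deviation"` (default) min-max scales the
#'   magnitude of the log importance ratio — uninformative channels cluster
#'   at WI = 1 and informative ones deviate in either direction, so the
#'   distance from 1 is the discriminating signal; `"ratio"` divides by the
#'   maximum (see [normalizeImportance()]).
#' @param patience stop after this many consecutive iterations without
#'   improvement of the best minRMSECV; the minimum over M sampled models is
#'   a noisy extreme statistic, so requiring a run of non-improvements is a
#'   far more reliable convergence signal than a single one.
#' @param maxOuterIter hard cap on iterations.
#' @param recomputeImportance recompute the HSIC importances T each iteration
#'   (default FALSE: T is computed once from the full data).
#' @param seed integer seed governing sampling and fold assignment.
#' @return list of class `"VSIOConfig"`.
#' @export
vsioConfig <- function(M = 1000L, sigma = 0.10, K = 20L, nLV = 10L,
                       cvFolds = 5L, kernel = kernelSpec(),
                       importanceLV = 4L,
                       importanceTransform = c("deviation", "ratio"),
                       patience = 3L, maxOuterIter = 30L,
                       recomputeImportance = FALSE,
                       seed = 1L) {
  M <- as.integer(M); K <- as.integer(K)
  importanceTransform <- match.arg(importanceTransform)
  if (M < 10) stop("parameter error: M must be >= 10")
  if (sigma <= 0 || sigma > 1) stop("parameter error: sigma must be in (0, 1]")
  if (round(M * sigma) < 1) stop("parameter error: round(M * sigma) must be >= 1")
  if (K < 1) stop("parameter error: K must be >= 1")
  if (patience < 1) stop("parameter error: patience must be >= 1")
  structure(list(M = M, sigma = sigma, K = K, nLV = as.integer(nLV),
                 cvFolds = as.integer(cvFolds), kernel = kernel,
                 importanceLV = as.integer(importanceLV),
                 importanceTransform = importanceTransform,
                 patience = as.integer(patience),
                 maxOuterIter = as.integer(maxOuterIter),
                 recomputeImportance = isTRUE(recomputeImportance),
                 seed = as.integer(seed)),
            class = "VSIOConfig")
}

# raw importances -> T' in [0, 1] per the configured transform
transformImportance <- function(T, transform) {
  if (transform == "ratio") return(normalizeImportance(T))
  d <- abs(log(pmax(T, 1e-12)))
  rng <- max(d) - min(d)
  if (rng <= 0) return(rep(0, length(d)))
  (d - min(d)) / rng
}

#' Weighted binary matrix sampling
#'
#' Builds an M x p 0/1 matrix whose column i carries exactly
#' `round(M * w_i)` ones, placed uniformly at random without replacement
#' among the M rows. Each row is a candidate channel subset; a row that ends
#' up empty is redrawn entrywise as Bernoulli(w) (up to 100 attempts) so
#' every sampled model contains at least one channel.
#'
#' @param weights length-p vector of channel weights in \[0, 1\].
#' @param M number of rows (candidate models).
#' @param seed RNG seed.
#' @return M x p integer matrix of 0/1.
#' @export
wbmsSample <- function(weights, M, seed = 1L) {
  w <- as.numeric(weights)
  if (any(w < 0 | w > 1)) stop("parameter error: weights must lie in [0, 1]")
  M <- as.integer(M)
  p <- length(w)
  withSeed(seed, {
    B <- matrix(0L, M, p)
    ones <- as.integer(round(M * w))
    for (i in seq_len(p)) if (ones[i] > 0)
      B[sample.int(M, ones[i]), i] <- 1L
    empty <- which(rowSums(B) == 0)
    for (r in empty) {
      for (attempt in seq_len(100L)) {
        row <- as.integer(rbinom(p, 1L, w))
        if (sum(row) > 0) { B[r, ] <- row; break }
        if (attempt == 100L)
          stop("sampling error: could not draw a non-empty model row ",
               "(weights are all ~0)")
      }
    }
    B
  })
}

#' HSIC wavelength importance
#'
#' Fits the full-spectrum PLSR model and, for each channel m, the model with
#' channel m removed; the importance of channel m is the ratio of the HSIC
#' dependence between the response and the leave-one-channel-out training
#' residuals to the dependence between the response and the full-model
#' residuals: WI_m = HSIC(y, eps_m) / HSIC(y, eps_full). Removing an
#' informative channel leaves response structure in the residuals, inflating
#' the ratio.
#'
#' @param X n x p matrix; @param y length-n response.
#' @param nLV latent variables for the PLSR fits (capped at min(n-1, p-1)).
#' @param kernel [kernelSpec()] used for both HSIC arguments.
#' @return length-p non-negative vector T of importances.
#' @export
wavelengthImportance <- function(X, y, nLV = 10L, kernel = kernelSpec()) {
  X <- as.matrix(X); y <- as.numeric(y)
  p <- ncol(X)
  if (p < 2) stop("parameter error: need p >= 2 channels")
  A <- min(as.integer(nLV), nrow(X) - 1L, p - 1L)
  full <- .pls1(X, y, A)
  epsFull <- y - as.numeric(sweep(X, 2, full$xMean) %*%
                              full$coefPath[, full$nLV] + full$yMean)
  if (sd(epsFull) < 1e-10 * max(1, sd(y)))
    stop("importance-undefined error: full model fits (numerically) perfectly, ",
         "so HSIC(y, eps_full) ~ 0; reduce nLV or add noise")
  hFull <- empiricalHSIC(y, epsFull, kernel, kernel)
  if (hFull <= 0)
    stop("importance-undefined error: full model fits perfectly ",
         "(HSIC(y, eps_full) = 0); reduce nLV or add noise")
  vapply(seq_len(p), function(m) {
    fit <- .pls1(X[, -m, drop = FALSE], y, A)
    eps <- y - as.numeric(sweep(X[, -m, drop = FALSE], 2, fit$xMean) %*%
                            fit$coefPath[, fit$nLV] + fit$yMean)
    empiricalHSIC(y, eps, kernel, kernel) / hFull
  }, numeric(1))
}

#' Normalize importances to \[0, 1\]
#'
#' Division by the maximum, so the most important channel maps to 1 and the
#' normalised importances are commensurate with occurrence frequencies.
#'
#' @param T non-negative numeric vector with max(T) > 0.
#' @return T / max(T).
#' @export
normalizeImportance <- function(T) {
  T <- as.numeric(T)
  if (any(T < 0)) stop("parameter error: importances must be non-negative")
  m <- max(T)
  if (m <= 0) stop("degenerate error: all importances are zero")
  T / m
}

#' Occurrence frequencies over the top-ranked sampled models
#'
#' Ranks the M sampled models by RMSECV (ascending, ties broken by row
#' index), keeps the top `round(M * sigma)` of them, and returns for each
#' channel the fraction of kept models that contain it,
#' f_i = N_i / round(M * sigma).
#'
#' @param binaryMatrix M x p 0/1 matrix from [wbmsSample()].
#' @param rmsecvValues length-M model scores.
#' @param sigma fraction in (0, 1].
#' @return length-p frequency vector Q in \[0, 1\].
#' @export
topModelFrequencies <- function(binaryMatrix, rmsecvValues, sigma) {
  B <- as.matrix(binaryMatrix)
  M <- nrow(B)
  if (length(rmsecvValues) != M) stop("shape error: one RMSECV per model row")
  nKeep <- as.integer(round(M * sigma))
  if (nKeep < 1) stop("parameter error: round(M * sigma) must be >= 1")
  keep <- order(rmsecvValues)[seq_len(nKeep)]   # stable: ties by row index
  colSums(B[keep, , drop = FALSE]) / nKeep
}

#' Weight update of the iterative selector
#'
#' Equal-parts blend of the normalised HSIC importances and the top-model
#' occurrence frequencies: W = 0.5 T' + 0.5 Q.
#'
#' @param Tn,Q length-p vectors in \[0, 1\].
#' @return length-p weight vector in \[0, 1\].
#' @export
updateWeights <- function(Tn, Q) {
  if (length(Tn) != length(Q)) stop("shape error: length mismatch")
  0.5 * as.numeric(Tn) + 0.5 * as.numeric(Q)
}

#' Run the HSIC-VSIO wavelength selector
#'
#' Variable Space Iterative Optimization: (i) the HSIC channel importances T
#' are computed once from the full calibration data and transformed to
#' T' in \[0, 1\] (see `importanceTransform` in [vsioConfig()]); (ii) all
#' channel weights start at 0.5; (iii) each iteration samples M candidate
#' channel subsets by WBMS, scores every subset by k-fold RMSECV of a PLSR
#' model on its channels (at the configured latent-variable count), records
#' the iteration's minimum RMSECV, derives the top-sigma occurrence
#' frequencies Q and updates W = 0.5 T' + 0.5 Q; (iv) iteration continues
#' while the best minRMSECV keeps improving and stops once it has failed to
#' improve for `patience` consecutive iterations (or at the cap); (v) the K
#' channels with the largest final weights are selected (ties go to the
#' lower channel index).
#'
#' One seeded fold partition is shared by all subset scorings within a run so
#' that RMSECV values are comparable across models and iterations.
#'
#' @param X n x p calibration matrix; @param y length-n response.
#' @param cfg a [vsioConfig()].
#' @return A [VSIOResult-class].
#' @export
runHsicVsio <- function(X, y, cfg = vsioConfig()) {
  stopifnot(inherits(cfg, "VSIOConfig"))
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (p < cfg$K) stop("parameter error: p < K (cannot select more channels than exist)")
  if (n < cfg$cvFolds) stop("parameter error: need n >= cvFolds")

  folds <- foldAssignment(n, cfg$cvFolds, deriveSeed(cfg$seed, 1L))
  Traw <- wavelengthImportance(X, y, cfg$importanceLV, cfg$kernel)
  Tn <- transformImportance(Traw, cfg$importanceTransform)

  W <- rep(0.5, p)
  trace <- numeric(0)
  bestOverall <- Inf
  bestChannels <- integer(0)
  sinceImprove <- 0L
  Qfinal <- rep(NA_real_, p)
  # RMSECV at the configured dimensionality (capped by subset width / fold
  # size), so subsets are compared at a fixed latent-variable count
  scoreModel <- function(cols) {
    cv <- tryCatch(
      kfoldRMSECV(X[, cols, drop = FALSE], y, cfg$nLV, folds = folds),
      error = function(e) NULL)
    if (is.null(cv)) return(NA_real_)
    cv$rmsecvPerLV[min(cfg$nLV, length(cv$rmsecvPerLV))]
  }

  for (I in seq_len(cfg$maxOuterIter)) {
    if (cfg$recomputeImportance && I > 1) {
      Traw <- wavelengthImportance(X, y, cfg$importanceLV, cfg$kernel)
      Tn <- transformImportance(Traw, cfg$importanceTransform)
    }
    B <- wbmsSample(W, cfg$M, seed = deriveSeed(cfg$seed, 100L + I))
    rms <- vapply(seq_len(cfg$M), function(r) scoreModel(which(B[r, ] == 1L)),
                  numeric(1))
    if (mean(!is.finite(rms)) > 0.5)
      stop("instability error: non-finite RMSECV in more than half the sampled models")
    rms[!is.finite(rms)] <- Inf
    minR <- min(rms)
    trace <- c(trace, minR)
    if (minR < bestOverall) {
      bestOverall <- minR
      bestChannels <- which(B[which.min(rms), ] == 1L)
      sinceImprove <- 0L
    } else {
      sinceImprove <- sinceImprove + 1L
    }
    Qfinal <- topModelFrequencies(B, rms, cfg$sigma)
    W <- updateWeights(Tn, Qfinal)
    if (sinceImprove >= cfg$patience) break
  }

  selOrder <- order(-W, seq_along(W))  # ties -> lower channel index
  selected <- sort(selOrder[seq_len(cfg$K)])
  methods::new("VSIOResult",
               importanceRaw = Traw, importanceNorm = Tn,
               frequencies = as.numeric(Qfinal), weights = W,
               rmsecvTrace = trace, selected = as.integer(selected),
               bestModelChannels = as.integer(bestChannels),
               seedUsed = cfg$seed, config = unclass(cfg))
}

#' @rdname runHsicVsio
#' @param result a [VSIOResult-class].
#' @export
selectedChannels <- function(result) {
  stopifnot(is(result, "VSIOResult"))
  result@selected
}
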