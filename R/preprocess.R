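#' AirPLS baseline correction
#'
#' Adaptive iteratively reweighted penalized least squares (Whittaker smoother
#' with a second-difference penalty). At each iteration the baseline z solves
#' (W + lambda D'D) z = W x; weights of points above the running baseline are
#' set to zero and points below are reweighted exponentially, so peaks are
#' progressively excluded while smooth background is tracked. Iteration stops
#' when the mass of negative residuals falls below `ratio` of the total
#' signal, or after `maxIter` sweeps.
#'
#' @param spectrum numeric intensity vector (length >= 5).
#' @param lambda smoothness penalty, > 0. Larger values give stiffer
#'   baselines; around 1e5 suits broad NIR backgrounds, 1e4 sharp SERS ones.
#' @param maxIter maximum reweighting iterations.
#' @param ratio convergence threshold on residual weight mass (default 1e-3,
#'   i.e. 0.1 percent of the total absolute signal).
#' @return list with `baseline` and `corrected` (= spectrum - baseline).
#' @export
airplsBaseline <- function(spectrum, lambda = 1e5, maxIter = 30L, ratio = 1e-3) {
  x <- as.numeric(spectrum)
  p <- length(x)
  if (p < 5) stop("parameter error: spectrum must have length >= 5")
  if (!all(is.finite(x))) stop("numeric error: non-finite input")
  if (!is.numeric(lambda) || lambda <= 0) stop("parameter error: lambda must be > 0")
  D <- Matrix::bandSparse(p - 2, p, k = 0:2,
                          diagonals = list(rep(1, p - 2), rep(-2, p - 2), rep(1, p - 2)))
  DtD <- lambda * Matrix::crossprod(D)
  w <- rep(1, p)
  z <- x
  total <- sum(abs(x))
  if (total == 0) return(list(baseline = x, corrected = x))
  for (it in seq_len(maxIter)) {
    Wm <- Matrix::Diagonal(p, w)
    z <- as.numeric(Matrix::solve(Wm + DtD, w * x))
    d <- x - z
    neg <- d < 0
    dssn <- sum(abs(d[neg]))
    if (dssn <= ratio * total || it == maxIter) break
    w[!neg] <- 0
    w[neg] <- exp(it * abs(d[neg]) / dssn)
    # pin the endpoints so the baseline cannot drift away at the edges
    w[1] <- exp(it * max(abs(d[neg])) / dssn)
    w[p] <- w[1]
  }
  list(baseline = z, corrected = x - z)
}

#' Multiplicative scatter correction
#'
#' Each spectrum x is regressed on a reference spectrum by ordinary least
#' squares, x ~ a + b * ref, and replaced by (x - a) / b, removing per-sample
#' additive offsets and multiplicative scaling caused by light scattering.
#'
#' @param X samples x channels matrix or [SpectrumSet-class].
#' @param reference `"mean"` (column mean of `X`, the usual choice) or an
#'   explicit numeric reference spectrum of matching length.
#' @return Same type as `X`, corrected. The fitted reference is attached as
#'   attribute `"reference"` when `X` is a matrix.
#' @export
mscCorrect <- function(X, reference = "mean") {
  if (is(X, "SpectrumSet")) {
    out <- mscCorrect(intensities(X), reference)
    return(replaceIntensities(X, out, "msc"))
  }
  X <- as.matrix(X)
  if (nrow(X) < 1) stop("degenerate-input error: need >= 1 spectrum")
  ref <- if (identical(reference, "mean")) colMeans(X) else as.numeric(reference)
  if (length(ref) != ncol(X))
    stop("shape error: reference length must equal channel count")
  refC <- ref - mean(ref)
  den <- sum(refC^2)
  out <- X
  for (i in seq_len(nrow(X))) {
    xi <- X[i, ]
    b <- sum((xi - mean(xi)) * refC) / den
    if (abs(b) < 1e-12)
      stop("degenerate-fit error: slope ~ 0 for spectrum ", i)
    a <- mean(xi) - b * mean(ref)
    out[i, ] <- (xi - a) / b
  }
  attr(out, "reference") <- ref
  out
}

#' Standard normal variate scaling
#'
#' Per-spectrum standardisation to mean 0 and (sample) standard deviation 1,
#' removing baseline offset and multiplicative spread.
#'
#' @param x numeric spectrum, samples x channels matrix, or
#'   [SpectrumSet-class].
#' @return Same type as `x`.
#' @export
snvScale <- function(x) {
  if (is(x, "SpectrumSet"))
    return(replaceIntensities(x, snvScale(intensities(x)), "snv"))
  if (is.matrix(x)) return(t(apply(x, 1, snvScale)))
  if (length(x) < 2) stop("degenerate-input error: need > 1 channel")
  s <- sd(x)
  if (s < .Machine$double.eps * max(1, abs(mean(x))) * 10 || s == 0)
    stop("degenerate-input error: zero-variance spectrum")
  (x - mean(x)) / s
}

#' Savitzky-Golay smoothing / differentiation
#'
#' Least-squares local polynomial convolution filter (via
#' [signal::sgolayfilt()]). Edge points are produced by the filter matrix
#' rows that fit the polynomial on the truncated (one-sided) window, so
#' polynomials of degree <= `order` are reproduced exactly everywhere.
#'
#' @param x numeric spectrum, samples x channels matrix, or
#'   [SpectrumSet-class].
#' @param window odd window length, > `order`.
#' @param order polynomial order.
#' @param deriv derivative order (0 = smoothing).
#' @return Same type as `x`.
#' @export
savgolFilter <- function(x, window = 11L, order = 2L, deriv = 0L) {
  if (is(x, "SpectrumSet"))
    return(replaceIntensities(x, savgolFilter(intensities(x), window, order, deriv),
                              sprintf("savgol(%d,%d,%d)", window, order, deriv)))
  if (is.matrix(x))
    return(t(apply(x, 1, savgolFilter, window = window, order = order, deriv = deriv)))
  window <- as.integer(window); order <- as.integer(order); deriv <- as.integer(deriv)
  if (window %% 2 == 0) stop("parameter error: window must be odd")
  if (window <= order) stop("parameter error: window must exceed polynomial order")
  if (deriv > order) stop("parameter error: deriv must be <= order")
  if (window >= length(x)) stop("parameter error: window must be shorter than the spectrum")
  signal::sgolayfilt(as.numeric(x), p = order, n = window, m = deriv)
}

#' Min-max intensity scaling to \[0, 1\]
#'
#' Scales intensities so the minimum maps to 0 and the maximum to 1, putting
#' modalities of very different raw magnitude on the same level before
#' fusion. `mode = "spectrum"` (default) scales each spectrum by its own
#' range; `mode = "set"` uses the global range of the whole matrix.
#'
#' @param X samples x channels matrix or [SpectrumSet-class].
#' @param mode `"spectrum"` or `"set"`.
#' @param bounds optional list(lo, hi) of previously fitted bounds
#'   (set mode only), to apply calibration scaling to prediction data.
#' @return Same type as `X`.
#' @export
minmaxScale <- function(X, mode = c("spectrum", "set"), bounds = NULL) {
  mode <- match.arg(mode)
  if (is(X, "SpectrumSet"))
    return(replaceIntensities(X, minmaxScale(intensities(X), mode, bounds),
                              paste0("minmax(", mode, ")")))
  X <- as.matrix(X)
  if (mode == "spectrum") {
    rng <- apply(X, 1, range)
    if (any(rng[2, ] - rng[1, ] <= 0))
      stop("degenerate-input error: constant spectrum cannot be min-max scaled")
    return((X - rng[1, ]) / (rng[2, ] - rng[1, ]))
  }
  if (is.null(bounds)) bounds <- list(lo = min(X), hi = max(X))
  if (bounds$hi - bounds$lo <= 0)
    stop("degenerate-input error: constant set cannot be min-max scaled")
  out <- (X - bounds$lo) / (bounds$hi - bounds$lo)
  attr(out, "bounds") <- bounds
  out
}

# swap the intensity matrix of a SpectrumSet, appending to the history
replaceIntensities <- function(set, X, historyTag = NULL) {
  X <- as.matrix(X)
  attr(X, "bounds") <- NULL
  attr(X, "reference") <- NULL
  stopifnot(all(dim(X) == dim(intensities(set))))
  assay <- t(X)
  dimnames(assay) <- dimnames(SummarizedExperiment::assay(set, "intensity"))
  SummarizedExperiment::assay(set, "intensity", withDimnames = FALSE) <- assay
  if (!is.null(historyTag))
    S4Vectors::metadata(set)$history <-
      c(S4Vectors::metadata(set)$history, historyTag)
  set
}

#' Build a preprocessing step / pipeline
#'
#' A pipeline is an ordered list of steps. Stateful steps (MSC reference,
#' set-mode min-max bounds) are fitted on calibration data only inside
#' [applyPipeline()] and applied unchanged to prediction data, so no
#' information leaks from the prediction set.
#'
#' Shipped presets: `"sg-snv-msc"` (default: Savitzky-Golay, SNV, MSC,
#' min-max — the combination that performs best for this workflow) and
#' `"airpls-msc-sg"` (AirPLS, MSC, Savitzky-Golay, min-max — the full
#' baseline-correction chain).
#'
#' @param kind one of `"AIRPLS"`, `"MSC"`, `"SNV"`, `"SAVGOL"`, `"MINMAX"`.
#' @param ... step parameters (see the corresponding operator).
#' @return `preprocessStep`: a step record; `pipelinePreset` /
#'   `preprocessPipeline`: a list of steps with class `"PreprocessPipeline"`.
#' @export
preprocessStep <- function(kind = c("AIRPLS", "MSC", "SNV", "SAVGOL", "MINMAX"), ...) {
  kind <- match.arg(kind)
  params <- list(...)
  if (kind == "SAVGOL") {
    params$window <- params$window %||% 11L
    params$order <- params$order %||% 2L
    params$deriv <- params$deriv %||% 0L
    if (params$window %% 2 == 0 || params$window <= params$order)
      stop("parameter error: SAVGOL window must be odd and > order")
  }
  if (kind == "AIRPLS") {
    params$lambda <- params$lambda %||% 1e5
    params$maxIter <- params$maxIter %||% 30L
    if (params$lambda <= 0) stop("parameter error: lambda must be > 0")
  }
  if (kind == "MINMAX") params$mode <- params$mode %||% "spectrum"
  if (kind == "MSC") params$reference <- params$reference %||% "mean"
  structure(list(kind = kind, params = params), class = "PreprocessStep")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname preprocessStep
#' @param steps list of `PreprocessStep` records.
#' @export
preprocessPipeline <- function(steps = list()) {
  stopifnot(all(vapply(steps, inherits, logical(1), "PreprocessStep")))
  structure(list(steps = steps), class = "PreprocessPipeline")
}

#' @rdname preprocessStep
#' @param preset preset name.
#' @param lambda AirPLS smoothness penalty used by the `"airpls-msc-sg"` preset.
#' @export
pipelinePreset <- function(preset = c("sg-snv-msc", "airpls-msc-sg"), lambda = 1e5) {
  preset <- match.arg(preset)
  steps <- switch(preset,
    "sg-snv-msc" = list(preprocessStep("SAVGOL"), preprocessStep("SNV"),
                        preprocessStep("MSC"), preprocessStep("MINMAX")),
    "airpls-msc-sg" = list(preprocessStep("AIRPLS", lambda = lambda),
                           preprocessStep("MSC"), preprocessStep("SAVGOL"),
                           preprocessStep("MINMAX")))
  preprocessPipeline(steps)
}

#' Fit a preprocessing pipeline on calibration data and apply it to both sets
#'
#' Steps are applied in order. The MSC reference (mean of the calibration
#' spectra at that point in the chain) and set-mode min-max bounds are
#' captured from the calibration data and reused verbatim for the prediction
#' data; per-spectrum steps carry no state. The applied chain is appended to
#' each set's preprocessing history.
#'
#' @param pipeline a `"PreprocessPipeline"`.
#' @param cal calibration [SpectrumSet-class] (nonempty).
#' @param pred optional prediction [SpectrumSet-class] on the same axis.
#' @return list with elements `cal` and `pred` (the latter `NULL` when not
#'   supplied).
#' @export
applyPipeline <- function(pipeline, cal, pred = NULL) {
  stopifnot(inherits(pipeline, "PreprocessPipeline"), is(cal, "SpectrumSet"))
  if (ncol(cal) < 1) stop("precondition error: calibration set is empty")
  if (!is.null(pred)) {
    stopifnot(is(pred, "SpectrumSet"))
    if (!isTRUE(all.equal(spectralAxis(cal), spectralAxis(pred))))
      stop("compatibility error: calibration and prediction axes differ")
  }
  for (step in pipeline$steps) {
    k <- step$kind
    p <- step$params
    if (k == "AIRPLS") {
      fn <- function(set) {
        X <- intensities(set)
        Xc <- t(apply(X, 1, function(row)
          airplsBaseline(row, lambda = p$lambda, maxIter = p$maxIter)$corrected))
        replaceIntensities(set, Xc, sprintf("airpls(%g)", p$lambda))
      }
      cal <- fn(cal); if (!is.null(pred)) pred <- fn(pred)
    } else if (k == "SNV") {
      cal <- snvScale(cal); if (!is.null(pred)) pred <- snvScale(pred)
    } else if (k == "SAVGOL") {
      cal <- savgolFilter(cal, p$window, p$order, p$deriv)
      if (!is.null(pred)) pred <- savgolFilter(pred, p$window, p$order, p$deriv)
    } else if (k == "MSC") {
      ref <- if (identical(p$reference, "mean")) colMeans(intensities(cal))
             else as.numeric(p$reference)
      cal <- replaceIntensities(cal, mscCorrect(intensities(cal), ref), "msc")
      if (!is.null(pred))
        pred <- replaceIntensities(pred, mscCorrect(intensities(pred), ref), "msc")
    } else if (k == "MINMAX") {
      if (p$mode == "spectrum") {
        cal <- minmaxScale(cal, "spectrum")
        if (!is.null(pred)) pred <- minmaxScale(pred, "spectrum")
      } else {
        Xc <- minmaxScale(intensities(cal), "set")
        b <- attr(Xc, "bounds")
        cal <- replaceIntensities(cal, Xc, "minmax(set)")
        if (!is.null(pred))
          pred <- replaceIntensities(pred,
            minmaxScale(intensities(pred), "set", bounds = b), "minmax(set)")
      }
    }
  }
  list(cal = cal, pred = pred)
}
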