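#' Prominence-ranked peak detection
#'
#' Finds local maxima of a single spectrum and ranks them by topographic
#' prominence: the drop from the peak apex to the higher of its two key
#' saddles (the lowest point separating it from higher terrain on each side;
#' the side minimum if no higher terrain exists). Peaks with prominence
#' below `minProminenceFrac` of the spectrum's dynamic range are discarded.
#' Positions are reported on the channel grid, without sub-channel
#' interpolation; an empty result is not an error.
#'
#' @param spectrum a single-sample [SpectrumSet-class], or a numeric
#'   intensity vector (then supply `axis`).
#' @param minProminenceFrac prominence threshold as a fraction of
#'   (max - min) intensity; default 0.05.
#' @param baselineCorrect apply [airplsBaseline()] first.
#' @param lambda AirPLS penalty used when `baselineCorrect = TRUE`.
#' @param axis channel positions when `spectrum` is a bare vector.
#' @return data.frame with columns `position`, `height`, `prominence`,
#'   sorted by prominence descending.
#' @export
detectPeaks <- function(spectrum, minProminenceFrac = 0.05,
                        baselineCorrect = FALSE, lambda = 1e4, axis = NULL) {
  if (is(spectrum, "SpectrumSet")) {
    if (ncol(spectrum) != 1)
      stop("parameter error: detectPeaks expects a single-sample set")
    axis <- spectralAxis(spectrum)
    x <- as.numeric(intensities(spectrum)[1, ])
  } else {
    x <- as.numeric(spectrum)
    if (is.null(axis)) axis <- seq_along(x)
  }
  if (length(x) < 5) stop("parameter error: need >= 5 channels")
  if (baselineCorrect) x <- airplsBaseline(x, lambda = lambda)$corrected
  n <- length(x)
  rng <- max(x) - min(x)
  empty <- data.frame(position = numeric(0), height = numeric(0),
                      prominence = numeric(0))
  if (rng == 0) return(empty)

  isPeak <- vapply(2:(n - 1), function(i) x[i] > x[i - 1] && x[i] > x[i + 1],
                   logical(1))
  idx <- which(isPeak) + 1L
  if (!length(idx)) return(empty)

  prominence <- vapply(idx, function(i) {
    h <- x[i]
    leftSeg <- x[seq_len(i - 1)]
    higherL <- which(leftSeg > h)
    baseL <- if (length(higherL)) min(x[(max(higherL) + 1):(i - 1)]) else min(leftSeg)
    rightSeg <- x[(i + 1):n]
    higherR <- which(rightSeg > h)
    baseR <- if (length(higherR)) min(x[(i + 1):(i + min(higherR) - 1)]) else min(rightSeg)
    h - max(baseL, baseR)
  }, numeric(1))

  keep <- prominence >= minProminenceFrac * rng
  out <- data.frame(position = axis[idx[keep]], height = x[idx[keep]],
                    prominence = prominence[keep])
  out[order(-out$prominence), , drop = FALSE]
}
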