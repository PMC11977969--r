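# small fixtures built in code

makeTinySet <- function(n = 3, p = 5, seed = 1, modality = "SERS",
                        conc = NULL, axis = NULL) {
  set.seed(seed)
  if (is.null(conc)) conc <- 10^-(seq_len(n) + 2)
  if (is.null(axis)) axis <- seq(400, 400 + 10 * (p - 1), length.out = p)
  SpectrumSet(matrix(round(rnorm(n * p), 6), n, p), axis = axis,
              concentrations = conc, modality = modality)
}

# n-level x r-replicate set with a y-informative channel for split/model tests
makeLeveledSet <- function(levels = 10^seq(-6, -3, length.out = 6), reps = 10,
                           p = 12, seed = 1) {
  set.seed(seed)
  conc <- rep(levels, each = reps)
  n <- length(conc)
  X <- matrix(rnorm(n * p, sd = 0.1), n, p)
  X[, 3] <- X[, 3] + log10(conc)
  SpectrumSet(X, axis = seq(500, 500 + 5 * (p - 1), 5), concentrations = conc,
              modality = "SERS")
}

# single synthetic spectrum with Gaussian peaks on a wavenumber axis
makePeakSpectrum <- function(centers, heights, width = 8,
                             axis = seq(400, 1800, by = 2), noise = 0,
                             baseline = 0, seed = 1) {
  set.seed(seed)
  x <- rep(baseline, length(axis))
  for (i in seq_along(centers))
    x <- x + heights[i] * exp(-(axis - centers[i])^2 / (2 * width^2))
  if (noise > 0) x <- x + rnorm(length(axis), 0, noise)
  list(axis = axis, intensity = x)
}
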