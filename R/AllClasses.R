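#' @import methods
#' @importFrom stats median sd var rnorm runif rbinom coef predict quantile
#' @importFrom utils unzip head tail
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors metadata DataFrame
NULL

#' SpectrumSet: a labelled spectral matrix
#'
#' Container for a set of spectra measured on a common channel grid, together
#' with per-sample analyte concentrations. It extends
#' [SummarizedExperiment::SummarizedExperiment] with channels as rows and
#' samples as columns: the channel axis (wavenumber in cm^-1 for Raman/SERS,
#' wavelength in nm for NIR) lives in `rowData(x)$axis`, concentrations (mol/L)
#' in `colData(x)$concentration`, and the modality plus free-form annotations
#' (analyte name, preprocessing history) in `metadata(x)`.
#'
#' Validity requires a strictly increasing axis, one concentration per sample,
#' and non-negative concentrations. Use the [SpectrumSet()] constructor rather
#' than `new()`; it sorts the axis ascending and reorders columns consistently.
#'
#' @slot No additional slots beyond SummarizedExperiment.
#' @seealso [SpectrumSet()], [intensities()], [spectralAxis()],
#'   [concentrations()], [modality()]
#' @export
setClass("SpectrumSet", contains = "SummarizedExperiment")

.MODALITIES <- c("NIR", "SERS", "RAMAN", "FUSED")

setValidity("SpectrumSet", function(object) {
  msg <- character()
  ax <- SummarizedExperiment::rowData(object)$axis
  if (is.null(ax)) {
    msg <- c(msg, "rowData must contain an 'axis' column")
  } else {
    if (anyNA(ax) || !is.numeric(ax)) msg <- c(msg, "axis must be numeric and non-missing")
    else if (length(ax) > 1 && any(diff(ax) <= 0))
      msg <- c(msg, "axis must be strictly increasing")
  }
  conc <- SummarizedExperiment::colData(object)$concentration
  if (is.null(conc)) {
    msg <- c(msg, "colData must contain a 'concentration' column")
  } else if (any(!is.na(conc) & conc < 0)) {
    msg <- c(msg, "concentrations must be non-negative")
  }
  mod <- S4Vectors::metadata(object)$modality
  if (is.null(mod) || !mod %in% .MODALITIES)
    msg <- c(msg, sprintf("metadata()$modality must be one of %s",
                          paste(.MODALITIES, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a SpectrumSet
#'
#' @param intensities numeric matrix, samples in rows and channels in columns
#'   (the usual chemometric X orientation, n << p).
#' @param axis numeric vector of channel positions, one per column of
#'   `intensities`. Need not be sorted: columns are reordered so the stored
#'   axis is strictly increasing.
#' @param concentrations numeric vector of analyte concentrations (mol/L),
#'   one per sample.
#' @param sampleIDs character vector of sample labels; defaults to
#'   `rownames(intensities)` or `"S1", "S2", ...`.
#' @param modality one of `"NIR"`, `"SERS"`, `"RAMAN"`, `"FUSED"`.
#' @param meta named list of free-form annotations.
#' @return A [SpectrumSet-class] object.
#' @examples
#' s <- SpectrumSet(matrix(rnorm(15), 3, 5), axis = seq(400, 800, length.out = 5),
#'                  concentrations = c(1e-5, 1e-4, 1e-3), modality = "SERS")
#' dim(intensities(s))
#' @export
SpectrumSet <- function(intensities, axis, concentrations,
                        sampleIDs = NULL, modality = "SERS", meta = list()) {
  intensities <- as.matrix(intensities)
  if (length(axis) != ncol(intensities))
    stop("axis length (", length(axis), ") must equal channel count (",
         ncol(intensities), ")")
  if (length(concentrations) != nrow(intensities))
    stop("concentrations length (", length(concentrations),
         ") must equal sample count (", nrow(intensities), ")")
  if (anyDuplicated(axis))
    stop("axis positions must be distinct")
  ord <- order(axis)
  axis <- axis[ord]
  intensities <- intensities[, ord, drop = FALSE]
  if (is.null(sampleIDs)) {
    sampleIDs <- rownames(intensities)
    if (is.null(sampleIDs))
      sampleIDs <- sprintf("S%d", seq_len(nrow(intensities)))
  }
  modality <- match.arg(modality, .MODALITIES)
  assay <- t(intensities)
  dimnames(assay) <- list(format_axis(axis), sampleIDs)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = assay),
    rowData = S4Vectors::DataFrame(axis = as.numeric(axis)),
    colData = S4Vectors::DataFrame(concentration = as.numeric(concentrations),
                                   row.names = sampleIDs))
  meta$modality <- modality
  if (is.null(meta$history)) meta$history <- character()
  S4Vectors::metadata(se) <- meta
  methods::new("SpectrumSet", se)
}

format_axis <- function(axis) {
  # stable textual channel names; round-trips through CSV headers
  format(axis, trim = TRUE, scientific = FALSE, drop0trailing = TRUE)
}

setMethod("show", "SpectrumSet", function(object) {
  ax <- spectralAxis(object)
  cat(sprintf("SpectrumSet [%s]: %d samples x %d channels, axis %s..%s\n",
              modality(object), ncol(object), nrow(object),
              format(min(ax)), format(max(ax))))
  conc <- concentrations(object)
  cat(sprintf("  concentrations: %d level(s), %s..%s mol/L\n",
              length(unique(conc)), format(min(conc)), format(max(conc))))
  hist <- S4Vectors::metadata(object)$history
  if (length(hist)) cat("  preprocessing:", paste(hist, collapse = " -> "), "\n")
})

#' SplitResult: a concentration-stratified calibration/prediction split
#'
#' @slot calibration,prediction [SpectrumSet-class] halves of the split.
#' @slot seed integer seed that produced the assignment.
#' @slot perLevelCounts data.frame with columns `level`, `nCal`, `nPred`.
#' @seealso [stratifiedSplit()]
#' @export
setClass("SplitResult", representation(
  calibration = "SpectrumSet",
  prediction = "SpectrumSet",
  seed = "integer",
  perLevelCounts = "data.frame"))

setMethod("show", "SplitResult", function(object) {
  cat(sprintf("SplitResult: %d calibration / %d prediction samples (%d levels, seed %d)\n",
              ncol(object@calibration), ncol(object@prediction),
              nrow(object@perLevelCounts), object@seed))
})

#' PLSRModel: a fitted NIPALS partial least squares regression
#'
#' Stores the centered PLS1 decomposition: per-component weight vectors `W`,
#' X-loadings `P`, y-loadings `q`, the centering means, and the regression
#' vector in the original X space (one column per number of retained latent
#' variables, so `coefPath[, a]` is the model truncated at `a` components).
#'
#' @slot nLV integer, number of latent variables retained.
#' @slot xMean,yMean centering vectors.
#' @slot weights,xLoadings p x nLV matrices; @slot yLoadings length-nLV vector.
#' @slot coefficients length-p regression vector for `nLV` components.
#' @slot coefPath p x nLV matrix of coefficient vectors for 1..nLV components.
#' @slot scores n x nLV matrix of training X-scores (for diagnostics).
#' @seealso [plsFit()], [plsPredict()]
#' @export
setClass("PLSRModel", representation(
  nLV = "integer",
  xMean = "numeric",
  yMean = "numeric",
  weights = "matrix",
  xLoadings = "matrix",
  yLoadings = "numeric",
  coefficients = "numeric",
  coefPath = "matrix",
  scores = "matrix"))

setMethod("show", "PLSRModel", function(object) {
  cat(sprintf("PLSRModel: %d latent variable(s), %d channels\n",
              object@nLV, length(object@coefficients)))
})

#' VSIOResult: output of the HSIC-VSIO wavelength selector
#'
#' @slot importanceRaw HSIC wavelength importances T = (WI_1..WI_p).
#' @slot importanceNorm max-normalised importances T' in \[0, 1\].
#' @slot frequencies top-model occurrence frequencies Q from the final
#'   iteration.
#' @slot weights final channel weights W = 0.5 T' + 0.5 Q.
#' @slot rmsecvTrace per-iteration minimum RMSECV; its running minimum is
#'   non-increasing and the final `patience` entries failed to improve it.
#' @slot selected sorted indices of the K channels with the largest final
#'   weights.
#' @slot bestModelChannels channel subset of the overall best sampled model.
#' @slot seedUsed integer seed; @slot config the [vsioConfig()] list used.
#' @seealso [runHsicVsio()]
#' @export
setClass("VSIOResult", representation(
  importanceRaw = "numeric",
  importanceNorm = "numeric",
  frequencies = "numeric",
  weights = "numeric",
  rmsecvTrace = "numeric",
  selected = "integer",
  bestModelChannels = "integer",
  seedUsed = "integer",
  config = "list"))

setMethod("show", "VSIOResult", function(object) {
  cat(sprintf("VSIOResult: %d / %d channels selected in %d iteration(s), final minRMSECV %.4g\n",
              length(object@selected), length(object@weights),
              length(object@rmsecvTrace),
              min(object@rmsecvTrace)))
})

#' FusedMatrix: block-concatenated dual-modality design matrix
#'
#' @slot matrix numeric n x (p1+p2) matrix, NIR block first then SERS.
#' @slot blockMap data.frame with one row per column: `modality`, `channel`
#'   (index into the source set), `axis` (original channel position).
#' @slot mode `"DIRECT"` (full spectra) or `"FEATURE"` (selected channels).
#' @slot concentrations per-sample concentrations carried from the inputs.
#' @seealso [directFuse()], [featureFuse()]
#' @export
setClass("FusedMatrix", representation(
  matrix = "matrix",
  blockMap = "data.frame",
  mode = "character",
  concentrations = "numeric"))

setMethod("show", "FusedMatrix", function(object) {
  blocks <- table(object@blockMap$modality)
  cat(sprintf("FusedMatrix (%s): %d samples x %d columns [%s]\n",
              object@mode, nrow(object@matrix), ncol(object@matrix),
              paste(sprintf("%s:%d", names(blocks), blocks), collapse = " | ")))
})

#' SyntheticDesign: recipe for a simulated spectral dataset
#'
#' Describes analyte and background peaks, smooth baseline drift,
#' per-spectrum multiplicative/additive scatter, channel noise, and the
#' concentration design for one modality. See [defaultDesign()].
#'
#' @slot axisStart,axisEnd,nChannels channel grid.
#' @slot analytePeaks data.frame: `analyte`, `center`, `width`, `shape`
#'   ("gaussian"/"lorentzian"), `response` (height coefficient).
#' @slot backgroundPeaks data.frame: `center`, `width`, `shape`,
#'   `fixedHeight` (concentration-independent).
#' @slot baselineCoef polynomial coefficients of the drift over u in \[0, 1\].
#' @slot scatterSD length-2 numeric: multiplicative sd, additive sd.
#' @slot noiseSD channelwise white-noise sd.
#' @slot concentrationLevels distinct analyte concentrations (mol/L).
#' @slot replicatesPerLevel integer.
#' @slot modalityStyle `"SERS_SHARP"` or `"NIR_BROAD"`.
#' @slot responseModel `"langmuir"`, `"linear"` or `"loglinear"`.
#' @slot langmuirKd fallback adsorption constant (mol/L) for the Langmuir
#'   response; per-peak constants live in the `kd` column of `analytePeaks`.
#' @slot concRef reference concentration for the log-linear response.
#' @slot depositionSD lognormal sd of the per-sample effective-concentration
#'   factor (deposition / enhancement variability shared by all peaks).
#' @slot peakJitterSD additive per-peak intensity fluctuation sd (hotspot
#'   blinking; intensity units).
#' @slot backgroundJitterSD multiplicative per-background-band height
#'   fluctuation sd.
#' @export
setClass("SyntheticDesign", representation(
  axisStart = "numeric",
  axisEnd = "numeric",
  nChannels = "integer",
  analytePeaks = "data.frame",
  backgroundPeaks = "data.frame",
  baselineCoef = "numeric",
  scatterSD = "numeric",
  noiseSD = "numeric",
  concentrationLevels = "numeric",
  replicatesPerLevel = "integer",
  modalityStyle = "character",
  responseModel = "character",
  langmuirKd = "numeric",
  concRef = "numeric",
  depositionSD = "numeric",
  peakJitterSD = "numeric",
  backgroundJitterSD = "numeric"))

setValidity("SyntheticDesign", function(object) {
  msg <- character()
  if (object@nChannels < 10) msg <- c(msg, "nChannels must be >= 10")
  lv <- object@concentrationLevels
  if (anyDuplicated(lv) || any(lv < 0)) msg <- c(msg, "levels must be distinct and non-negative")
  if (object@replicatesPerLevel < 1) msg <- c(msg, "replicatesPerLevel must be >= 1")
  if (nrow(object@analytePeaks) && any(object@analytePeaks$width <= 0))
    msg <- c(msg, "analyte peak widths must be positive")
  if (nrow(object@backgroundPeaks) && any(object@backgroundPeaks$width <= 0))
    msg <- c(msg, "background peak widths must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticDesign", function(object) {
  cat(sprintf("SyntheticDesign [%s]: axis %g..%g (%d channels), %d analyte peak(s), %d level(s) x %d replicates\n",
              object@modalityStyle, object@axisStart, object@axisEnd,
              object@nChannels, nrow(object@analytePeaks),
              length(object@concentrationLevels), object@replicatesPerLevel))
})
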