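#' Accessors for SpectrumSet
#'
#' `intensities()` returns the spectra as a samples x channels matrix (the
#' chemometric X orientation); `spectralAxis()` the channel positions;
#' `concentrations()` the per-sample analyte concentrations (mol/L);
#' `modality()` the modality tag; `sampleIDs()` the sample labels.
#'
#' @param x a [SpectrumSet-class].
#' @return See above; `intensities` is an n x p numeric matrix.
#' @name SpectrumSet-accessors
#' @aliases intensities spectralAxis concentrations modality sampleIDs
NULL

#' @rdname SpectrumSet-accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname SpectrumSet-accessors
#' @export
setGeneric("spectralAxis", function(x) standardGeneric("spectralAxis"))

#' @rdname SpectrumSet-accessors
#' @export
setGeneric("concentrations", function(x) standardGeneric("concentrations"))

#' @rdname SpectrumSet-accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @rdname SpectrumSet-accessors
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

setMethod("intensities", "SpectrumSet", function(x)
  t(SummarizedExperiment::assay(x, "intensity")))

setMethod("spectralAxis", "SpectrumSet", function(x)
  as.numeric(SummarizedExperiment::rowData(x)$axis))

setMethod("concentrations", "SpectrumSet", function(x)
  as.numeric(SummarizedExperiment::colData(x)$concentration))

setMethod("modality", "SpectrumSet", function(x)
  S4Vectors::metadata(x)$modality)

setMethod("sampleIDs", "SpectrumSet", function(x) colnames(x))

#' Subset a SpectrumSet by samples or channels
#'
#' @param x a [SpectrumSet-class].
#' @param idx integer, logical or character index.
#' @return A [SpectrumSet-class] with the selected samples/channels.
#' @export
selectSamples <- function(x, idx) {
  stopifnot(is(x, "SpectrumSet"))
  x[, idx]
}

#' @rdname selectSamples
#' @export
selectChannels <- function(x, idx) {
  stopifnot(is(x, "SpectrumSet"))
  x[idx, ]
}

#' Modelled response vector for a SpectrumSet
#'
#' The calibration response y. Concentration spans several decades in typical
#' residue studies, so the default models log10 concentration; `"linear"`
#' returns the raw molar values.
#'
#' @param x a [SpectrumSet-class].
#' @param scale `"log10"` (default) or `"linear"`.
#' @return numeric vector, one value per sample.
#' @export
responseVector <- function(x, scale = c("log10", "linear")) {
  scale <- match.arg(scale)
  conc <- concentrations(x)
  if (scale == "linear") return(conc)
  if (any(conc <= 0))
    stop("log10 response undefined for non-positive concentrations; use scale = 'linear'")
  log10(conc)
}
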