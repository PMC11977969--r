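.checkAligned <- function(a, b) {
  if (!identical(sampleIDs(a), sampleIDs(b)))
    stop("alignment error: sample ids differ or are ordered differently")
  if (!isTRUE(all.equal(concentrations(a), concentrations(b))))
    stop("alignment error: concentrations differ between modalities")
}

.checkScaled <- function(set, what) {
  hist <- S4Vectors::metadata(set)$history
  if (!any(grepl("^minmax", hist)))
    stop("precondition error: ", what, " has not been min-max scaled; ",
         "fuse after preprocessing or pass checkScaled = FALSE")
}

.blockMap <- function(set, idx) {
  data.frame(modality = rep(modality(set), length(idx)), channel = idx,
             axis = spectralAxis(set)[idx], stringsAsFactors = FALSE)
}

#' Direct (full-spectrum) fusion of two modalities
#'
#' Columnwise concatenation of two preprocessed spectral matrices measured
#' on the same samples, NIR block first then SERS (more generally, `a` then
#' `b`). Both inputs are expected to have been intensity-scaled to a common
#' level (min-max); this is checked via the preprocessing history.
#'
#' @param a,b [SpectrumSet-class] objects with identical samples in
#'   identical order.
#' @param checkScaled require a min-max step in both histories.
#' @return A [FusedMatrix-class] of width p1 + p2.
#' @export
directFuse <- function(a, b, checkScaled = TRUE) {
  stopifnot(is(a, "SpectrumSet"), is(b, "SpectrumSet"))
  .checkAligned(a, b)
  if (checkScaled) { .checkScaled(a, "first input"); .checkScaled(b, "second input") }
  mat <- cbind(intensities(a), intensities(b))
  map <- rbind(.blockMap(a, seq_len(nrow(a))), .blockMap(b, seq_len(nrow(b))))
  methods::new("FusedMatrix", matrix = mat, blockMap = map, mode = "DIRECT",
               concentrations = concentrations(a))
}

#' Feature-level fusion of selected channels
#'
#' Concatenates only the selected channels of each modality (typically the
#' top-K channels from [runHsicVsio()] run per modality), giving a
#' |selA| + |selB| column matrix whose block map preserves the original
#' channel indices and axis positions.
#'
#' @param a,b [SpectrumSet-class] objects with identical samples.
#' @param selA,selB integer channel selections (duplicate-free, in range);
#'   an empty selection is allowed (with a warning) and yields a single-block
#'   result.
#' @param checkScaled require a min-max step in both histories.
#' @return A [FusedMatrix-class] with `mode = "FEATURE"`.
#' @export
featureFuse <- function(a, selA, b, selB, checkScaled = TRUE) {
  stopifnot(is(a, "SpectrumSet"), is(b, "SpectrumSet"))
  .checkAligned(a, b)
  if (checkScaled) { .checkScaled(a, "first input"); .checkScaled(b, "second input") }
  chk <- function(sel, set, what) {
    sel <- as.integer(sel)
    if (anyDuplicated(sel)) stop("selection error: duplicate indices in ", what)
    if (length(sel) && (min(sel) < 1 || max(sel) > nrow(set)))
      stop("selection error: index out of range in ", what)
    sel
  }
  selA <- chk(selA, a, "selA"); selB <- chk(selB, b, "selB")
  if (!length(selA)) warning("empty selection for the first modality")
  if (!length(selB)) warning("empty selection for the second modality")
  if (!length(selA) && !length(selB)) stop("selection error: both selections empty")
  mat <- cbind(intensities(a)[, selA, drop = FALSE],
               intensities(b)[, selB, drop = FALSE])
  map <- rbind(.blockMap(a, selA), .blockMap(b, selB))
  methods::new("FusedMatrix", matrix = mat, blockMap = map, mode = "FEATURE",
               concentrations = concentrations(a))
}

# fit one method: choose LVs by CV on the calibration matrix, then report
# calibration fit and prediction performance
.fitEvaluate <- function(Xcal, yCal, Xpred, yPred, nLvGrid, cvFolds, seed) {
  maxLV <- min(max(nLvGrid), nrow(Xcal) - 1L, ncol(Xcal))
  cv <- kfoldRMSECV(Xcal, yCal, maxLV, k = cvFolds, seed = seed)
  grid <- intersect(nLvGrid, seq_along(cv$rmsecvPerLV))
  best <- grid[which.min(cv$rmsecvPerLV[grid])]
  model <- plsFit(Xcal, yCal, best)
  mc <- calibrationMetrics(yCal, plsPredict(model, Xcal))
  mp <- calibrationMetrics(yPred, plsPredict(model, Xpred))
  list(LVs = best, RMSE1 = mc$rmse, Rc2 = mc$r2,
       RMSE2 = mp$rmse, Rp2 = mp$r2, RPD = mp$rpd, model = model)
}

#' Four-way comparison: single modalities vs direct vs feature-level fusion
#'
#' Fits and evaluates four PLSR calibrations on matched calibration /
#' prediction splits of the two modalities: NIR only, SERS only, direct
#' fusion of the full spectra, and feature-level fusion of the per-modality
#' HSIC-VSIO selections. Latent-variable counts are chosen per method by
#' k-fold cross-validation over `nLvGrid`. Metrics are the calibration and
#' prediction RMSE, R2 and the prediction-set RPD.
#'
#' @param nirSplit,sersSplit [SplitResult-class] objects of preprocessed
#'   data, with matched sample identity across modalities.
#' @param cfg [vsioConfig()] used for the per-modality channel selection.
#' @param nLvGrid candidate latent-variable counts.
#' @param responseScale passed to [responseVector()].
#' @return list with `table` (4-row data.frame: Method, LVs, RMSE1, Rc2,
#'   RMSE2, Rp2, RPD), `selections` (per-modality [VSIOResult-class]) and
#'   `models`.
#' @export
compareMethods <- function(nirSplit, sersSplit, cfg = vsioConfig(),
                           nLvGrid = 1:10, responseScale = "log10") {
  stopifnot(is(nirSplit, "SplitResult"), is(sersSplit, "SplitResult"))
  nirCal <- calibrationSet(nirSplit); nirPred <- predictionSet(nirSplit)
  sersCal <- calibrationSet(sersSplit); sersPred <- predictionSet(sersSplit)
  .checkAligned(nirCal, sersCal); .checkAligned(nirPred, sersPred)
  yCal <- responseVector(nirCal, responseScale)
  yPred <- responseVector(nirPred, responseScale)
  cvFolds <- cfg$cvFolds
  cvSeed <- deriveSeed(cfg$seed, 7L)

  selNir <- runHsicVsio(intensities(nirCal), yCal,
                        modifyList2(cfg, seed = deriveSeed(cfg$seed, 11L)))
  selSers <- runHsicVsio(intensities(sersCal), yCal,
                         modifyList2(cfg, seed = deriveSeed(cfg$seed, 12L)))

  fuseCalD <- directFuse(nirCal, sersCal)
  fusePredD <- directFuse(nirPred, sersPred)
  fuseCalF <- featureFuse(nirCal, selNir@selected, sersCal, selSers@selected)
  fusePredF <- featureFuse(nirPred, selNir@selected, sersPred, selSers@selected)

  rows <- list(
    NIR = .fitEvaluate(intensities(nirCal), yCal, intensities(nirPred), yPred,
                       nLvGrid, cvFolds, cvSeed),
    SERS = .fitEvaluate(intensities(sersCal), yCal, intensities(sersPred), yPred,
                        nLvGrid, cvFolds, cvSeed),
    `NIR+SERS (direct fusion)` =
      .fitEvaluate(fuseCalD@matrix, yCal, fusePredD@matrix, yPred,
                   nLvGrid, cvFolds, cvSeed),
    `NIR+SERS (feature-level fusion)` =
      .fitEvaluate(fuseCalF@matrix, yCal, fusePredF@matrix, yPred,
                   nLvGrid, cvFolds, cvSeed))

  table <- data.frame(
    Method = names(rows),
    LVs = vapply(rows, `[[`, numeric(1), "LVs"),
    RMSE1 = vapply(rows, `[[`, numeric(1), "RMSE1"),
    Rc2 = vapply(rows, `[[`, numeric(1), "Rc2"),
    RMSE2 = vapply(rows, `[[`, numeric(1), "RMSE2"),
    Rp2 = vapply(rows, `[[`, numeric(1), "Rp2"),
    RPD = vapply(rows, `[[`, numeric(1), "RPD"),
    row.names = NULL, stringsAsFactors = FALSE)
  list(table = table,
       selections = list(nir = selNir, sers = selSers),
       models = lapply(rows, `[[`, "model"))
}

# copy of a VSIOConfig with fields replaced (keeps the class attribute)
modifyList2 <- function(cfg, ...) {
  out <- utils::modifyList(unclass(cfg), list(...))
  class(out) <- class(cfg)
  out
}
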