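#' Read a labelled spectral matrix from a wide CSV file
#'
#' The expected layout is the one written by [writeSpectraCSV()]: columns
#' `sample_id`, `concentration`, then one numeric column per channel whose
#' header is the channel position. Channel columns are reordered so the axis
#' is strictly increasing.
#'
#' @param path CSV file path.
#' @param modality modality tag stored on the result.
#' @param sep,dec field and decimal separators.
#' @return A [SpectrumSet-class].
#' @export
readSpectraCSV <- function(path, modality = "SERS", sep = ",", dec = ".") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, dec = dec,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = NA)
  need <- c("sample_id", "concentration")
  if (!all(need %in% names(df)))
    stop("labelled-data error: CSV must contain columns ",
         paste(need, collapse = " and "))
  chanCols <- setdiff(names(df), need)
  axis <- suppressWarnings(as.numeric(chanCols))
  if (anyNA(axis))
    stop("format error: channel headers must be numeric positions; offending: ",
         paste(utils::head(chanCols[is.na(axis)], 3), collapse = ", "))
  if (anyDuplicated(axis))
    stop("format error: duplicated channel positions in header")
  conc <- df$concentration
  if (anyNA(conc))
    stop("labelled-data error: missing concentration in row(s) ",
         paste(which(is.na(conc)), collapse = ", "))
  intens <- as.matrix(df[, chanCols, drop = FALSE])
  if (!is.numeric(intens))
    stop("format error: non-numeric intensity values")
  SpectrumSet(intens, axis = axis, concentrations = conc,
              sampleIDs = as.character(df$sample_id), modality = modality)
}

#' Write a SpectrumSet to a wide CSV file
#'
#' First columns `sample_id` and `concentration`, then one column per channel
#' named by its axis position. Values are written with full precision
#' (`format = %.17g` equivalent via `format(..., digits = 17)`) so a
#' read/write round trip is exact for decimal-representable data.
#'
#' @param data a [SpectrumSet-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSpectraCSV <- function(data, path) {
  stopifnot(is(data, "SpectrumSet"))
  X <- intensities(data)
  df <- data.frame(sample_id = sampleIDs(data),
                   concentration = concentrations(data),
                   check.names = FALSE, stringsAsFactors = FALSE)
  chan <- as.data.frame(X)
  names(chan) <- format_axis(spectralAxis(data))
  out <- cbind(df, chan)
  ok <- tryCatch({
    utils::write.table(format(out, digits = 17, trim = TRUE, scientific = FALSE,
                              drop0trailing = TRUE),
                       path, sep = ",", row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("I/O error writing ", path, ": ", conditionMessage(ok))
  invisible(path)
}

#' Concentration-stratified calibration/prediction split
#'
#' Within every concentration level, exactly `nCalPerLevel` samples are drawn
#' uniformly at random (reproducibly under `seed`) into the calibration set;
#' the remaining replicates of that level form the prediction set. This is the
#' standard design for residue calibration studies, e.g. 6 of 10 replicates
#' per level giving a 36/24 split over 6 levels.
#'
#' @param data a [SpectrumSet-class].
#' @param nCalPerLevel integer, calibration replicates per concentration level.
#' @param seed integer RNG seed.
#' @return A [SplitResult-class].
#' @export
stratifiedSplit <- function(data, nCalPerLevel, seed = 1L) {
  stopifnot(is(data, "SpectrumSet"))
  nCalPerLevel <- as.integer(nCalPerLevel)
  conc <- concentrations(data)
  levels <- sort(unique(conc))
  counts <- table(conc)
  short <- names(counts)[counts < nCalPerLevel]
  if (length(short))
    stop("stratification error: concentration level(s) ",
         paste(short, collapse = ", "), " have fewer than ",
         nCalPerLevel, " replicates")
  calIdx <- integer()
  withSeed(seed, {
    for (lv in levels) {
      members <- which(conc == lv)
      calIdx <- c(calIdx, sort(members[sample.int(length(members), nCalPerLevel)]))
    }
  })
  calIdx <- sort(calIdx)
  predIdx <- setdiff(seq_along(conc), calIdx)
  perLevel <- data.frame(
    level = levels,
    nCal = nCalPerLevel,
    nPred = as.integer(counts[as.character(levels)]) - nCalPerLevel)
  methods::new("SplitResult",
               calibration = data[, calIdx],
               prediction = data[, predIdx],
               seed = as.integer(seed),
               perLevelCounts = perLevel)
}

#' @rdname SplitResult-class
#' @param x a [SplitResult-class].
#' @export
calibrationSet <- function(x) { stopifnot(is(x, "SplitResult")); x@calibration }

#' @rdname SplitResult-class
#' @export
predictionSet <- function(x) { stopifnot(is(x, "SplitResult")); x@prediction }
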