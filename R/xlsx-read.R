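# Minimal XLSX worksheet reader.
#
# Supplementary figure-source workbooks are simple rectangular sheets of
# numbers with an optional header row. Only that subset of OOXML is handled:
# cell values (numeric, shared string, inline string), one sheet at a time.
# An .xlsx file is a ZIP container; utils::unzip (internal method) plus xml2
# are sufficient, so no spreadsheet package is required.

.xlsxLetters2Col <- function(ref) {
  letters <- gsub("[0-9]+$", "", ref)
  chars <- strsplit(letters, "")[[1]]
  sum(vapply(chars, function(ch) match(ch, LETTERS), numeric(1)) *
        26^rev(seq_along(chars) - 1))
}

.xlsxSheetTable <- function(path, sheet = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  exdir <- tempfile("xlsx")
  on.exit(unlink(exdir, recursive = TRUE), add = TRUE)
  utils::unzip(path, exdir = exdir)
  ns <- c(d = "http://schemas.openxmlformats.org/spreadsheetml/2006/main")

  wbFile <- file.path(exdir, "xl", "workbook.xml")
  if (!file.exists(wbFile)) stop("format error: not an xlsx workbook: ", path)
  wb <- xml2::read_xml(wbFile)
  sheetNodes <- xml2::xml_find_all(wb, ".//d:sheets/d:sheet", ns)
  sheetNames <- xml2::xml_attr(sheetNodes, "name")
  if (is.character(sheet)) {
    idx <- match(sheet, sheetNames)
    if (is.na(idx)) stop("sheet not found: ", sheet)
  } else idx <- as.integer(sheet)
  if (idx < 1 || idx > length(sheetNodes)) stop("sheet index out of range: ", idx)

  # map the sheet's relationship id to its worksheet part
  rid <- xml2::xml_attr(sheetNodes[[idx]], "id")
  rels <- xml2::read_xml(file.path(exdir, "xl", "_rels", "workbook.xml.rels"))
  relNodes <- xml2::xml_find_all(rels, ".//*[local-name()='Relationship']")
  target <- xml2::xml_attr(relNodes, "Target")[match(rid, xml2::xml_attr(relNodes, "Id"))]
  if (is.na(target)) target <- sprintf("worksheets/sheet%d.xml", idx)
  target <- sub("^/?(xl/)?", "", target)
  sheetFile <- file.path(exdir, "xl", target)

  strings <- character()
  ssFile <- file.path(exdir, "xl", "sharedStrings.xml")
  if (file.exists(ssFile)) {
    ss <- xml2::read_xml(ssFile)
    strings <- vapply(xml2::xml_find_all(ss, ".//d:si", ns),
                      xml2::xml_text, character(1))
  }

  ws <- xml2::read_xml(sheetFile)
  cells <- xml2::xml_find_all(ws, ".//d:sheetData/d:row/d:c", ns)
  if (!length(cells)) return(matrix(NA_character_, 0, 0))
  ref <- xml2::xml_attr(cells, "r")
  type <- xml2::xml_attr(cells, "t")
  val <- vapply(cells, function(cell) {
    t <- xml2::xml_attr(cell, "t")
    if (!is.na(t) && t == "inlineStr")
      return(xml2::xml_text(xml2::xml_find_first(cell, ".//d:t", ns)))
    v <- xml2::xml_find_first(cell, "./d:v", ns)
    if (inherits(v, "xml_missing")) NA_character_ else xml2::xml_text(v)
  }, character(1))
  isShared <- !is.na(type) & type == "s"
  val[isShared] <- strings[as.integer(val[isShared]) + 1L]

  rows <- as.integer(gsub("^[A-Z]+", "", ref))
  cols <- vapply(ref, .xlsxLetters2Col, numeric(1))
  out <- matrix(NA_character_, max(rows), max(cols))
  out[cbind(rows, cols)] <- val
  out
}

#' Read spectra from a supplementary figure-source spreadsheet
#'
#' Figure-source workbooks hold two-column (axis, intensity) series: one
#' shared axis column and one intensity column per spectrum. The layout is
#' not standardised, so the axis column is auto-detected as the (first)
#' strictly monotone numeric column; every other complete numeric column of
#' the same length becomes one sample. A leading header row of labels is
#' skipped and used as sample ids. The axis is stored ascending.
#'
#' @param path .xlsx file path.
#' @param sheet sheet name or 1-based index.
#' @param modality modality tag for the result (not inferred from the file).
#' @param concentrations optional per-series concentrations; defaults to 0
#'   (unknown) for every series.
#' @return A [SpectrumSet-class] with one sample per intensity series.
#' @export
readSupplementaryXLSX <- function(path, sheet = 1L, modality = "RAMAN",
                                  concentrations = NULL) {
  tab <- .xlsxSheetTable(path, sheet)
  if (!length(tab)) stop("format error: empty sheet")
  num <- suppressWarnings(apply(tab, 2, as.numeric))
  num <- matrix(num, nrow = nrow(tab))
  # header rows: rows where no cell parses as a number
  headerRows <- which(rowSums(!is.na(num)) == 0 & rowSums(!is.na(tab)) > 0)
  headerRows <- headerRows[headerRows == seq_along(headerRows)]  # leading only
  body <- if (length(headerRows)) num[-headerRows, , drop = FALSE] else num
  header <- if (length(headerRows)) tab[utils::tail(headerRows, 1), ] else
    rep(NA_character_, ncol(tab))
  body <- body[rowSums(!is.na(body)) > 0, , drop = FALSE]

  complete <- colSums(is.na(body)) == 0 & nrow(body) > 1
  monotone <- vapply(seq_len(ncol(body)), function(j) {
    if (!complete[j]) return(FALSE)
    d <- diff(body[, j])
    all(d > 0) || all(d < 0)
  }, logical(1))
  if (!any(monotone))
    stop("cannot-locate-axis error: no strictly monotone numeric column found")
  axisCol <- which(monotone)[1]

  seriesCols <- setdiff(which(colSums(!is.na(body)) > 0), axisCol)
  if (!length(seriesCols))
    stop("format error: no intensity series next to the axis column")
  ragged <- seriesCols[colSums(is.na(body[, seriesCols, drop = FALSE])) > 0]
  if (length(ragged))
    stop("format error: mixed axis lengths across series (column(s) ",
         paste(ragged, collapse = ", "), " incomplete)")

  axis <- body[, axisCol]
  X <- t(body[, seriesCols, drop = FALSE])
  ids <- header[seriesCols]
  ids[is.na(ids) | ids == ""] <- paste0("series", seq_along(seriesCols))[is.na(ids) | ids == ""]
  if (is.null(concentrations)) concentrations <- rep(0, nrow(X))
  SpectrumSet(X, axis = axis, concentrations = concentrations,
              sampleIDs = as.character(ids), modality = modality)
}
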