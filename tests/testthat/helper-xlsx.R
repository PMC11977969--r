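# Minimal XLSX writer used only to build test fixtures in code.
# Writes an uncompressed (stored) ZIP archive by hand, so no zip utility or
# spreadsheet package is needed.

.crc32_table <- local({
  xor32 <- function(a, b) {
    hi <- bitwXor(a %/% 65536, b %/% 65536)
    lo <- bitwXor(a %% 65536, b %% 65536)
    hi * 65536 + lo
  }
  tab <- numeric(256)
  for (i in 0:255) {
    c <- i
    for (k in 1:8) {
      c <- if (c %% 2 == 1) xor32(c %/% 2, 3988292384) else c %/% 2  # 0xEDB88320
    }
    tab[i + 1] <- c
  }
  tab
})

crc32 <- function(raw) {
  xor32 <- function(a, b) {
    hi <- bitwXor(a %/% 65536, b %/% 65536)
    lo <- bitwXor(a %% 65536, b %% 65536)
    hi * 65536 + lo
  }
  crc <- 4294967295  # 0xFFFFFFFF
  bytes <- as.integer(raw)
  for (b in bytes) {
    idx <- bitwXor(crc %% 256, b)
    crc <- xor32(crc %/% 256, .crc32_table[idx + 1])
  }
  xor32(crc, 4294967295)
}

.w16 <- function(con, x) writeBin(as.integer(x %% 65536), con, size = 2, endian = "little")
.w32 <- function(con, x) {
  .w16(con, x %% 65536)
  .w16(con, x %/% 65536)
}

# files: named list of character (XML) or raw contents
writeStoredZip <- function(files, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- integer(length(files))
  sizes <- integer(length(files))
  crcs <- numeric(length(files))
  datas <- lapply(files, function(f) if (is.raw(f)) f else charToRaw(f))
  pos <- 0
  for (i in seq_along(files)) {
    name <- charToRaw(names(files)[i])
    data <- datas[[i]]
    offsets[i] <- pos
    sizes[i] <- length(data)
    crcs[i] <- crc32(data)
    .w32(con, 67324752)            # local file header signature
    .w16(con, 20); .w16(con, 0); .w16(con, 0)   # version, flags, method=stored
    .w16(con, 0); .w16(con, 0)     # mod time/date
    .w32(con, crcs[i]); .w32(con, sizes[i]); .w32(con, sizes[i])
    .w16(con, length(name)); .w16(con, 0)
    writeBin(name, con)
    writeBin(data, con)
    pos <- pos + 30 + length(name) + length(data)
  }
  cdStart <- pos
  for (i in seq_along(files)) {
    name <- charToRaw(names(files)[i])
    .w32(con, 33639248)            # central directory header signature
    .w16(con, 20); .w16(con, 20); .w16(con, 0); .w16(con, 0)
    .w16(con, 0); .w16(con, 0)
    .w32(con, crcs[i]); .w32(con, sizes[i]); .w32(con, sizes[i])
    .w16(con, length(name)); .w16(con, 0); .w16(con, 0)
    .w16(con, 0); .w16(con, 0); .w32(con, 0)
    .w32(con, offsets[i])
    writeBin(name, con)
    pos <- pos + 46 + length(name)
  }
  .w32(con, 101010256)             # end of central directory
  .w16(con, 0); .w16(con, 0)
  .w16(con, length(files)); .w16(con, length(files))
  .w32(con, pos - cdStart); .w32(con, cdStart)
  .w16(con, 0)
  invisible(path)
}

.colLetter <- function(j) {
  s <- ""
  while (j > 0) {
    r <- (j - 1) %% 26
    s <- paste0(LETTERS[r + 1], s)
    j <- (j - 1) %/% 26
  }
  s
}

# columns: named list of equal-length vectors (numeric, or character headers
# mixed in as first row when `header = TRUE`)
writeTestXLSX <- function(path, columns, header = TRUE, sheetName = "Sheet1") {
  nr <- max(vapply(columns, length, integer(1)))
  rowsXml <- character(0)
  startRow <- 1L
  if (header) {
    cells <- paste0(vapply(seq_along(columns), function(j)
      sprintf('<c r="%s1" t="inlineStr"><is><t>%s</t></is></c>',
              .colLetter(j), names(columns)[j]), character(1)), collapse = "")
    rowsXml <- c(rowsXml, sprintf('<row r="1">%s</row>', cells))
    startRow <- 2L
  }
  for (i in seq_len(nr)) {
    cells <- character(0)
    for (j in seq_along(columns)) {
      v <- columns[[j]]
      if (i <= length(v) && !is.na(v[i]))
        cells <- c(cells, sprintf('<c r="%s%d"><v>%s</v></c>',
                                  .colLetter(j), i + startRow - 1L,
                                  format(v[i], digits = 15)))
    }
    rowsXml <- c(rowsXml, sprintf('<row r="%d">%s</row>', i + startRow - 1L,
                                  paste0(cells, collapse = "")))
  }
  ws <- paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
    '<sheetData>', paste0(rowsXml, collapse = ""), '</sheetData></worksheet>')
  wb <- paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    sprintf('<sheets><sheet name="%s" sheetId="1" r:id="rId1"/></sheets></workbook>',
            sheetName))
  rels <- paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" ',
    'Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" ',
    'Target="worksheets/sheet1.xml"/></Relationships>')
  rootRels <- paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" ',
    'Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" ',
    'Target="xl/workbook.xml"/></Relationships>')
  contentTypes <- paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    '<Override PartName="/xl/worksheets/sheet1.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
    '</Types>')
  writeStoredZip(list(
    "[Content_Types].xml" = contentTypes,
    "_rels/.rels" = rootRels,
    "xl/workbook.xml" = wb,
    "xl/_rels/workbook.xml.rels" = rels,
    "xl/worksheets/sheet1.xml" = ws), path)
}
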