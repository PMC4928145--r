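# Minimal OOXML spreadsheet writer: multiple worksheets, inline strings,
# numbers at full precision, stored (uncompressed) ZIP container. Written
# here because report export must work without any spreadsheet library;
# deliberately supports only what exportReport() needs.

.crc32Table <- local({
  tab <- integer(256)
  poly <- -306674912L # 0xEDB88320 as signed 32-bit
  for (i in 0:255) {
    c <- i
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L)) bitwXor(bitwShiftR(c, 1L), poly) else bitwShiftR(c, 1L)
    }
    tab[i + 1L] <- c
  }
  tab
})

# CRC-32 of a raw vector, returned as signed 32-bit integer pattern.
.crc32 <- function(bytes) {
  crc <- -1L
  b <- as.integer(bytes)
  for (x in b) {
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   .crc32Table[bitwAnd(bitwXor(crc, x), 255L) + 1L])
  }
  bitwXor(crc, -1L)
}

.le <- function(value, nBytes) {
  # little-endian unsigned integer as raw; value given as double
  out <- raw(nBytes)
  v <- value
  if (v < 0) v <- v + 4294967296 # reinterpret signed 32-bit pattern
  for (i in seq_len(nBytes)) {
    out[i] <- as.raw(v %% 256)
    v <- v %/% 256
  }
  out
}

# entries: named list name -> raw content. Stored, deterministic timestamps.
.writeZip <- function(entries, path) {
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  offsets <- numeric(length(entries))
  crcs <- numeric(length(entries))
  sizes <- numeric(length(entries))
  offset <- 0
  dosTime <- .le(0, 2); dosDate <- .le(33, 2) # fixed epoch-ish date: deterministic output
  for (k in seq_along(entries)) {
    name <- charToRaw(enc2utf8(names(entries)[k]))
    data <- entries[[k]]
    crcs[k] <- .crc32(data)
    sizes[k] <- length(data)
    offsets[k] <- offset
    local <- c(.le(67324752, 4),      # local file header signature
               .le(20, 2), .le(0, 2), # version, flags
               .le(0, 2),             # method: stored
               dosTime, dosDate,
               .le(crcs[k], 4), .le(sizes[k], 4), .le(sizes[k], 4),
               .le(length(name), 2), .le(0, 2),
               name)
    writeBin(local, con)
    writeBin(data, con)
    offset <- offset + length(local) + length(data)
  }
  cdStart <- offset
  cdLen <- 0
  for (k in seq_along(entries)) {
    name <- charToRaw(enc2utf8(names(entries)[k]))
    cd <- c(.le(33639248, 4),                 # central directory signature
            .le(20, 2), .le(20, 2), .le(0, 2),
            .le(0, 2),                        # method: stored
            dosTime, dosDate,
            .le(crcs[k], 4), .le(sizes[k], 4), .le(sizes[k], 4),
            .le(length(name), 2), .le(0, 2), .le(0, 2),
            .le(0, 2), .le(0, 2), .le(0, 4),
            .le(offsets[k], 4),
            name)
    writeBin(cd, con)
    cdLen <- cdLen + length(cd)
  }
  eocd <- c(.le(101010256, 4), .le(0, 2), .le(0, 2),
            .le(length(entries), 2), .le(length(entries), 2),
            .le(cdLen, 4), .le(cdStart, 4), .le(0, 2))
  writeBin(eocd, con)
  invisible(path)
}

.xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub('"', "&quot;", x, fixed = TRUE)
  x
}

.colLetter <- function(j) {
  out <- ""
  while (j > 0) {
    r <- (j - 1) %% 26
    out <- paste0(LETTERS[r + 1], out)
    j <- (j - 1) %/% 26
  }
  out
}

# One worksheet XML from a data.frame (header row + data; numerics as
# numbers, everything else as inline strings).
.sheetXML <- function(df) {
  rows <- character(nrow(df) + 1L)
  hdr <- vapply(seq_along(df), function(j)
    sprintf('<c r="%s1" t="inlineStr"><is><t xml:space="preserve">%s</t></is></c>',
            .colLetter(j), .xmlEscape(names(df)[j])), character(1))
  rows[1L] <- sprintf('<row r="1">%s</row>', paste(hdr, collapse = ""))
  isNum <- vapply(df, is.numeric, logical(1))
  for (i in seq_len(nrow(df))) {
    cells <- vapply(seq_along(df), function(j) {
      ref <- sprintf("%s%d", .colLetter(j), i + 1L)
      v <- df[[j]][i]
      if (isNum[j] && !is.na(v)) {
        sprintf('<c r="%s"><v>%s</v></c>', ref, formatNum(as.numeric(v)))
      } else {
        sprintf('<c r="%s" t="inlineStr"><is><t xml:space="preserve">%s</t></is></c>',
                ref, .xmlEscape(as.character(v %||% "")))
      }
    }, character(1))
    rows[i + 1L] <- sprintf('<row r="%d">%s</row>', i + 1L, paste(cells, collapse = ""))
  }
  paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
         '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
         '<sheetData>', paste(rows, collapse = ""), '</sheetData></worksheet>')
}

#' Write data frames as a multi-worksheet XLSX workbook
#'
#' Self-contained OOXML writer (inline strings, no styling, uncompressed
#' container); numbers are written at full double precision. Output is
#' deterministic: identical inputs give byte-identical files.
#'
#' @param sheets named list of data.frames; names become worksheet names.
#' @param path output `.xlsx` path.
#' @return invisibly, `path`.
#' @export
writeXlsx <- function(sheets, path) {
  stopifnot(length(sheets) >= 1L, !is.null(names(sheets)))
  ns <- length(sheets)
  contentTypes <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    paste(sprintf('<Override PartName="/xl/worksheets/sheet%d.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
                  seq_len(ns)), collapse = ""),
    '</Types>')
  rootRels <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    '</Relationships>')
  workbook <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    '<sheets>',
    paste(sprintf('<sheet name="%s" sheetId="%d" r:id="rId%d"/>',
                  .xmlEscape(names(sheets)), seq_len(ns), seq_len(ns)), collapse = ""),
    '</sheets></workbook>')
  wbRels <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    paste(sprintf('<Relationship Id="rId%d" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet%d.xml"/>',
                  seq_len(ns), seq_len(ns)), collapse = ""),
    '</Relationships>')
  entries <- list()
  entries[["[Content_Types].xml"]] <- charToRaw(enc2utf8(contentTypes))
  entries[["_rels/.rels"]] <- charToRaw(enc2utf8(rootRels))
  entries[["xl/workbook.xml"]] <- charToRaw(enc2utf8(workbook))
  entries[["xl/_rels/workbook.xml.rels"]] <- charToRaw(enc2utf8(wbRels))
  for (k in seq_len(ns)) {
    entries[[sprintf("xl/worksheets/sheet%d.xml", k)]] <- charToRaw(enc2utf8(.sheetXML(sheets[[k]])))
  }
  .writeZip(entries, path)
}
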