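# Minimal Office Open XML spreadsheet writer (inline strings, multiple
# worksheets) over a hand-assembled ZIP container. Deflate compression
# comes from base R's memCompress (zlib stream, header and adler trailer
# stripped); CRC32 reuses the PNG writer's table. Enough of the standard is
# implemented for the clist export to open in Excel/LibreOffice/openpyxl.

.u16le <- function(x) as.raw(c(x %% 256, x %/% 256 %% 256))
.u32le <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, x %/% 256 %% 256, x %/% 65536 %% 256, x %/% 16777216 %% 256))
}

.crc32_le <- function(data) rev(.crc32(data))

.deflate <- function(data) {
  z <- memCompress(data, "gzip")  # zlib: 2-byte header ... 4-byte adler
  z[3:(length(z) - 4L)]
}

# Create a ZIP archive at `path` from a named list of raw vectors.
zip_create <- function(path, entries) {
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- integer(0)
  central <- list()
  pos <- 0L
  for (nm in names(entries)) {
    data <- entries[[nm]]
    if (is.character(data)) data <- charToRaw(paste(data, collapse = "\n"))
    comp <- .deflate(data)
    crc <- .crc32_le(data)
    name <- charToRaw(nm)
    hdr <- c(.u32le(0x04034b50), .u16le(20), .u16le(0), .u16le(8),
             .u16le(0), .u16le(0x21), crc, .u32le(length(comp)),
             .u32le(length(data)), .u16le(length(name)), .u16le(0), name)
    writeBin(hdr, con)
    writeBin(comp, con)
    offsets <- c(offsets, pos)
    central[[nm]] <- c(.u32le(0x02014b50), .u16le(20), .u16le(20), .u16le(0),
                       .u16le(8), .u16le(0), .u16le(0x21), crc,
                       .u32le(length(comp)), .u32le(length(data)),
                       .u16le(length(name)), .u16le(0), .u16le(0),
                       .u16le(0), .u16le(0), .u32le(0), .u32le(pos), name)
    pos <- pos + length(hdr) + length(comp)
  }
  cd_start <- pos
  for (nm in names(central)) {
    writeBin(central[[nm]], con)
    pos <- pos + length(central[[nm]])
  }
  eocd <- c(.u32le(0x06054b50), .u16le(0), .u16le(0),
            .u16le(length(entries)), .u16le(length(entries)),
            .u32le(pos - cd_start), .u32le(cd_start), .u16le(0))
  writeBin(eocd, con)
  invisible(path)
}

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.col_letter <- function(j) {
  out <- ""
  while (j > 0L) {
    out <- paste0(LETTERS[(j - 1L) %% 26L + 1L], out)
    j <- (j - 1L) %/% 26L
  }
  out
}

.sheet_xml <- function(df) {
  nr <- nrow(df); nc <- ncol(df)
  rows <- character(nr + 1L)
  head_cells <- vapply(seq_len(nc), function(j)
    sprintf('<c r="%s1" t="inlineStr"><is><t>%s</t></is></c>',
            .col_letter(j), .xml_escape(names(df)[j])), character(1))
  rows[1] <- paste0('<row r="1">', paste(head_cells, collapse = ""), "</row>")
  for (i in seq_len(nr)) {
    cells <- character(0)
    for (j in seq_len(nc)) {
      v <- df[i, j]
      if (is.na(v)) next
      ref <- paste0(.col_letter(j), i + 1L)
      cells <- c(cells, if (is.numeric(v))
        sprintf('<c r="%s" t="n"><v>%s</v></c>', ref,
                format(v, digits = 15, scientific = FALSE, trim = TRUE))
        else
          sprintf('<c r="%s" t="inlineStr"><is><t>%s</t></is></c>', ref,
                  .xml_escape(as.character(v))))
    }
    rows[i + 1L] <- paste0('<row r="', i + 1L, '">',
                           paste(cells, collapse = ""), "</row>")
  }
  paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
         '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
         "<sheetData>", paste(rows, collapse = ""), "</sheetData></worksheet>")
}

#' Write data frames to an XLSX workbook
#'
#' @param sheets named list of data frames (names become worksheet names).
#' @param path output .xlsx path.
#' @return `path`, invisibly.
#' @export
write_xlsx <- function(sheets, path) {
  stopifnot(length(sheets) >= 1L, !is.null(names(sheets)))
  n <- length(sheets)
  ct <- paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
               '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
               '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
               '<Default Extension="xml" ContentType="application/xml"/>',
               '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
               paste(sprintf('<Override PartName="/xl/worksheets/sheet%d.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
                             seq_len(n)), collapse = ""),
               "</Types>")
  rels <- paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
                 '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
                 '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
                 "</Relationships>")
  wb <- paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
               '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
               'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
               "<sheets>",
               paste(sprintf('<sheet name="%s" sheetId="%d" r:id="rId%d"/>',
                             .xml_escape(names(sheets)), seq_len(n), seq_len(n)),
                     collapse = ""),
               "</sheets></workbook>")
  wbrels <- paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
                   '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
                   paste(sprintf('<Relationship Id="rId%d" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet%d.xml"/>',
                                 seq_len(n), seq_len(n)), collapse = ""),
                   "</Relationships>")
  entries <- list("[Content_Types].xml" = ct, "_rels/.rels" = rels,
                  "xl/workbook.xml" = wb, "xl/_rels/workbook.xml.rels" = wbrels)
  for (i in seq_len(n))
    entries[[sprintf("xl/worksheets/sheet%d.xml", i)]] <-
      .sheet_xml(as.data.frame(sheets[[i]]))
  zip_create(path, entries)
  invisible(path)
}
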