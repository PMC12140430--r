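# Editable cell masks on disk: 16-bit single-channel grayscale PNG, one
# integer label per cell, 0 = background. Files can be touched up in any
# external image editor and re-imported, so the on-disk representation must
# be exact. Reading uses the png package; writing is done by a minimal
# PNG encoder because neither png nor EBImage can write 16-bit PNG here.

.u32be <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %/% 16777216 %% 256, x %/% 65536 %% 256, x %/% 256 %% 256, x %% 256))
}

.crc32_table <- local({
  tab <- integer(256)
  for (i in 0:255) {
    cc <- i
    for (k in 1:8)
      cc <- if (bitwAnd(cc, 1L)) bitwXor(-306674912L, bitwShiftR(cc, 1)) else bitwShiftR(cc, 1)
    tab[i + 1] <- cc
  }
  tab
})

.crc32 <- function(data) {
  cc <- -1L
  for (b in as.integer(data))
    cc <- bitwXor(.crc32_table[bitwAnd(bitwXor(cc, b), 255L) + 1L], bitwShiftR(cc, 8))
  cc <- bitwXor(cc, -1L)
  .u32be(if (cc < 0) cc + 4294967296 else cc)
}

.png_chunk <- function(type, data) {
  td <- c(charToRaw(type), data)
  c(.u32be(length(data)), td, .crc32(td))
}

#' Write a labelled cell mask as 16-bit grayscale PNG
#'
#' Pixel values are the integer region labels, background 0. The file is a
#' plain single-channel 16-bit PNG readable (and editable) by standard image
#' tools; [read_mask_png()] recovers the labels exactly.
#'
#' @param mask integer matrix of labels in `[0, 65535]`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  v <- as.integer(mask)
  if (anyNA(v) || any(v < 0L)) stop("mask labels must be non-negative integers")
  if (any(v > 65535L))
    stop("mask labels exceed 65535 and cannot be stored in a 16-bit PNG")
  h <- nrow(mask); w <- ncol(mask)
  vt <- as.integer(t(mask))
  px <- as.raw(rbind(vt %/% 256L, vt %% 256L))  # big-endian uint16
  dim(px) <- NULL
  scm <- matrix(as.raw(0L), nrow = 2L * w + 1L, ncol = h)
  scm[-1L, ] <- px  # leading raw(0) per row = PNG filter type "none"
  sc <- as.vector(scm)
  idat <- memCompress(sc, "gzip")  # base R emits an RFC1950 zlib stream
  ihdr <- c(.u32be(w), .u32be(h), as.raw(c(16L, 0L, 0L, 0L, 0L)))
  out <- c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
           .png_chunk("IHDR", ihdr), .png_chunk("IDAT", idat),
           .png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

#' Read a labelled cell mask from a grayscale PNG
#'
#' Accepts 8- or 16-bit single-channel PNGs, including files that were
#' hand-edited after export, as long as every pixel is a non-negative
#' integer label. RGB or paletted PNGs are rejected with advice to convert
#' to grayscale, because channel flattening would corrupt labels silently.
#'
#' @param path PNG file path.
#' @return Integer matrix of labels.
#' @export
read_mask_png <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  x <- png::readPNG(path, info = TRUE)
  if (length(dim(x)) == 3L)
    stop("mask PNG '", basename(path), "' has ", dim(x)[3],
         " channels; convert it to single-channel grayscale before import")
  info <- attr(x, "info")
  depth <- if (!is.null(info) && !is.null(info$bit.depth)) info$bit.depth else 16L
  # readPNG scales to [0,1] by the file's bit depth; recover integer labels.
  m <- round(x * (2^depth - 1))
  if (max(abs(x * (2^depth - 1) - m)) > 1e-4)
    stop("mask PNG '", basename(path), "' contains non-integer pixel values")
  matrix(as.integer(m), nrow(x), ncol(x))
}
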