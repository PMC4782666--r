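# Minimal uncompressed BMP support, 8-bit palette grayscale only.
# BMP is byte-oriented little-endian; rows are stored bottom-up and padded
# to 4-byte boundaries.

bmp_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
bmp_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

#' Write a matrix as an 8-bit grayscale BMP
#'
#' @param mat Numeric matrix with integer values in \[0, 255\].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bmp <- function(mat, path) {
  if (!is.matrix(mat)) stop_input("`mat` must be a matrix")
  if (any(mat < 0 | mat > 255 | mat != floor(mat))) {
    stop_input("BMP output requires integer intensities in [0, 255]")
  }
  h <- nrow(mat)
  w <- ncol(mat)
  row_bytes <- ((w + 3L) %/% 4L) * 4L
  data_size <- row_bytes * h
  offset <- 14L + 40L + 256L * 4L
  header <- c(
    charToRaw("BM"), bmp_u32(offset + data_size), bmp_u32(0L), bmp_u32(offset),
    # BITMAPINFOHEADER
    bmp_u32(40L), bmp_u32(w), bmp_u32(h), bmp_u16(1L), bmp_u16(8L),
    bmp_u32(0L), bmp_u32(data_size), bmp_u32(2835L), bmp_u32(2835L),
    bmp_u32(256L), bmp_u32(0L)
  )
  pal <- as.raw(rbind(0:255, 0:255, 0:255, rep(0L, 256)))
  rows <- vapply(h:1, function(i) {
    r <- raw(row_bytes)
    r[seq_len(w)] <- as.raw(mat[i, ])
    r
  }, raw(row_bytes))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(header, pal, as.raw(rows)), con)
  invisible(path)
}

#' Read an 8-bit grayscale BMP into a matrix
#'
#' Supports uncompressed 8-bit palette BMPs (top-down or bottom-up);
#' the palette must be grayscale.
#'
#' @param path BMP file path.
#' @return Numeric matrix of intensities in \[0, 255\].
#' @export
read_bmp <- function(path) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  raw_all <- readBin(path, "raw", file.info(path)$size)
  rd_u16 <- function(i) sum(as.integer(raw_all[i + 0:1]) * c(1, 256))
  rd_u32 <- function(i) sum(as.integer(raw_all[i + 0:3]) * c(1, 256, 65536, 16777216))
  rd_s32 <- function(i) {
    v <- rd_u32(i)
    if (v >= 2^31) v - 2^32 else v
  }
  if (length(raw_all) < 54 || rawToChar(raw_all[1:2]) != "BM") {
    stop_input("not a BMP file: %s", path)
  }
  offset <- rd_u32(11L)
  hdr_size <- rd_u32(15L)
  if (hdr_size < 40) stop_input("unsupported BMP header in %s", path)
  w <- rd_s32(19L)
  h_raw <- rd_s32(23L)
  bottom_up <- h_raw > 0
  h <- abs(h_raw)
  bpp <- rd_u16(29L)
  compression <- rd_u32(31L)
  if (bpp != 8L || compression != 0L) {
    stop_input("only uncompressed 8-bit BMP is supported (got %d bpp, compression %d)",
               bpp, compression)
  }
  n_colors <- rd_u32(47L)
  if (n_colors == 0L) n_colors <- 256L
  pal_at <- 14L + hdr_size
  pal <- matrix(as.integer(raw_all[pal_at + seq_len(n_colors * 4L)]),
                nrow = 4L)
  gray <- pal[3L, ] # red channel; checked equal to green/blue below
  if (any(pal[1L, ] != pal[2L, ]) || any(pal[2L, ] != pal[3L, ])) {
    stop_input("BMP palette in %s is not grayscale", path)
  }
  row_bytes <- ((w + 3L) %/% 4L) * 4L
  px <- raw_all[offset + seq_len(row_bytes * h)]
  idx <- matrix(as.integer(px), nrow = row_bytes)[seq_len(w), , drop = FALSE]
  mat <- t(idx)
  if (bottom_up) mat <- mat[h:1, , drop = FALSE]
  matrix(gray[mat + 1L], nrow = h)
}
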