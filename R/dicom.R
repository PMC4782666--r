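# Minimal DICOM Part-10 support: single-frame, uncompressed, little-endian
# series as produced by MR scanners after export. Explicit and implicit VR
# little endian transfer syntaxes are handled; encapsulated/compressed pixel
# data and nested sequences with undefined length are rejected with a clear
# error. Only the tags the pipeline needs are decoded; everything else is
# skipped by its recorded length.

DICOM_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
DICOM_IMPLICIT_LE <- "1.2.840.10008.1.2"

# VRs whose value length is a 4-byte field preceded by 2 reserved bytes
dicom_long_vrs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

dcm_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
dcm_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

dcm_pad <- function(s, nul = FALSE) {
  r <- charToRaw(s)
  if (length(r) %% 2L == 1L) r <- c(r, if (nul) as.raw(0L) else charToRaw(" "))
  r
}

# One explicit-VR little-endian element
dcm_element <- function(group, elem, vr, value_raw) {
  len <- length(value_raw)
  hdr <- c(dcm_u16(group), dcm_u16(elem), charToRaw(vr))
  if (vr %in% dicom_long_vrs) {
    c(hdr, as.raw(c(0L, 0L)), dcm_u32(len), value_raw)
  } else {
    c(hdr, dcm_u16(len), value_raw)
  }
}

#' Write a single-frame DICOM file
#'
#' Writes one axial slice as an explicit-VR little-endian DICOM Part-10
#' file with the minimal MR tag set (instance number, slice location,
#' matrix size, pixel spacing, TR/TE, unsigned pixel data). Intended for
#' phantom export and round-trip testing; it is not a full DICOM encoder.
#'
#' @param mat Numeric matrix of non-negative integer intensities.
#' @param path Output path.
#' @param instance_number Series instance number (ordering key).
#' @param slice_location Axial position in mm.
#' @param pixel_spacing_mm Length-2 in-plane spacing (row, column), mm.
#' @param bits_allocated 8 or 16.
#' @param tr,te Repetition/echo time in ms, stored as metadata.
#' @return `path`, invisibly.
#' @export
write_dicom_slice <- function(mat, path, instance_number,
                              slice_location = instance_number,
                              pixel_spacing_mm = c(1, 1),
                              bits_allocated = 16L,
                              tr = NULL, te = NULL) {
  if (!is.matrix(mat)) stop_input("`mat` must be a matrix")
  bits_allocated <- as.integer(bits_allocated)
  if (!bits_allocated %in% c(8L, 16L)) stop_input("bits_allocated must be 8 or 16")
  maxval <- 2^bits_allocated - 1
  if (any(mat < 0 | mat > maxval | mat != floor(mat))) {
    stop_input("pixel values must be integers in [0, %d]", maxval)
  }
  rows <- nrow(mat)
  cols <- ncol(mat)
  # pixel data is stored row-major
  px <- as.integer(t(mat))
  px_raw <- writeBin(px, raw(), size = bits_allocated %/% 8L, endian = "little")
  sop_uid <- sprintf("1.2.826.0.1.3680043.9.9999.%d.%d",
                     as.integer(instance_number), rows)

  ds <- c(
    dcm_element(0x0008, 0x0016, "UI", dcm_pad("1.2.840.10008.5.1.4.1.1.4", TRUE)),
    dcm_element(0x0008, 0x0018, "UI", dcm_pad(sop_uid, TRUE)),
    dcm_element(0x0008, 0x0060, "CS", dcm_pad("MR")),
    if (!is.null(tr)) dcm_element(0x0018, 0x0080, "DS", dcm_pad(format(tr))),
    if (!is.null(te)) dcm_element(0x0018, 0x0081, "DS", dcm_pad(format(te))),
    dcm_element(0x0020, 0x0013, "IS", dcm_pad(format(as.integer(instance_number)))),
    dcm_element(0x0020, 0x1041, "DS", dcm_pad(format(slice_location))),
    dcm_element(0x0028, 0x0002, "US", dcm_u16(1L)),
    dcm_element(0x0028, 0x0004, "CS", dcm_pad("MONOCHROME2")),
    dcm_element(0x0028, 0x0010, "US", dcm_u16(rows)),
    dcm_element(0x0028, 0x0011, "US", dcm_u16(cols)),
    dcm_element(0x0028, 0x0030, "DS",
                dcm_pad(paste(format(pixel_spacing_mm), collapse = "\\"))),
    dcm_element(0x0028, 0x0100, "US", dcm_u16(bits_allocated)),
    dcm_element(0x0028, 0x0101, "US", dcm_u16(bits_allocated)),
    dcm_element(0x0028, 0x0102, "US", dcm_u16(bits_allocated - 1L)),
    dcm_element(0x0028, 0x0103, "US", dcm_u16(0L)),
    dcm_element(0x7FE0, 0x0010, "OW", px_raw)
  )
  meta_body <- c(
    dcm_element(0x0002, 0x0002, "UI", dcm_pad("1.2.840.10008.5.1.4.1.1.4", TRUE)),
    dcm_element(0x0002, 0x0003, "UI", dcm_pad(sop_uid, TRUE)),
    dcm_element(0x0002, 0x0010, "UI", dcm_pad(DICOM_EXPLICIT_LE, TRUE))
  )
  meta <- c(dcm_element(0x0002, 0x0000, "UL", dcm_u32(length(meta_body))), meta_body)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128L), charToRaw("DICM"), meta, ds), con)
  invisible(path)
}

#' Read a single-frame DICOM file
#'
#' @param path DICOM file path.
#' @return A list with `pixel` (numeric matrix, rows x cols),
#'   `instance_number`, `slice_location`, `pixel_spacing_mm`, and `meta`
#'   (TR, TE, bits allocated, transfer syntax).
#' @export
read_dicom_slice <- function(path) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  raw_all <- readBin(path, "raw", file.info(path)$size)
  if (length(raw_all) < 140 || rawToChar(raw_all[129:132]) != "DICM") {
    stop_input("not a DICOM Part-10 file: %s", path)
  }
  rd_u16 <- function(i) sum(as.integer(raw_all[i + 0:1]) * c(1, 256))
  rd_u32 <- function(i) sum(as.numeric(raw_all[i + 0:3]) * c(1, 256, 65536, 16777216))
  rd_str <- function(i, n) {
    r <- raw_all[i + seq_len(n) - 1L]
    trimws(rawToChar(r[r != as.raw(0L)]), which = "both")
  }

  found <- list()
  explicit <- TRUE # file meta group is always explicit
  pos <- 133L
  n <- length(raw_all)
  past_meta <- FALSE
  transfer_syntax <- DICOM_EXPLICIT_LE
  while (pos + 7L <= n) {
    group <- rd_u16(pos)
    elem <- rd_u16(pos + 2L)
    if (!past_meta && group != 0x0002) {
      past_meta <- TRUE
      explicit <- !identical(transfer_syntax, DICOM_IMPLICIT_LE)
      if (!transfer_syntax %in% c(DICOM_EXPLICIT_LE, DICOM_IMPLICIT_LE)) {
        stop_input("unsupported DICOM transfer syntax '%s' in %s",
                   transfer_syntax, path)
      }
    }
    if (explicit || group == 0x0002) {
      vr <- rawToChar(raw_all[pos + 4:5])
      if (vr %in% dicom_long_vrs) {
        len <- rd_u32(pos + 8L)
        val_at <- pos + 12L
      } else {
        len <- rd_u16(pos + 6L)
        val_at <- pos + 8L
      }
    } else {
      vr <- NA_character_
      len <- rd_u32(pos + 4L)
      val_at <- pos + 8L
    }
    if (len == 4294967295) {
      stop_input("undefined-length DICOM element (%04x,%04x) in %s is not supported",
                 group, elem, path)
    }
    key <- sprintf("%04X%04X", group, elem)
    decode_num <- function() as.numeric(strsplit(rd_str(val_at, len), "\\\\")[[1]])
    if (key == "00020010") transfer_syntax <- rd_str(val_at, len)
    else if (key == "00180080") found$tr <- decode_num()[1]
    else if (key == "00180081") found$te <- decode_num()[1]
    else if (key == "00200013") found$instance_number <- as.integer(decode_num()[1])
    else if (key == "00201041") found$slice_location <- decode_num()[1]
    else if (key == "00200032") found$image_position <- decode_num()
    else if (key == "00280010") found$rows <- rd_u16(val_at)
    else if (key == "00280011") found$cols <- rd_u16(val_at)
    else if (key == "00280030") found$pixel_spacing <- decode_num()
    else if (key == "00280100") found$bits_allocated <- rd_u16(val_at)
    else if (key == "00280103") found$pixel_representation <- rd_u16(val_at)
    else if (key == "7FE00010") found$pixel_at <- c(val_at, len)
    pos <- val_at + len
  }
  if (is.null(found$rows) || is.null(found$cols) || is.null(found$pixel_at)) {
    stop_input("DICOM file %s is missing Rows/Columns/PixelData", path)
  }
  bits <- found$bits_allocated %||% 16L
  if (!bits %in% c(8L, 16L)) {
    stop_input("unsupported BitsAllocated %d in %s", bits, path)
  }
  signed <- isTRUE(found$pixel_representation == 1L)
  npx <- found$rows * found$cols
  bytes <- raw_all[found$pixel_at[1] + seq_len(npx * bits %/% 8L) - 1L]
  if (bits == 8L) {
    vals <- as.integer(bytes)
    if (signed) vals <- ifelse(vals > 127L, vals - 256L, vals)
  } else {
    vals <- readBin(bytes, "integer", n = npx, size = 2L,
                    signed = signed, endian = "little")
  }
  pixel <- matrix(as.numeric(vals), nrow = found$rows, byrow = TRUE)
  list(
    pixel = pixel,
    instance_number = found$instance_number,
    slice_location = found$slice_location %||%
      (if (!is.null(found$image_position)) found$image_position[3] else NULL),
    pixel_spacing_mm = found$pixel_spacing,
    meta = list(
      tr = found$tr, te = found$te,
      bits_allocated = bits, transfer_syntax = transfer_syntax
    )
  )
}
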