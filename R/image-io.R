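#' Load a subject's axial slices into a stack
#'
#' Reads a DICOM series or a set of 8-bit raster images (PNG/BMP) into a
#' [slice_stack()]. DICOM slices are ordered by Instance Number, falling
#' back to Slice Location when instance numbers are absent or duplicated;
#' an unresolvable tie is an input error. Raster files are taken in the
#' order given (or alphabetical order when a directory is supplied), which
#' is assumed to follow ascending axial level.
#'
#' Raw DICOM intensities are kept as stored; call [rescale_to_8bit()]
#' before analysis. Raster input is already on the 0-255 scale and is
#' loaded as-is.
#'
#' When the directory holds a `*_stack.json` sidecar written by
#' [write_slice_stack()], the sidecar's file list, subject id and slice
#' levels are used, so auxiliary files (ground-truth masks, configs) are
#' never mistaken for slices.
#'
#' @param source Either a directory containing one subject's files, or a
#'   character vector of file paths.
#' @param subject_id Subject identifier recorded in the stack; may be
#'   omitted when a sidecar provides it.
#' @param slice_index_origin Axial level number assigned to the first
#'   slice after ordering; a sidecar's levels take precedence.
#' @return A [slice_stack()].
#' @export
load_slice_stack <- function(source, subject_id = NULL, slice_index_origin = 1L) {
  if (length(source) == 1L && dir.exists(source)) {
    sidecars <- list.files(source, pattern = "_stack\\.json$", full.names = TRUE)
    if (length(sidecars) == 1L) {
      sc <- jsonlite::read_json(sidecars[1], simplifyVector = TRUE)
      files <- file.path(source, sc$files)
      subject_id <- subject_id %||% sc$subject_id
      slice_index_origin <- sc$slice_levels[1] %||% slice_index_origin
    } else {
      files <- sort(list.files(source, full.names = TRUE))
      files <- files[!grepl("\\.(json|ya?ml|txt|csv)$", files, ignore.case = TRUE)]
      files <- files[!grepl("_mask[0-9]*\\.(png|bmp)$", files)]
    }
  } else {
    files <- as.character(source)
  }
  if (is.null(subject_id) && length(source) == 1L && dir.exists(source)) {
    subject_id <- basename(normalizePath(source))
  }
  if (is.null(subject_id)) stop_input("`subject_id` is required when no sidecar names one")
  if (length(files) == 0L) stop_input("no slice files found in source")
  missing <- files[!file.exists(files)]
  if (length(missing) > 0L) {
    stop_input("missing slice file(s): %s", paste(missing, collapse = ", "))
  }
  kinds <- vapply(files, sniff_slice_format, character(1))
  if (length(unique(kinds)) > 1L) {
    stop_input("mixed slice formats in one series: %s",
               paste(unique(kinds), collapse = ", "))
  }
  kind <- kinds[1]
  if (kind == "dicom") {
    load_dicom_series(files, subject_id, slice_index_origin)
  } else {
    mats <- lapply(files, read_raster_slice)
    slice_stack(mats, subject_id, slice_index_origin = slice_index_origin)
  }
}

sniff_slice_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("dcm", "dicom")) return("dicom")
  if (ext == "png") return("png")
  if (ext == "bmp") return("bmp")
  head_raw <- readBin(path, "raw", 132L)
  if (length(head_raw) >= 132 && rawToChar(head_raw[129:132]) == "DICM") return("dicom")
  if (length(head_raw) >= 8 &&
      identical(head_raw[1:8],
                as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A)))) {
    return("png")
  }
  if (length(head_raw) >= 2 && rawToChar(head_raw[1:2]) == "BM") return("bmp")
  stop_input("unrecognized slice format: %s", path)
}

read_raster_slice <- function(path) {
  kind <- sniff_slice_format(path)
  if (kind == "bmp") return(read_bmp(path))
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) {
    ch <- dim(img)[3]
    gray <- img[, , 1]
    for (k in seq_len(min(ch, 3L))[-1]) {
      if (any(abs(img[, , k] - gray) > 1e-9)) {
        stop_input("PNG %s is not grayscale; convert before loading", path)
      }
    }
    img <- gray
  }
  round_half_up(img * 255)
}

load_dicom_series <- function(files, subject_id, slice_index_origin) {
  parsed <- lapply(files, read_dicom_slice)
  dims <- vapply(parsed, function(p) dim(p$pixel), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop_geometry("DICOM series has mixed matrix sizes")
  }
  inst <- vapply(parsed, function(p) p$instance_number %||% NA_integer_, integer(1))
  loc <- vapply(parsed, function(p) as.numeric(p$slice_location %||% NA_real_),
                numeric(1))
  ord <- if (!anyNA(inst) && !anyDuplicated(inst)) {
    order(inst)
  } else if (!anyNA(loc) && !anyDuplicated(loc)) {
    order(loc)
  } else {
    stop_input("cannot order DICOM series: instance numbers and slice locations are missing or tied")
  }
  parsed <- parsed[ord]
  first <- parsed[[1]]
  slice_stack(
    lapply(parsed, `[[`, "pixel"),
    subject_id,
    slice_index_origin = slice_index_origin,
    pixel_spacing_mm = first$pixel_spacing_mm,
    meta = c(first$meta, list(
      matrix_size = dim(first$pixel),
      instance_numbers = vapply(parsed, function(p) p$instance_number %||% NA_integer_,
                                integer(1))
    ))
  )
}

#' Write an 8-bit stack to per-slice rasters plus a JSON sidecar
#'
#' Each slice becomes one 8-bit PNG or BMP named
#' `<subject>_slice<level>.<ext>`; a `<subject>_stack.json` sidecar records
#' the subject id, slice levels, file names, pixel spacing and metadata so
#' the stack can be reloaded without guessing.
#'
#' @param stack An 8-bit [slice_stack()] (see [rescale_to_8bit()]).
#' @param dir Output directory, created if needed.
#' @param format `"png"` or `"bmp"`.
#' @return Invisibly, the sidecar path.
#' @export
write_slice_stack <- function(stack, dir, format = c("png", "bmp")) {
  check_stack(stack)
  format <- match.arg(format)
  if (!is_8bit(stack)) {
    stop_input("stack must be 8-bit before writing; call rescale_to_8bit() first")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  levels <- slice_levels(stack)
  files <- sprintf("%s_slice%02d.%s", stack$subject_id, levels, format)
  for (i in seq_along(levels)) {
    p <- file.path(dir, files[i])
    if (format == "png") {
      png::writePNG(stack$slices[[i]] / 255, p)
    } else {
      write_bmp(stack$slices[[i]], p)
    }
  }
  sidecar <- file.path(dir, sprintf("%s_stack.json", stack$subject_id))
  jsonlite::write_json(
    list(
      subject_id = stack$subject_id,
      slice_levels = levels,
      files = files,
      pixel_spacing_mm = stack$pixel_spacing_mm,
      meta = stack$meta,
      package_version = as.character(utils::packageVersion("dwisig"))
    ),
    sidecar, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
  invisible(sidecar)
}
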