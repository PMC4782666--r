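#' Build an axial slice stack
#'
#' A slice stack is the package's in-memory form of one subject's axial
#' DW-MRI series: an ordered list of 2-D intensity matrices sharing one
#' pixel grid, plus acquisition metadata carried along unchanged.
#'
#' @param slices List of numeric matrices, ordered by ascending axial level.
#'   All matrices must share the same dimensions and contain finite values.
#' @param subject_id Opaque subject identifier string.
#' @param slice_index_origin Axial level number of the first slice
#'   (series are conventionally numbered from 1).
#' @param pixel_spacing_mm Optional length-2 numeric, in-plane pixel spacing
#'   in millimetres (row, column).
#' @param meta Named list of free-form acquisition metadata (TR, TE,
#'   b-value, matrix size, ...). Stored, never interpreted.
#'
#' @return An object of class `slice_stack`.
#' @seealso [rescale_to_8bit()], [load_slice_stack()]
#' @export
#' @examples
#' s <- slice_stack(list(matrix(0, 8, 8), matrix(1, 8, 8)), "demo")
#' dim(s)
slice_stack <- function(slices, subject_id,
                        slice_index_origin = 1L,
                        pixel_spacing_mm = NULL,
                        meta = list()) {
  if (!is.list(slices) || length(slices) == 0L) {
    stop_input("`slices` must be a non-empty list of matrices")
  }
  slices <- lapply(slices, function(m) {
    if (!is.matrix(m) || !is.numeric(m)) {
      stop_input("every slice must be a numeric matrix")
    }
    if (!all(is.finite(m))) stop_input("slice intensities must be finite")
    storage.mode(m) <- "double"
    m
  })
  dims <- vapply(slices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop_geometry(
      "all slices must share one pixel grid; got heights %s and widths %s",
      paste(unique(dims[1, ]), collapse = "/"),
      paste(unique(dims[2, ]), collapse = "/")
    )
  }
  if (!is.null(pixel_spacing_mm)) {
    pixel_spacing_mm <- as.numeric(pixel_spacing_mm)
    if (length(pixel_spacing_mm) != 2L || any(pixel_spacing_mm <= 0)) {
      stop_input("`pixel_spacing_mm` must be two positive numbers")
    }
  }
  structure(
    list(
      subject_id = as.character(subject_id)[1],
      slices = slices,
      slice_index_origin = as.integer(slice_index_origin),
      pixel_spacing_mm = pixel_spacing_mm,
      meta = meta
    ),
    class = "slice_stack"
  )
}

#' @export
dim.slice_stack <- function(x) {
  c(length(x$slices), dim(x$slices[[1]]))
}

#' @export
print.slice_stack <- function(x, ...) {
  d <- dim(x)
  rng <- range(unlist(lapply(x$slices, range)))
  cat(sprintf(
    "<slice_stack> subject '%s': %d slice(s) of %d x %d px, levels %d-%d, intensity range [%g, %g]\n",
    x$subject_id, d[1], d[2], d[3],
    x$slice_index_origin, x$slice_index_origin + d[1] - 1L,
    rng[1], rng[2]
  ))
  invisible(x)
}

#' Axial levels present in a stack
#'
#' @param stack A [slice_stack()].
#' @return Integer vector of axial level numbers, one per slice.
#' @export
slice_levels <- function(stack) {
  check_stack(stack)
  stack$slice_index_origin + seq_along(stack$slices) - 1L
}

#' Extract one slice by axial level
#'
#' @param stack A [slice_stack()].
#' @param level Axial level number (counted from `slice_index_origin`).
#' @return The slice as a numeric matrix.
#' @export
get_slice <- function(stack, level) {
  check_stack(stack)
  i <- match(as.integer(level), slice_levels(stack))
  if (is.na(i)) {
    stop_input("axial level %d not in stack (levels %d-%d)",
               as.integer(level), min(slice_levels(stack)), max(slice_levels(stack)))
  }
  stack$slices[[i]]
}

check_stack <- function(stack) {
  if (!inherits(stack, "slice_stack")) {
    stop_input("expected a `slice_stack` object")
  }
  invisible(stack)
}

# Round-half-up to the nearest integer; used for every intensity
# quantization in the package so rescaling is reproducible bit-for-bit.
round_half_up <- function(x) floor(x + 0.5)

#' Rescale a stack to the 8-bit 0-255 range
#'
#' Applies one linear min-max map computed over the *whole* stack: the
#' global minimum goes to 0 and the global maximum to 255, with
#' round-half-up quantization. Using a single global map (rather than one
#' per slice) keeps intensities comparable across slices, which matters
#' when per-slice resultant gradients are later averaged into a decisive
#' value. A constant stack (zero dynamic range) maps to all zeros.
#'
#' @param stack A [slice_stack()].
#' @return A `slice_stack` whose intensities are integers in \[0, 255\].
#' @export
#' @examples
#' s <- slice_stack(list(matrix(c(0, 2047, 4095, 1000), 2, 2)), "demo")
#' rescale_to_8bit(s)$slices[[1]]
rescale_to_8bit <- function(stack) {
  check_stack(stack)
  lo <- min(vapply(stack$slices, min, numeric(1)))
  hi <- max(vapply(stack$slices, max, numeric(1)))
  stack$slices <- if (hi > lo) {
    lapply(stack$slices, function(m) round_half_up((m - lo) / (hi - lo) * 255))
  } else {
    lapply(stack$slices, function(m) array(0, dim(m)))
  }
  stack
}

#' Is a stack already on the 8-bit scale?
#'
#' @param stack A [slice_stack()].
#' @return `TRUE` if all intensities are integers in \[0, 255\].
#' @export
is_8bit <- function(stack) {
  check_stack(stack)
  all(vapply(stack$slices, function(m) {
    all(m >= 0 & m <= 255 & m == floor(m))
  }, logical(1)))
}
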