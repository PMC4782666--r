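#' Describe a rectangular tumor (or control) region of interest
#'
#' Coordinates are 0-based and half-open on both axes, matching the ROI
#' config file schema: a rect `(row_start, col_start, height, width)`
#' covers pixel rows `row_start .. row_start + height - 1`.
#'
#' @param slice_level Axial level the ROI sits on.
#' @param row_start,col_start Top-left corner, 0-based.
#' @param height,width Extent in pixels; each must be at least 13, the
#'   smallest admissible subregion tile dimension.
#' @param side `"tumor"` or `"contralateral"`.
#' @param area_label Optional informational area number 1-6 (see
#'   [partition_areas()]).
#' @param midline_col Optional column of the interhemispheric midline used
#'   by [mirror_roi()] when the head is off-centre.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(slice_level, row_start, col_start, height, width,
                     side = c("tumor", "contralateral"),
                     area_label = NA_integer_, midline_col = NULL) {
  side <- match.arg(side)
  vals <- c(row_start, col_start, height, width)
  if (any(vals != floor(vals)) || any(c(row_start, col_start) < 0)) {
    stop_input("ROI rect must have non-negative integer coordinates")
  }
  if (height < 13 || width < 13) {
    stop_geometry("ROI of %dx%d px is smaller than the minimum 13-px tile dimension",
                  height, width)
  }
  if (!is.na(area_label) && !(area_label %in% 1:6)) {
    stop_input("area_label must be in 1..6 (or NA)")
  }
  structure(
    list(
      slice_level = as.integer(slice_level),
      row_start = as.integer(row_start), col_start = as.integer(col_start),
      height = as.integer(height), width = as.integer(width),
      side = side, area_label = as.integer(area_label),
      midline_col = if (is.null(midline_col)) NULL else as.numeric(midline_col)
    ),
    class = "roi_spec"
  )
}

#' @export
print.roi_spec <- function(x, ...) {
  cat(sprintf(
    "<roi_spec> %s side, slice %d: rows [%d,%d), cols [%d,%d) (%dx%d px)\n",
    x$side, x$slice_level,
    x$row_start, x$row_start + x$height,
    x$col_start, x$col_start + x$width, x$height, x$width
  ))
  invisible(x)
}

check_roi_in_slice <- function(roi, slice_dim) {
  if (roi$row_start + roi$height > slice_dim[1] ||
      roi$col_start + roi$width > slice_dim[2]) {
    stop_geometry(
      "ROI rows [%d,%d) x cols [%d,%d) exceeds the %dx%d slice",
      roi$row_start, roi$row_start + roi$height,
      roi$col_start, roi$col_start + roi$width, slice_dim[1], slice_dim[2]
    )
  }
  invisible(roi)
}

# Crop the ROI's pixels out of a slice matrix (1-based R indexing inside).
roi_pixels <- function(roi, slice) {
  check_roi_in_slice(roi, dim(slice))
  slice[(roi$row_start + 1L):(roi$row_start + roi$height),
        (roi$col_start + 1L):(roi$col_start + roi$width), drop = FALSE]
}

#' Partition a slice into the six analysis areas
#'
#' Divides a slice into a 3-row by 2-column grid of rectangles labelled
#' 1-6 in row-major order: rows are split as evenly as possible from top
#' to bottom (any remainder pixels go to the upper rows) and columns are
#' split at the vertical midline. The areas are bookkeeping labels for
#' reporting where a tumor sits; no gradient quantity depends on them.
#'
#' @param slice_shape Length-2 integer (height, width), both at least 6.
#' @return A tibble with columns `area`, `row_start`, `col_start`,
#'   `height`, `width` (0-based, half-open).
#' @export
#' @examples
#' partition_areas(c(128, 128))
partition_areas <- function(slice_shape) {
  h <- as.integer(slice_shape[1])
  w <- as.integer(slice_shape[2])
  if (is.na(h) || is.na(w) || h < 6L || w < 6L) {
    stop_geometry("slice of %sx%s px cannot be split into six areas (need >= 6x6)",
                  slice_shape[1], slice_shape[2])
  }
  row_h <- rep(h %/% 3L, 3L) + c(rep(1L, h %% 3L), rep(0L, 3L - h %% 3L))
  col_w <- c(ceiling(w / 2), floor(w / 2))
  tibble(
    area = 1:6,
    row_start = rep(cumsum(c(0L, row_h))[1:3], each = 2L),
    col_start = rep(c(0L, col_w[1]), times = 3L),
    height = rep(row_h, each = 2L),
    width = rep(col_w, times = 3L)
  )
}

#' Mirror a tumor ROI into the contralateral hemisphere
#'
#' Reflects the ROI's columns about the interhemispheric midline, giving
#' the same-size control region at the mirror-image location on the
#' opposite hemisphere. The midline defaults to the image centre column
#' (`slice_width / 2`); supply `midline_col` when the head is off-centre.
#'
#' @param roi A [roi_spec()]; the returned ROI is on the opposite side.
#' @param slice_width Slice width in pixels.
#' @param midline_col Optional midline column (may be fractional); when
#'   `NULL`, the ROI's own `midline_col` field, then `slice_width / 2`.
#' @return The contralateral [roi_spec()]. Mirroring twice returns the
#'   original rect. A ROI that straddles the midline mirrors onto itself
#'   in part; this is allowed but flagged with a warning.
#' @export
#' @examples
#' r <- roi_spec(12, 40, 80, 20, 20)
#' mirror_roi(r, 128)
mirror_roi <- function(roi, slice_width, midline_col = NULL) {
  if (!inherits(roi, "roi_spec")) stop_input("`roi` must be a roi_spec")
  mid <- midline_col %||% roi$midline_col %||% (slice_width / 2)
  new_start <- 2 * mid - (roi$col_start + roi$width)
  if (new_start != floor(new_start)) {
    stop_geometry("midline %g mirrors the ROI onto a half-pixel grid; use an integer or half-integer midline consistent with the rect", mid)
  }
  if (new_start < 0 || new_start + roi$width > slice_width) {
    stop_geometry(
      "mirrored ROI cols [%d,%d) falls outside the width-%d slice; supply midline_col for an off-centre head",
      as.integer(new_start), as.integer(new_start + roi$width), as.integer(slice_width)
    )
  }
  overlap <- min(roi$col_start + roi$width, new_start + roi$width) -
    max(roi$col_start, new_start)
  if (overlap > 0) {
    warn(sprintf(
      "ROI straddles the midline: mirrored rect overlaps the original by %d column(s)",
      as.integer(overlap)
    ))
  }
  roi_spec(roi$slice_level, roi$row_start, new_start, roi$height, roi$width,
           side = if (roi$side == "tumor") "contralateral" else "tumor",
           area_label = roi$area_label, midline_col = mid)
}

#' Tile a ROI into fixed-size subregions
#'
#' Erodes the ROI by `margin_px` on every side — keeping tiles away from
#' the tumor periphery, where edge effects would contaminate the gradient
#' — then lays non-overlapping `tile_rows x tile_cols` tiles row-major
#' from the top-left of the eroded rect. Trailing partial tiles are
#' discarded, never emitted.
#'
#' @param roi A [roi_spec()].
#' @param tile_rows,tile_cols Tile dimensions in pixels, each in 13-18.
#' @param margin_px Non-negative erosion margin in pixels.
#' @return An object of class `subregion_grid`: the parent ROI, the tile
#'   parameters, and a tibble of tiles (`tile`, `row_start`, `col_start`,
#'   `height`, `width`; 0-based, half-open).
#' @export
#' @examples
#' g <- tile_subregions(roi_spec(1, 0, 0, 36, 36), 16, 16, margin_px = 2)
#' g$tiles
tile_subregions <- function(roi, tile_rows = 16L, tile_cols = 16L, margin_px = 2L) {
  if (!inherits(roi, "roi_spec")) stop_input("`roi` must be a roi_spec")
  tile_rows <- as.integer(tile_rows)
  tile_cols <- as.integer(tile_cols)
  margin_px <- as.integer(margin_px)
  if (any(c(tile_rows, tile_cols) < 13L) || any(c(tile_rows, tile_cols) > 18L)) {
    stop_config("tile dimensions must lie in 13..18 px (got %dx%d)",
                tile_rows, tile_cols)
  }
  if (is.na(margin_px) || margin_px < 0L) stop_config("margin_px must be >= 0")
  er_h <- roi$height - 2L * margin_px
  er_w <- roi$width - 2L * margin_px
  n_r <- er_h %/% tile_rows
  n_c <- er_w %/% tile_cols
  if (n_r < 1L || n_c < 1L) {
    stop_tiling(
      "ROI too small: eroded %dx%d px cannot hold one %dx%d tile",
      max(er_h, 0L), max(er_w, 0L), tile_rows, tile_cols
    )
  }
  origin_r <- roi$row_start + margin_px
  origin_c <- roi$col_start + margin_px
  tiles <- tidyr::expand_grid(i = seq_len(n_r) - 1L, j = seq_len(n_c) - 1L)
  tiles <- tibble(
    tile = seq_len(n_r * n_c),
    row_start = origin_r + tiles$i * tile_rows,
    col_start = origin_c + tiles$j * tile_cols,
    height = tile_rows,
    width = tile_cols
  )
  structure(
    list(parent = roi, tile_rows = tile_rows, tile_cols = tile_cols,
         margin_px = margin_px, tiles = tiles),
    class = "subregion_grid"
  )
}

#' @export
print.subregion_grid <- function(x, ...) {
  cat(sprintf(
    "<subregion_grid> %d tile(s) of %dx%d px (margin %d) over %s ROI, slice %d\n",
    nrow(x$tiles), x$tile_rows, x$tile_cols, x$margin_px,
    x$parent$side, x$parent$slice_level
  ))
  invisible(x)
}

#' Read a per-subject ROI configuration file
#'
#' The config is YAML or JSON with the schema:
#' ```yaml
#' subject_id: subj01          # optional
#' midline_col: 64             # optional, subject-wide override
#' rois:
#'   - slice_level: 12
#'     rect: [40, 80, 36, 36]  # row_start, col_start, height, width
#'     area_label: 5           # optional
#'     midline_col: 63         # optional, per-slice override
#' ```
#' Rects are 0-based, half-open. Each entry is validated on load.
#'
#' @param path Config file path (`.yaml`/`.yml`/`.json`).
#' @return A list with `subject_id` (may be `NA`), `midline_col` (may be
#'   `NULL`), and `rois`, a list of tumor-side [roi_spec()] objects.
#' @export
read_roi_config <- function(path) {
  if (!file.exists(path)) stop_input("ROI config not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    stop_input("ROI config must be YAML or JSON: %s", path)
  }
  if (is.null(cfg$rois) || length(cfg$rois) == 0L) {
    stop_config("ROI config %s lists no ROIs under `rois:`", path)
  }
  rois <- lapply(cfg$rois, function(r) {
    if (is.null(r$slice_level) || is.null(r$rect) || length(unlist(r$rect)) != 4L) {
      stop_config("each ROI needs `slice_level` and a length-4 `rect` (in %s)", path)
    }
    rect <- as.numeric(unlist(r$rect))
    roi_spec(r$slice_level, rect[1], rect[2], rect[3], rect[4],
             side = "tumor",
             area_label = r$area_label %||% NA_integer_,
             midline_col = r$midline_col %||% cfg$midline_col)
  })
  list(
    subject_id = cfg$subject_id %||% NA_character_,
    midline_col = cfg$midline_col,
    rois = rois
  )
}

#' Write a ROI configuration file
#'
#' @param rois List of tumor-side [roi_spec()] objects.
#' @param path Output path (`.yaml` or `.json`).
#' @param subject_id Optional subject id recorded in the file.
#' @param midline_col Optional subject-wide midline override.
#' @return `path`, invisibly.
#' @export
write_roi_config <- function(rois, path, subject_id = NULL, midline_col = NULL) {
  entries <- lapply(rois, function(r) {
    e <- list(slice_level = r$slice_level,
              rect = c(r$row_start, r$col_start, r$height, r$width))
    if (!is.na(r$area_label)) e$area_label <- r$area_label
    e
  })
  cfg <- list(subject_id = subject_id, midline_col = midline_col, rois = entries)
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(cfg, path)
  } else {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
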