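#' The eight Robinson compass kernels
#'
#' Sobel-type 3x3 masks with weights 1/2/1: the north kernel has rows
#' `(1, 2, 1)`, `(0, 0, 0)`, `(-1, -2, -1)` and each of the other seven is
#' the previous one with its outer ring rotated one step (a 45-degree
#' rotation), giving one mask per compass direction. Every kernel sums to
#' zero, so a constant region produces zero response in all directions,
#' and the set is closed under rotations and flips of the image plane.
#'
#' @return Named list of eight 3x3 integer matrices, in the order
#'   S, SE, E, NE, N, NW, W, SW.
#' @export
#' @examples
#' robinson_kernels()$N
robinson_kernels <- function() {
  # outer-ring positions, clockwise from the top-left corner
  ring_idx <- rbind(c(1, 1), c(1, 2), c(1, 3), c(2, 3),
                    c(3, 3), c(3, 2), c(3, 1), c(2, 1))
  ring_n <- c(1, 2, 1, 0, -1, -2, -1, 0)
  # one clockwise ring-rotation per 45 degrees: N, NE, E, SE, S, SW, W, NW
  labels <- c("N", "NE", "E", "SE", "S", "SW", "W", "NW")
  ks <- lapply(0:7, function(s) {
    k <- matrix(0L, 3, 3)
    vals <- ring_n[((seq_len(8) - 1L - s) %% 8L) + 1L]
    k[ring_idx] <- as.integer(vals)
    k
  })
  names(ks) <- labels
  ks[c("S", "SE", "E", "NE", "N", "NW", "W", "SW")]
}

# Valid-position 3x3 convolution (correlation) via shift-and-add; output is
# (M-2) x (N-2). No padding: padded borders would manufacture spurious
# gradients at the subregion edge.
conv3_valid <- function(img, kernel) {
  m <- nrow(img)
  n <- ncol(img)
  out <- matrix(0, m - 2L, n - 2L)
  for (i in 1:3) {
    for (j in 1:3) {
      if (kernel[i, j] != 0) {
        out <- out + kernel[i, j] * img[i:(m - 3L + i), j:(n - 3L + j), drop = FALSE]
      }
    }
  }
  out
}

#' Directional gradient responses of one subregion
#'
#' Convolves the subregion with each of the eight Robinson compass
#' kernels over valid positions only (no padding) and reduces each
#' direction to a single non-negative response: the maximum absolute
#' convolution value attained anywhere in the subregion.
#'
#' @param subregion Numeric matrix, at least 3x3.
#' @return Named numeric vector of eight non-negative responses in the
#'   order S, SE, E, NE, N, NW, W, SW.
#' @export
#' @examples
#' step <- matrix(rep(c(0, 0, 10, 10), each = 16), 4, 16, byrow = TRUE)
#' compass_responses(t(step)) # vertical step of height 10: E/W respond 40
compass_responses <- function(subregion) {
  if (!is.matrix(subregion) || nrow(subregion) < 3L || ncol(subregion) < 3L) {
    stop_size("subregion must be a matrix of at least 3x3 px (got %sx%s)",
              if (is.matrix(subregion)) nrow(subregion) else length(subregion),
              if (is.matrix(subregion)) ncol(subregion) else 1L)
  }
  vapply(robinson_kernels(), function(k) max(abs(conv3_valid(subregion, k))),
         numeric(1))
}

#' SIGmax and SIGmin of one subregion
#'
#' The signal intensity gradient of a subregion in its most responsive
#' direction (`sig_max`, the maximum of the eight compass responses) and
#' its least responsive direction (`sig_min`, the minimum). `sig_max`
#' quantifies heterogeneity on the tumor side; `sig_min` is the robust
#' choice on the contralateral side, where sulci and gyri would otherwise
#' inflate the maximum response over otherwise uniform tissue.
#'
#' @param subregion Numeric matrix, at least 3x3.
#' @return A list with `per_kernel` (named length-8 vector), `sig_max`
#'   and `sig_min`.
#' @export
subregion_sig <- function(subregion) {
  per_kernel <- compass_responses(subregion)
  list(per_kernel = per_kernel,
       sig_max = max(per_kernel),
       sig_min = min(per_kernel))
}

#' Per-slice resultant SIG over a subregion grid
#'
#' On the tumor side the resultant is the largest `sig_max` over all
#' tiles — the subregion exhibiting the strongest intensity fluctuation,
#' taken to mark the highest cellular density. On the contralateral side
#' it is the smallest `sig_min` over all tiles — the most uniform patch
#' of normal tissue. Ties are broken by the first tile in row-major order.
#'
#' @param grid A [tile_subregions()] grid.
#' @param stack The subject's [slice_stack()].
#' @param side `"tumor"` or `"contralateral"`; defaults to the side of
#'   the grid's parent ROI.
#' @return A list with `value` (the resultant SIG), `arg_tile` (one-row
#'   tibble for the achieving tile) and `per_tile` (tibble of all tiles
#'   with their `sig_max`/`sig_min`).
#' @export
resultant_sig_slice <- function(grid, stack, side = NULL) {
  if (!inherits(grid, "subregion_grid")) stop_input("`grid` must be a subregion_grid")
  check_stack(stack)
  side <- side %||% grid$parent$side
  if (!side %in% c("tumor", "contralateral")) {
    stop_input("side must be 'tumor' or 'contralateral'")
  }
  if (nrow(grid$tiles) == 0L) stop_tiling("subregion grid has no tiles")
  slice <- get_slice(stack, grid$parent$slice_level)
  sigs <- purrr::map(seq_len(nrow(grid$tiles)), function(i) {
    t <- grid$tiles[i, ]
    sub <- slice[(t$row_start + 1L):(t$row_start + t$height),
                 (t$col_start + 1L):(t$col_start + t$width), drop = FALSE]
    subregion_sig(sub)
  })
  per_tile <- dplyr::mutate(
    grid$tiles,
    sig_max = vapply(sigs, `[[`, numeric(1), "sig_max"),
    sig_min = vapply(sigs, `[[`, numeric(1), "sig_min")
  )
  idx <- if (side == "tumor") which.max(per_tile$sig_max) else which.min(per_tile$sig_min)
  value <- if (side == "tumor") per_tile$sig_max[idx] else per_tile$sig_min[idx]
  list(value = value, arg_tile = per_tile[idx, ], per_tile = per_tile)
}

#' Decisive SIG: average of per-slice resultants
#'
#' One number per subject and side, averaging the resultant SIG over all
#' analysed axial slices so every affected level contributes equally.
#'
#' @param per_slice_values Non-empty numeric vector of per-slice
#'   resultant SIGs.
#' @return The arithmetic mean.
#' @export
decisive_sig <- function(per_slice_values) {
  if (length(per_slice_values) == 0L || anyNA(per_slice_values)) {
    stop_input("need at least one per-slice resultant SIG, none missing")
  }
  mean(per_slice_values)
}

#' Relative SIG (RSIG)
#'
#' The within-subject normalized heterogeneity excess:
#' `(decisive_tumor - decisive_contralateral) / decisive_contralateral`.
#' Using the subject's own contralateral hemisphere as the reference
#' cancels scanner- and subject-level intensity scale, so RSIG is
#' invariant under any global multiplicative gain.
#'
#' @param decisive_tumor Decisive SIG on the tumor side (non-negative).
#' @param decisive_contralateral Decisive SIG on the contralateral side;
#'   must be positive.
#' @return The RSIG value.
#' @export
#' @examples
#' rsig(108, 8) # 12.5
rsig <- function(decisive_tumor, decisive_contralateral) {
  if (!is.finite(decisive_contralateral) || decisive_contralateral <= 0) {
    stop_division(
      "contralateral decisive SIG is %s; a positive reference is required (degenerate control region, e.g. a blank phantom)",
      format(decisive_contralateral)
    )
  }
  (decisive_tumor - decisive_contralateral) / decisive_contralateral
}

#' Classify a subject by its RSIG value
#'
#' Applies the empirical range boundaries separating the two tumor types:
#' RSIG at or above `glioma_min` is called glioma-like, at or below
#' `meningioma_max` meningioma-like, and anything in the open gap between
#' the two thresholds is indeterminate. The defaults are the observed
#' range boundaries (glioma 10.08-28.36, meningioma 5.60-9.86); both are
#' explicit configuration, not a fitted decision rule.
#'
#' @param rsig_value RSIG value(s).
#' @param glioma_min Lower edge of the glioma-like range.
#' @param meningioma_max Upper edge of the meningioma-like range; must
#'   not exceed `glioma_min`.
#' @return Character vector: `"glioma-like"`, `"meningioma-like"` or
#'   `"indeterminate"`.
#' @export
#' @examples
#' classify_by_rsig(c(16.87, 7.94, 10))
classify_by_rsig <- function(rsig_value, glioma_min = 10.08, meningioma_max = 9.86) {
  if (!is.finite(glioma_min) || !is.finite(meningioma_max) ||
      meningioma_max > glioma_min) {
    stop_config(
      "inconsistent thresholds: meningioma_max (%g) must not exceed glioma_min (%g)",
      meningioma_max, glioma_min
    )
  }
  dplyr::case_when(
    rsig_value >= glioma_min ~ "glioma-like",
    rsig_value <= meningioma_max ~ "meningioma-like",
    .default = "indeterminate"
  )
}

#' Analyse one subject end-to-end
#'
#' For every configured axial slice: mirror the tumor ROI into the
#' contralateral hemisphere, tile both ROIs into subregions, and compute
#' the per-slice resultant SIG on each side. Per-slice resultants are
#' then averaged into decisive SIGs, combined into RSIG, and classified.
#' The achieving (argmax/argmin) tiles are recorded per slice for audit.
#'
#' @param stack The subject's [slice_stack()]; must be on the 0-255 scale.
#' @param roi_config Path to a ROI config file, the result of
#'   [read_roi_config()], or a list of tumor-side [roi_spec()] objects.
#' @param tile_rows,tile_cols Subregion tile size in pixels (13-18).
#' @param margin_px Edge-effect margin eroded off each ROI before tiling.
#' @param glioma_min,meningioma_max Classification thresholds,
#'   see [classify_by_rsig()].
#' @return An object of class `subject_sig` with fields `subject_id`,
#'   `per_slice` (tibble), `decisive_sig_tumor`,
#'   `decisive_sig_contralateral`, `rsig`, `label` and `params`.
#' @export
analyze_subject <- function(stack, roi_config,
                            tile_rows = 16L, tile_cols = 16L, margin_px = 2L,
                            glioma_min = 10.08, meningioma_max = 9.86) {
  check_stack(stack)
  if (!is_8bit(stack)) {
    stop_input("stack intensities must be on the 8-bit 0-255 scale; call rescale_to_8bit() first")
  }
  rois <- if (is.character(roi_config)) {
    read_roi_config(roi_config)$rois
  } else if (is.list(roi_config) && !is.null(roi_config$rois)) {
    roi_config$rois
  } else if (inherits(roi_config, "roi_spec")) {
    list(roi_config)
  } else {
    roi_config
  }
  if (length(rois) == 0L) stop_input("no tumor ROIs configured")
  slice_dim <- dim(stack)[2:3]

  per_slice <- purrr::map_dfr(rois, function(roi) {
    with_slice_context(roi$slice_level, {
      check_roi_in_slice(roi, slice_dim)
      roi_c <- mirror_roi(roi, slice_width = slice_dim[2])
      grid_t <- tile_subregions(roi, tile_rows, tile_cols, margin_px)
      grid_c <- tile_subregions(roi_c, tile_rows, tile_cols, margin_px)
      res_t <- resultant_sig_slice(grid_t, stack)
      res_c <- resultant_sig_slice(grid_c, stack)
      tibble(
        slice_level = roi$slice_level,
        area_label = roi$area_label,
        resultant_sig_tumor = res_t$value,
        resultant_sig_contralateral = res_c$value,
        argmax_row = res_t$arg_tile$row_start,
        argmax_col = res_t$arg_tile$col_start,
        argmin_row = res_c$arg_tile$row_start,
        argmin_col = res_c$arg_tile$col_start,
        n_tiles = nrow(grid_t$tiles)
      )
    })
  })

  dec_t <- decisive_sig(per_slice$resultant_sig_tumor)
  dec_c <- decisive_sig(per_slice$resultant_sig_contralateral)
  if (dec_c <= 0) {
    zero_slices <- per_slice$slice_level[per_slice$resultant_sig_contralateral <= 0]
    stop_division(
      "contralateral decisive SIG is 0 (degenerate control region on slice(s) %s)",
      paste(zero_slices, collapse = ", ")
    )
  }
  r <- rsig(dec_t, dec_c)
  structure(
    list(
      subject_id = stack$subject_id,
      per_slice = per_slice,
      decisive_sig_tumor = dec_t,
      decisive_sig_contralateral = dec_c,
      rsig = r,
      label = classify_by_rsig(r, glioma_min, meningioma_max),
      params = list(
        tile_rows = as.integer(tile_rows), tile_cols = as.integer(tile_cols),
        margin_px = as.integer(margin_px),
        glioma_min = glioma_min, meningioma_max = meningioma_max,
        package_version = as.character(utils::packageVersion("dwisig"))
      )
    ),
    class = "subject_sig"
  )
}

# Re-signal any package error with the axial slice prepended, keeping its
# condition class so callers can still dispatch on the error kind.
with_slice_context <- function(slice_level, expr) {
  tryCatch(
    expr,
    dwisig_error = function(e) {
      abort(
        sprintf("slice %d: %s", as.integer(slice_level), conditionMessage(e)),
        class = setdiff(class(e), c("rlang_error", "error", "condition"))
      )
    }
  )
}

#' @export
print.subject_sig <- function(x, ...) {
  cat(sprintf(
    "<subject_sig> '%s': %d slice(s); decisive SIG tumor %.2f vs contralateral %.2f; RSIG %.2f -> %s\n",
    x$subject_id, nrow(x$per_slice), x$decisive_sig_tumor,
    x$decisive_sig_contralateral, x$rsig, x$label
  ))
  invisible(x)
}

#' @describeIn analyze_subject Per-slice resultants as a tibble, one row
#'   per analysed slice.
#' @param x A `subject_sig` object.
#' @param ... Unused.
#' @export
tidy.subject_sig <- function(x, ...) {
  dplyr::mutate(x$per_slice, subject_id = x$subject_id, .before = 1)
}

#' @describeIn analyze_subject One-row per-subject summary (decisive
#'   SIGs, RSIG, label).
#' @export
glance.subject_sig <- function(x, ...) {
  tibble(
    subject_id = x$subject_id,
    n_slices = nrow(x$per_slice),
    decisive_sig_tumor = x$decisive_sig_tumor,
    decisive_sig_contralateral = x$decisive_sig_contralateral,
    rsig = x$rsig,
    label = x$label
  )
}

#' Flag slices whose ROI area looks hyperintense
#'
#' Convenience helper for slice selection: flags slices where the 99th
#' percentile of intensity inside a candidate ROI rect exceeds the given
#' quantile of the whole slice, i.e. slices showing an abrupt bright
#' region. Selection remains the operator's decision; this only suggests.
#'
#' @param stack A [slice_stack()].
#' @param rect Length-4 candidate rect (row_start, col_start, height,
#'   width), 0-based, applied to every slice.
#' @param slice_prob Whole-slice quantile the ROI's 99th percentile must
#'   exceed (default 0.99).
#' @return Tibble with `slice_level`, `roi_q99`, `slice_q`, `flagged`.
#' @export
suggest_slices <- function(stack, rect, slice_prob = 0.99) {
  check_stack(stack)
  rect <- as.integer(rect)
  purrr::map_dfr(slice_levels(stack), function(lvl) {
    s <- get_slice(stack, lvl)
    roi <- s[(rect[1] + 1L):(rect[1] + rect[3]),
             (rect[2] + 1L):(rect[2] + rect[4]), drop = FALSE]
    roi_q <- stats::quantile(roi, 0.99, names = FALSE)
    slice_q <- stats::quantile(s, slice_prob, names = FALSE)
    tibble(slice_level = lvl, roi_q99 = roi_q, slice_q = slice_q,
           flagged = roi_q > slice_q)
  })
}
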