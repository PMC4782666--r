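test_that("partition_areas splits a 128x128 slice into the expected six boxes", {
  p <- partition_areas(c(128, 128))
  expect_equal(p$area, 1:6)
  expect_equal(unique(p$width), 64L)
  expect_equal(p$height[c(1, 3, 5)], c(43L, 43L, 42L))
  expect_equal(p$col_start[1:2], c(0L, 64L))
})

test_that("partition_areas handles exact division and rejects degenerate shapes", {
  p <- partition_areas(c(6, 6))
  expect_true(all(p$height == 2L) && all(p$width == 3L))
  expect_error(partition_areas(c(5, 5)), class = "dwisig_geometry_error")
})

test_that("the six areas tile the slice exactly", {
  withr::with_seed(21, {
    for (rep in 1:20) {
      h <- sample(6:200, 1)
      w <- sample(6:200, 1)
      p <- partition_areas(c(h, w))
      expect_equal(sum(p$height * p$width), h * w)
      # disjointness + coverage: every pixel claimed exactly once
      cover <- matrix(0L, h, w)
      for (i in 1:6) {
        r <- p[i, ]
        cover[(r$row_start + 1):(r$row_start + r$height),
              (r$col_start + 1):(r$col_start + r$width)] <-
          cover[(r$row_start + 1):(r$row_start + r$height),
                (r$col_start + 1):(r$col_start + r$width)] + 1L
      }
      expect_true(all(cover == 1L))
    }
  })
})

test_that("mirror_roi reflects columns about the default midline", {
  r <- roi_spec(4, 10, 80, 20, 20)
  m <- mirror_roi(r, 128)
  expect_equal(m$col_start, 28L)
  expect_equal(m$side, "contralateral")
  expect_equal(c(m$height, m$width, m$row_start), c(20L, 20L, 10L))
})

test_that("mirroring twice returns the original rect", {
  r <- roi_spec(4, 10, 80, 17, 23)
  back <- mirror_roi(mirror_roi(r, 128), 128)
  expect_equal(back$col_start, r$col_start)
  expect_equal(back$side, "tumor")
})

test_that("a midline-straddling ROI mirrors with a warning and the expected overlap", {
  r <- roi_spec(4, 10, 50, 20, 30) # cols [50, 80) straddle col 64
  expect_warning(m <- mirror_roi(r, 128), "overlap")
  # oracle: rectangle intersection arithmetic
  overlap <- min(50 + 30, m$col_start + 30) - max(50, m$col_start)
  expect_equal(m$col_start, 48L)
  expect_equal(overlap, 28)
})

test_that("an off-centre mirror that leaves the slice is a geometry error", {
  r <- roi_spec(4, 10, 80, 20, 20)
  expect_error(mirror_roi(r, 128, midline_col = 20),
               class = "dwisig_geometry_error")
})

test_that("tile_subregions honours exact tiling, remainders and margins", {
  # 32x32, 16px tiles, no margin: exact 2x2
  g <- tile_subregions(roi_spec(1, 0, 0, 32, 32), 16, 16, 0)
  expect_equal(nrow(g$tiles), 4L)
  # 40x40: the 8px remainder on each axis is discarded
  g <- tile_subregions(roi_spec(1, 0, 0, 40, 40), 16, 16, 0)
  expect_equal(nrow(g$tiles), 4L)
  # 36x36 with margin 2: erodes to 32x32 -> 4 tiles (arithmetic oracle)
  g <- tile_subregions(roi_spec(1, 5, 7, 36, 36), 16, 16, 2)
  expect_equal(nrow(g$tiles), ((36 - 2 * 2) %/% 16)^2)
  expect_equal(g$tiles$row_start[1], 5L + 2L)
})

test_that("tiles never leave the margin-eroded ROI", {
  withr::with_seed(22, {
    for (rep in 1:20) {
      h <- sample(20:90, 1)
      w <- sample(20:90, 1)
      tr <- sample(13:18, 1)
      tc <- sample(13:18, 1)
      mg <- sample(0:3, 1)
      roi <- roi_spec(1, 3, 4, h, w)
      g <- tryCatch(tile_subregions(roi, tr, tc, mg),
                    dwisig_tiling_error = function(e) NULL)
      if (is.null(g)) {
        expect_true((h - 2 * mg) < tr || (w - 2 * mg) < tc)
        next
      }
      expect_gte(nrow(g$tiles), 1L)
      expect_true(all(g$tiles$row_start >= 3 + mg))
      expect_true(all(g$tiles$col_start >= 4 + mg))
      expect_true(all(g$tiles$row_start + g$tiles$height <= 3 + h - mg))
      expect_true(all(g$tiles$col_start + g$tiles$width <= 4 + w - mg))
      # pairwise disjoint
      ids <- paste(g$tiles$row_start, g$tiles$col_start)
      expect_equal(anyDuplicated(ids), 0L)
    }
  })
})

test_that("mirrored ROIs tile into congruent grids", {
  roi <- roi_spec(2, 30, 75, 37, 41)
  g1 <- tile_subregions(roi, 14, 17, 2)
  g2 <- tile_subregions(mirror_roi(roi, 128), 14, 17, 2)
  expect_equal(nrow(g1$tiles), nrow(g2$tiles))
  expect_equal(g1$tiles$height, g2$tiles$height)
  expect_equal(g1$tiles$row_start, g2$tiles$row_start)
})

test_that("tile parameters outside 13-18 px are rejected", {
  roi <- roi_spec(1, 0, 0, 40, 40)
  expect_error(tile_subregions(roi, 12, 16, 0), class = "dwisig_config_error")
  expect_error(tile_subregions(roi, 16, 19, 0), class = "dwisig_config_error")
  expect_error(tile_subregions(roi, 16, 16, -1), class = "dwisig_config_error")
  expect_error(tile_subregions(roi_spec(1, 0, 0, 14, 14), 16, 16, 0),
               class = "dwisig_tiling_error")
})

test_that("ROI configs round-trip through YAML and JSON", {
  rois <- list(
    roi_spec(12, 40, 80, 36, 36, area_label = 5),
    roi_spec(13, 42, 78, 36, 38)
  )
  for (ext in c(".yaml", ".json")) {
    f <- withr::local_tempfile(fileext = ext)
    write_roi_config(rois, f, subject_id = "subj9", midline_col = 63)
    cfg <- read_roi_config(f)
    expect_equal(cfg$subject_id, "subj9")
    expect_equal(length(cfg$rois), 2L)
    expect_equal(cfg$rois[[1]]$slice_level, 12L)
    expect_equal(cfg$rois[[1]]$area_label, 5L)
    expect_equal(cfg$rois[[2]]$width, 38L)
    expect_equal(cfg$rois[[2]]$midline_col, 63)
  }
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("subject_id: x", bad)
  expect_error(read_roi_config(bad), class = "dwisig_config_error")
})
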