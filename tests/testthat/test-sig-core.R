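test_that("the compass kernel set has the defining symmetries", {
  ks <- robinson_kernels()
  expect_named(ks, c("S", "SE", "E", "NE", "N", "NW", "W", "SW"))
  expect_true(all(vapply(ks, sum, numeric(1)) == 0))
  key <- function(k) paste(as.vector(k), collapse = ",")
  set <- sort(unname(vapply(ks, key, character(1))))
  # closed under 90-degree rotation and both flips: each transform permutes
  # the set of masks
  transformed <- function(f) sort(unname(vapply(ks, function(k) key(f(k)), character(1))))
  expect_equal(transformed(rot90), set)
  expect_equal(transformed(function(k) k[3:1, ]), set)
  expect_equal(transformed(function(k) k[, 3:1]), set)
  # each kernel is the N mask rotated by some multiple of 45 degrees:
  # all masks share one multiset of coefficients
  expect_true(all(vapply(ks, function(k) identical(sort(as.vector(k)),
                                                   sort(as.vector(ks$N))),
                         logical(1))))
})

test_that("constant subregions give zero response in all directions", {
  r <- compass_responses(matrix(42, 16, 16))
  expect_true(all(r == 0))
  s <- subregion_sig(matrix(42, 16, 16))
  expect_equal(s$sig_max, 0)
  expect_equal(s$sig_min, 0)
})

test_that("a vertical step responds on E/W and is silent on N/S", {
  m <- step_tile(16, 16, step = 10, at = 8)
  r <- compass_responses(m)
  expect_equal(unname(r["E"]), 40)
  expect_equal(unname(r["W"]), 40)
  expect_equal(unname(r["N"]), 0)
  expect_equal(unname(r["S"]), 0)
  expect_equal(r, naive_compass_responses(m))
})

test_that("an isolated unit pixel elicits the kernels' peak coefficient", {
  m <- matrix(0, 16, 16)
  m[8, 8] <- 1
  r <- compass_responses(m)
  expect_true(all(r == 2))
  expect_equal(r, naive_compass_responses(m))
})

test_that("subregions smaller than 3x3 are rejected", {
  expect_error(compass_responses(matrix(0, 2, 5)), class = "dwisig_size_error")
  expect_error(subregion_sig(matrix(0, 3, 2)), class = "dwisig_size_error")
})

test_that("sig_max and sig_min bound the per-kernel responses", {
  withr::with_seed(31, {
    for (rep in 1:20) {
      m <- random_tile()
      s <- subregion_sig(m)
      expect_equal(s$sig_max, max(s$per_kernel))
      expect_equal(s$sig_min, min(s$per_kernel))
      expect_lte(s$sig_min, s$sig_max)
    }
  })
})

test_that("SIG values are invariant under the dihedral symmetries of a tile", {
  withr::with_seed(32, {
    for (rep in 1:10) {
      m <- random_tile()
      s0 <- subregion_sig(m)
      variants <- list(rot90(m), rot90(rot90(m)), rot90(rot90(rot90(m))),
                       m[nrow(m):1, ], m[, ncol(m):1])
      for (v in variants) {
        sv <- subregion_sig(v)
        expect_equal(sv$sig_max, s0$sig_max)
        expect_equal(sv$sig_min, s0$sig_min)
      }
    }
  })
})

test_that("SIG is shift-invariant and scales linearly with gain", {
  withr::with_seed(33, {
    for (rep in 1:10) {
      m <- random_tile()
      s0 <- subregion_sig(m)
      s_shift <- subregion_sig(m + 57)
      expect_equal(s_shift$per_kernel, s0$per_kernel)
      k <- runif(1, 0.5, 3)
      s_gain <- subregion_sig(m * k)
      expect_equal(s_gain$sig_max, k * s0$sig_max)
      expect_equal(s_gain$sig_min, k * s0$sig_min)
    }
  })
})

test_that("doubling a step height doubles sig_max", {
  for (h in c(5, 10, 20)) {
    s1 <- subregion_sig(step_tile(step = h))
    s2 <- subregion_sig(step_tile(step = 2 * h))
    expect_equal(s2$sig_max, 2 * s1$sig_max)
    expect_equal(s1$sig_max, 4 * h)
  }
})

test_that("per-slice resultants equal the extreme tile values, first-tile ties", {
  # three tiles in a row with distinct textures
  slice <- matrix(0, 40, 80)
  slice[10:25, 5:20] <- step_tile(16, 16, step = 3)   # sig_max 12
  slice[10:25, 25:40] <- step_tile(16, 16, step = 10) # sig_max 40
  stack <- slice_stack(list(slice), "res")
  roi <- roi_spec(1, 8, 2, 22, 60)
  g <- tile_subregions(roi, 16, 16, 0)
  res_t <- resultant_sig_slice(g, stack, side = "tumor")
  per <- res_t$per_tile
  expect_equal(res_t$value, max(per$sig_max))
  res_c <- resultant_sig_slice(g, stack, side = "contralateral")
  expect_equal(res_c$value, min(per$sig_min))
  # all-constant grid: ties resolved to the first row-major tile
  flat <- slice_stack(list(matrix(5, 40, 80)), "flat")
  res0 <- resultant_sig_slice(g, flat, side = "tumor")
  expect_equal(res0$value, 0)
  expect_equal(res0$arg_tile$tile, 1L)
})

test_that("decisive SIG is the arithmetic mean of per-slice resultants", {
  expect_equal(decisive_sig(108), 108)
  expect_equal(decisive_sig(c(100, 110, 120)), 110)
  withr::with_seed(34, {
    v <- runif(19, 0, 300)
    acc <- 0
    for (x in v) acc <- acc + x # independent naive summation
    expect_equal(decisive_sig(v), acc / 19)
  })
  expect_error(decisive_sig(numeric(0)), class = "dwisig_input_error")
})

test_that("rsig implements the relative excess over the contralateral side", {
  expect_identical(rsig(108, 8), 12.5)
  for (c0 in c(0.5, 8, 113)) expect_equal(rsig(c0, c0), 0)
  # ratio of group-mean decisive SIGs; differs from a mean of per-subject
  # ratios, as it must (mean of ratios != ratio of means)
  expect_equal(rsig(156.75, 9.17), (156.75 - 9.17) / 9.17)
  expect_false(isTRUE(all.equal(rsig(156.75, 9.17), 16.87, tolerance = 0.01)))
  expect_error(rsig(100, 0), class = "dwisig_division_error")
})

test_that("RSIG thresholds classify the two tumor types with a gap", {
  expect_equal(classify_by_rsig(16.87), "glioma-like")
  expect_equal(classify_by_rsig(7.94), "meningioma-like")
  expect_equal(classify_by_rsig(10.00), "indeterminate")
  expect_equal(classify_by_rsig(c(28.36, 5.60)),
               c("glioma-like", "meningioma-like"))
  expect_error(classify_by_rsig(5, glioma_min = 8, meningioma_max = 9),
               class = "dwisig_config_error")
})

test_that("analyze_subject averages slices and reports context on failure", {
  withr::with_seed(35, {
    slice <- matrix(sample(0:120, 64 * 64, replace = TRUE), 64, 64)
  })
  stack2 <- slice_stack(list(slice, slice), "two")
  rois <- list(roi_spec(1, 20, 36, 20, 20), roi_spec(2, 20, 36, 20, 20))
  res2 <- analyze_subject(stack2, rois, margin_px = 0)
  res1 <- analyze_subject(slice_stack(list(slice), "one"),
                          list(roi_spec(1, 20, 36, 20, 20)), margin_px = 0)
  # two identical configured slices: decisive values equal the one-slice case
  expect_equal(res2$decisive_sig_tumor, res1$decisive_sig_tumor)
  expect_equal(res2$decisive_sig_contralateral, res1$decisive_sig_contralateral)
  expect_equal(res2$rsig, res1$rsig)

  # constant contralateral region: division error naming the slice
  flat <- matrix(0, 64, 64)
  flat[, 33:64] <- slice[, 33:64]
  err <- expect_error(
    analyze_subject(slice_stack(list(flat), "const"),
                    list(roi_spec(1, 20, 36, 20, 20)), margin_px = 0),
    class = "dwisig_division_error"
  )
  expect_match(conditionMessage(err), "slice")

  # out-of-bounds ROI carries its slice level in the message
  err2 <- expect_error(
    analyze_subject(stack2, list(roi_spec(2, 50, 36, 20, 20))),
    class = "dwisig_geometry_error"
  )
  expect_match(conditionMessage(err2), "slice 2")
})

test_that("tidy and glance expose the subject result as tibbles", {
  withr::with_seed(36, {
    slice <- matrix(sample(0:120, 64 * 64, replace = TRUE), 64, 64)
  })
  res <- analyze_subject(slice_stack(list(slice), "td"),
                         list(roi_spec(1, 20, 36, 20, 20)), margin_px = 0)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$subject_id, "td")
  gl <- glance(res)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$rsig, res$rsig)
})

test_that("suggest_slices flags the hyperintense levels", {
  withr::with_seed(37, {
    base <- matrix(sample(50:70, 64 * 64, replace = TRUE), 64, 64)
    hot <- base
    # small enough to stay out of the whole-slice 99th percentile
    hot[28:33, 44:49] <- 220
    stack <- slice_stack(list(base, hot, base), "sg")
  })
  fl <- suggest_slices(stack, c(24, 40, 16, 16))
  expect_equal(fl$flagged, c(FALSE, TRUE, FALSE))
})
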