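# A lighter stack (9 levels, tumor on 3) used for the property sweeps;
# same anatomy model, fewer slices.
small_cfg <- function(preset, ...) {
  phantom_config(preset, n_slices = 9L, tumor_center_slice = 5L,
                 tumor_n_slices = 3L, ...)
}

test_that("the same seed reproduces a subject bit for bit", {
  a <- generate_subject(phantom_config("glioma", seed = 42))
  b <- generate_subject(phantom_config("glioma", seed = 42))
  expect_identical(a$stack$slices, b$stack$slices)
  expect_identical(a$tumor_mask, b$tumor_mask)
  c <- generate_subject(phantom_config("glioma", seed = 43))
  expect_false(identical(a$stack$slices, c$stack$slices))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(1234)
  before <- rnorm(3)
  set.seed(1234)
  invisible(generate_subject(small_cfg("meningioma", seed = 5)))
  after <- rnorm(3)
  expect_identical(before, after)
})

test_that("phantom output respects the intensity range and ground-truth bounds", {
  ph <- generate_subject(phantom_config("glioma", seed = 3))
  expect_true(is_8bit(ph$stack))
  expect_equal(dim(ph$stack), c(19, 128, 128))
  levels_with_roi <- vapply(ph$true_roi, `[[`, integer(1), "slice_level")
  for (s in seq_len(19)) {
    m <- ph$tumor_mask[[s]]
    if (s %in% levels_with_roi) {
      roi <- ph$true_roi[[match(s, levels_with_roi)]]
      # the ROI bounds the mask
      idx <- which(m, arr.ind = TRUE)
      expect_true(all(idx[, 1] > roi$row_start &
                        idx[, 1] <= roi$row_start + roi$height))
      expect_true(all(idx[, 2] > roi$col_start &
                        idx[, 2] <= roi$col_start + roi$width))
    }
  }
  # masks exist only on the configured tumor levels
  has_mask <- vapply(ph$tumor_mask, any, logical(1))
  expect_true(all(which(has_mask) %in% 8:12))
})

test_that("invalid tumor placement is a config error", {
  expect_error(phantom_config("glioma", tumor_center = c(60, 64)),
               class = "dwisig_config_error")
  expect_error(phantom_config("glioma", tumor_center = c(60, 70),
                              tumor_semi_axes = c(10, 10)),
               class = "dwisig_config_error")
  expect_error(phantom_config("glioma", tumor_center_slice = 1L,
                              tumor_n_slices = 5L),
               class = "dwisig_config_error")
})

test_that("cohorts have the configured sizes, labels and determinism", {
  coh <- generate_cohort(
    small_cfg("glioma"), small_cfg("meningioma"),
    n_glioma = 3, n_meningioma = 2, master_seed = 9
  )
  expect_length(coh, 5L)
  expect_equal(
    vapply(coh, `[[`, character(1), "group_label"),
    rep(c("glioma-like", "meningioma-like"), c(3, 2))
  )
  coh2 <- generate_cohort(small_cfg("glioma"), small_cfg("meningioma"),
                          n_glioma = 3, n_meningioma = 2, master_seed = 9)
  expect_identical(lapply(coh, function(s) s$stack$slices),
                   lapply(coh2, function(s) s$stack$slices))
  # jitter makes subjects differ within a group
  expect_false(identical(coh[[1]]$stack$slices, coh[[2]]$stack$slices))
})

test_that("a tumor indistinguishable from background yields near-zero RSIG", {
  rs <- vapply(1:50, function(s) {
    cfg <- phantom_config("glioma", tumor_texture_amplitude = 0,
                          tumor_mean = 60, seed = s)
    analyze_phantom(generate_subject(cfg))$rsig
  }, numeric(1))
  expect_gte(mean(abs(rs) < 1), 0.95)
})

test_that("mean RSIG is non-decreasing in the texture amplitude", {
  amps <- c(4, 10, 18, 26)
  means <- vapply(amps, function(a) {
    mean(vapply(1:20, function(s) {
      cfg <- small_cfg("glioma", tumor_texture_amplitude = a, seed = s)
      analyze_phantom(generate_subject(cfg))$rsig
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) >= 0))
})

test_that("a tumor-free phantom still has a positive contralateral SIG", {
  # guards the RSIG division: noise and sulci keep the control region textured
  for (s in 1:5) {
    cfg <- small_cfg("meningioma", tumor_texture_amplitude = 0, tumor_mean = 60,
                     seed = s)
    res <- analyze_phantom(generate_subject(cfg))
    expect_gt(res$decisive_sig_contralateral, 0)
  }
})

test_that("phantoms round-trip through disk and reanalyse identically", {
  ph <- generate_subject(small_cfg("glioma", seed = 8))
  d <- withr::local_tempdir()
  write_phantom(ph, d)
  expect_error(write_phantom(ph, d), class = "dwisig_input_error")
  expect_silent(write_phantom(ph, d, overwrite = TRUE))
  back <- load_slice_stack(d)
  expect_identical(back$slices, ph$stack$slices)
  roi_file <- list.files(d, pattern = "_roi\\.yaml$", full.names = TRUE)
  res_disk <- analyze_subject(back, roi_file)
  res_mem <- analyze_phantom(ph)
  expect_equal(res_disk$rsig, res_mem$rsig)
})
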