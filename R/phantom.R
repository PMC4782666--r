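# Synthetic axial DW-like phantoms: a roughly uniform bright brain ellipse
# with Gaussian pixel noise, dark curvilinear cortical strokes (sulci)
# mirrored approximately across the midline, and a hyperintense tumor blob
# whose internal band-limited speckle amplitude is the heterogeneity knob.
# Ground truth (per-slice mask + ROI) is carried with every subject so the
# whole pipeline is testable without patient data.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Separable Gaussian blur with circular boundary; adequate here because
# every blurred field sits well inside its matrix.
blur_gaussian <- function(m, sd) {
  if (sd <= 0) return(m)
  k <- max(1L, ceiling(3 * sd))
  g <- stats::dnorm(-k:k, sd = sd)
  g <- g / sum(g)
  out <- stats::filter(m, g, circular = TRUE)
  out <- t(stats::filter(t(out), g, circular = TRUE))
  matrix(as.numeric(out), nrow(m), ncol(m))
}

#' Phantom generator configuration
#'
#' Bundles every knob of the synthetic DW-slice generator. The two
#' presets differ only in the tumor's internal texture amplitude: the
#' glioma-like preset has strong band-limited speckle (heterogeneous,
#' high-cellularity appearance), the meningioma-like preset a moderate
#' one. All other defaults describe a 128 x 128 acquisition-matrix head
#' with 19 axial levels, background tissue near intensity 60 with pixel
#' noise sd 1.5, and a hyperintense (mean 180) tumor in the right
#' hemisphere spanning 5 levels.
#'
#' @param preset `"glioma"` or `"meningioma"`; selects the default
#'   texture amplitude.
#' @param image_size Height, width in px.
#' @param n_slices Number of axial levels.
#' @param brain_center,brain_semi_axes Brain ellipse (row/col centre and
#'   semi-axes, px).
#' @param background_mean,background_noise_sd Normal-tissue intensity and
#'   Gaussian pixel noise sd.
#' @param sulci_count Dark cortical strokes per slice (each also stamped,
#'   jittered, at the mirror position).
#' @param sulci_depth Intensity drop of a stroke core.
#' @param tumor_center,tumor_semi_axes Tumor ellipse at its central
#'   slice (row/col, px); must stay within one hemisphere.
#' @param tumor_center_slice,tumor_n_slices Axial extent; semi-axes taper
#'   ellipsoidally toward the end slices.
#' @param tumor_mean Tumor plateau intensity.
#' @param tumor_texture_amplitude Sd of the tumor's internal speckle in
#'   intensity units — the cellularity-heterogeneity knob.
#' @param tumor_texture_scale Correlation length of the speckle, px.
#' @param tumor_edge_sd Softness (Gaussian sd, px) of the tumor margin;
#'   keeps the rim gradient from masking the internal texture, mirroring
#'   the edge-effect care taken when subregions are chosen.
#' @param roi_pad_px Padding added around the tumor mask's bounding box
#'   when emitting the ground-truth ROI.
#' @param seed RNG seed; fully determines the generated subject.
#' @return An object of class `phantom_config` (a validated named list).
#' @export
phantom_config <- function(preset = c("glioma", "meningioma"),
                           image_size = c(128L, 128L),
                           n_slices = 19L,
                           brain_center = c(64.5, 64.5),
                           brain_semi_axes = c(54, 48),
                           background_mean = 60,
                           background_noise_sd = 1.5,
                           sulci_count = 10L,
                           sulci_depth = 25,
                           tumor_center = c(62.5, 90.5),
                           tumor_semi_axes = c(16, 12),
                           tumor_center_slice = 10L,
                           tumor_n_slices = 5L,
                           tumor_mean = 180,
                           tumor_texture_amplitude = NULL,
                           tumor_texture_scale = 1.2,
                           tumor_edge_sd = 5,
                           roi_pad_px = 3L,
                           seed = 1L) {
  preset <- match.arg(preset)
  if (is.null(tumor_texture_amplitude)) {
    # calibrated so default cohorts land near RSIG ~10-28 (glioma-like)
    # and ~5.6-9.9 (meningioma-like); see the methods vignette
    tumor_texture_amplitude <- switch(preset, glioma = 24, meningioma = 8)
  }
  cfg <- list(
    preset = preset,
    image_size = as.integer(image_size),
    n_slices = as.integer(n_slices),
    brain_center = as.numeric(brain_center),
    brain_semi_axes = as.numeric(brain_semi_axes),
    background_mean = background_mean,
    background_noise_sd = background_noise_sd,
    sulci_count = as.integer(sulci_count),
    sulci_depth = sulci_depth,
    tumor_center = as.numeric(tumor_center),
    tumor_semi_axes = as.numeric(tumor_semi_axes),
    tumor_center_slice = as.integer(tumor_center_slice),
    tumor_n_slices = as.integer(tumor_n_slices),
    tumor_mean = tumor_mean,
    tumor_texture_amplitude = tumor_texture_amplitude,
    tumor_texture_scale = tumor_texture_scale,
    tumor_edge_sd = tumor_edge_sd,
    roi_pad_px = as.integer(roi_pad_px),
    seed = as.integer(seed)
  )
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  h <- cfg$image_size[1]
  w <- cfg$image_size[2]
  if (h < 32 || w < 32) stop_config("phantom image must be at least 32x32 px")
  if (cfg$n_slices < 1) stop_config("n_slices must be >= 1")
  if (cfg$background_noise_sd < 0 || cfg$tumor_texture_amplitude < 0) {
    stop_config("noise/texture amplitudes must be non-negative")
  }
  if (cfg$background_mean < 0 || cfg$background_mean > 255 ||
      cfg$tumor_mean < 0 || cfg$tumor_mean > 255) {
    stop_config("intensity means must lie in [0, 255]")
  }
  mid <- w / 2
  cc <- cfg$tumor_center[2]
  ac <- cfg$tumor_semi_axes[2]
  if ((cc > mid && cc - ac <= mid) || (cc < mid && cc + ac >= mid) || cc == mid) {
    stop_config("tumor ellipse crosses the midline (centre col %.1f, semi-axis %.1f, midline %.1f); keep the tumor inside one hemisphere",
                cc, ac, mid)
  }
  lo <- cfg$tumor_center_slice - (cfg$tumor_n_slices - 1) %/% 2
  hi <- lo + cfg$tumor_n_slices - 1
  if (lo < 1 || hi > cfg$n_slices) {
    stop_config("tumor slices %d..%d fall outside the stack (1..%d)",
                lo, hi, cfg$n_slices)
  }
  invisible(cfg)
}

#' @export
print.phantom_config <- function(x, ...) {
  cat(sprintf(
    "<phantom_config> %s-like: %dx%d px, %d slices; tumor mean %g, texture amplitude %g (scale %g px), seed %d\n",
    x$preset, x$image_size[1], x$image_size[2], x$n_slices,
    x$tumor_mean, x$tumor_texture_amplitude, x$tumor_texture_scale, x$seed
  ))
  invisible(x)
}

ellipse_mask <- function(h, w, center, semi_axes) {
  r <- (seq_len(h) - center[1]) / semi_axes[1]
  c <- (seq_len(w) - center[2]) / semi_axes[2]
  outer(r^2, c^2, `+`) <= 1
}

# Rasterize one cortical stroke: a short arc at radial fraction 0.80-0.95
# of the brain ellipse with angular wobble. Returns integer pixel coords.
gen_stroke_pixels <- function(center, semi_axes) {
  theta0 <- runif(1, 0, 2 * pi)
  span <- runif(1, 0.15, 0.45)
  rho <- runif(1, 0.80, 0.95)
  theta <- seq(theta0, theta0 + span, by = 0.008)
  rho_t <- rho + cumsum(rnorm(length(theta), 0, 0.0015))
  cbind(
    round(center[1] + rho_t * semi_axes[1] * sin(theta)),
    round(center[2] + rho_t * semi_axes[2] * cos(theta))
  )
}

# Stamp strokes (and their mirrored twins) into a depth map.
sulci_map <- function(h, w, cfg, tumor_excl) {
  S <- matrix(0, h, w)
  mid <- w / 2
  for (k in seq_len(cfg$sulci_count)) {
    px <- gen_stroke_pixels(cfg$brain_center, cfg$brain_semi_axes)
    jitter <- rnorm(1, 0, 1)
    px_m <- cbind(px[, 1], round(2 * mid - px[, 2] + jitter))
    px <- rbind(px, px_m)
    keep <- px[, 1] >= 2 & px[, 1] <= h - 1 & px[, 2] >= 2 & px[, 2] <= w - 1
    px <- px[keep, , drop = FALSE]
    for (ex in tumor_excl) {
      inside <- ((px[, 1] - ex$center[1]) / ex$semi[1])^2 +
        ((px[, 2] - ex$center[2]) / ex$semi[2])^2 <= 1
      px <- px[!inside, , drop = FALSE]
    }
    if (nrow(px) == 0L) next
    S[px] <- cfg$sulci_depth
    for (shift in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
      nb <- sweep(px, 2, shift, `+`)
      S[nb] <- pmax(S[nb], cfg$sulci_depth / 2)
    }
  }
  S
}

#' Generate one synthetic phantom subject
#'
#' Builds the subject's full axial stack from a [phantom_config()]:
#' brain ellipse at `background_mean` plus Gaussian pixel noise, mirrored
#' dark sulcal strokes near the cortical rim, and on the affected levels
#' a soft-edged hyperintense tumor whose interior carries band-limited
#' speckle of the configured amplitude. Intensities are clamped to
#' \[0, 255\] and quantized; the same seed always yields bit-identical
#' output.
#'
#' @param config A [phantom_config()].
#' @param subject_id Subject identifier for the stack.
#' @return An object of class `phantom_subject`: `stack`
#'   ([slice_stack()]), `tumor_mask` (per-slice logical matrices),
#'   `true_roi` (list of tumor-side [roi_spec()], one per affected level
#'   large enough to tile), `group_label`, and `config`.
#' @export
generate_subject <- function(config, subject_id = sprintf("phantom_%s_%d", config$preset, config$seed)) {
  validate_phantom_config(config)
  h <- config$image_size[1]
  w <- config$image_size[2]
  with_seed(config$seed, {
    brain <- ellipse_mask(h, w, config$brain_center, config$brain_semi_axes)
    lo <- config$tumor_center_slice - (config$tumor_n_slices - 1) %/% 2
    offsets <- seq_len(config$tumor_n_slices) - 1L
    levels_affected <- lo + offsets
    half_span <- (config$tumor_n_slices + 1) / 2
    d <- levels_affected - config$tumor_center_slice
    scales <- sqrt(pmax(0, 1 - (d / half_span)^2))
    # keep stamped sulci off the tumor and off its mirrored control region,
    # so the contralateral ROI reflects the uniform-tissue noise floor
    excl_semi <- config$tumor_semi_axes * 1.3 + 2
    mirror_center <- c(config$tumor_center[1], w - config$tumor_center[2] + 1)
    tumor_excl <- list(
      list(center = config$tumor_center, semi = excl_semi),
      list(center = mirror_center, semi = excl_semi)
    )

    slices <- vector("list", config$n_slices)
    masks <- vector("list", config$n_slices)
    rois <- list()
    for (s in seq_len(config$n_slices)) {
      img <- matrix(0, h, w)
      img[brain] <- config$background_mean +
        rnorm(sum(brain), 0, config$background_noise_sd)
      S <- sulci_map(h, w, config, tumor_excl)
      img[brain] <- img[brain] - S[brain]
      mask <- matrix(FALSE, h, w)
      k <- match(s, levels_affected)
      if (!is.na(k) && scales[k] > 0) {
        semi <- config$tumor_semi_axes * scales[k]
        if (all(semi >= 1.5)) {
          mask <- ellipse_mask(h, w, config$tumor_center, semi)
          soft <- blur_gaussian(mask + 0, config$tumor_edge_sd)
          z <- blur_gaussian(matrix(rnorm(h * w), h, w), config$tumor_texture_scale)
          z <- z / sd(z)
          img <- img + (config$tumor_mean - config$background_mean) * soft +
            config$tumor_texture_amplitude * z * soft
          roi <- mask_roi(mask, s, config$roi_pad_px, h, w)
          if (!is.null(roi)) rois <- c(rois, list(roi))
        }
      }
      masks[[s]] <- mask
      slices[[s]] <- pmin(pmax(round_half_up(img), 0), 255)
    }
    structure(
      list(
        stack = slice_stack(
          slices, subject_id,
          meta = list(generator = "dwisig phantom", preset = config$preset,
                      seed = config$seed)
        ),
        tumor_mask = masks,
        true_roi = rois,
        group_label = paste0(config$preset, "-like"),
        config = config
      ),
      class = "phantom_subject"
    )
  })
}

# Bounding box of the mask, padded, clipped to the slice; NULL when the
# result is too small to hold one 16-px tile behind a margin up to 3 px.
mask_roi <- function(mask, slice_level, pad, h, w) {
  rows <- which(rowSums(mask) > 0)
  cols <- which(colSums(mask) > 0)
  if (length(rows) == 0L) return(NULL)
  r0 <- max(1L, min(rows) - pad)
  r1 <- min(h, max(rows) + pad)
  c0 <- max(1L, min(cols) - pad)
  c1 <- min(w, max(cols) + pad)
  if (r1 - r0 + 1L < 22L || c1 - c0 + 1L < 22L) return(NULL)
  roi_spec(slice_level, r0 - 1L, c0 - 1L, r1 - r0 + 1L, c1 - c0 + 1L,
           side = "tumor")
}

#' @export
print.phantom_subject <- function(x, ...) {
  cat(sprintf(
    "<phantom_subject> '%s' (%s): %d slices, tumor on %d level(s) [%s]\n",
    x$stack$subject_id, x$group_label, dim(x$stack)[1], length(x$true_roi),
    paste(vapply(x$true_roi, `[[`, integer(1), "slice_level"), collapse = ", ")
  ))
  invisible(x)
}

#' Analyse a phantom subject with its ground-truth ROIs
#'
#' Thin convenience wrapper: runs [analyze_subject()] on the phantom's
#' stack using the ROIs the generator emitted.
#'
#' @param subject A [generate_subject()] result.
#' @param ... Passed to [analyze_subject()].
#' @return A `subject_sig` object.
#' @export
analyze_phantom <- function(subject, ...) {
  if (!inherits(subject, "phantom_subject")) {
    stop_input("`subject` must be a phantom_subject")
  }
  analyze_subject(subject$stack, subject$true_roi, ...)
}

#' Generate a two-group phantom cohort
#'
#' Draws `n_glioma` glioma-like and `n_meningioma` meningioma-like
#' subjects (defaults mirror a 20 + 12 cohort). Per-subject seeds are
#' derived deterministically from `master_seed`, and each subject gets
#' bounded jitter on tumor position (+/- 3 px), size (+/- 10%) and
#' texture amplitude (x 0.8-1.25) so the groups form distributions, not
#' copies.
#'
#' @param glioma_config,meningioma_config Group base configurations.
#' @param n_glioma,n_meningioma Group sizes, each >= 1.
#' @param master_seed Seed controlling the whole cohort.
#' @return List of `phantom_subject` objects with ids `glioma_01`, ...,
#'   `meningioma_01`, ...
#' @export
generate_cohort <- function(glioma_config = phantom_config("glioma"),
                            meningioma_config = phantom_config("meningioma"),
                            n_glioma = 20L, n_meningioma = 12L,
                            master_seed = 1L) {
  if (n_glioma < 1L || n_meningioma < 1L) stop_input("group sizes must be >= 1")
  with_seed(master_seed, {
    specs <- c(
      lapply(seq_len(n_glioma), function(i) {
        list(cfg = glioma_config, id = sprintf("glioma_%02d", i))
      }),
      lapply(seq_len(n_meningioma), function(i) {
        list(cfg = meningioma_config, id = sprintf("meningioma_%02d", i))
      })
    )
    lapply(specs, function(sp) {
      cfg <- jitter_config(sp$cfg)
      generate_subject(cfg, subject_id = sp$id)
    })
  })
}

# Per-subject jitter, drawn from the active (master-seeded) RNG; the
# subject's own seed is drawn here too, so one master seed fixes the
# whole cohort.
jitter_config <- function(cfg) {
  h <- cfg$image_size[1]
  w <- cfg$image_size[2]
  mid <- w / 2
  cfg$tumor_center <- cfg$tumor_center + runif(2, -3, 3)
  cfg$tumor_semi_axes <- cfg$tumor_semi_axes * runif(2, 0.9, 1.1)
  cfg$tumor_texture_amplitude <- cfg$tumor_texture_amplitude * runif(1, 0.8, 1.25)
  cfg$seed <- sample.int(.Machine$integer.max - 1L, 1L)
  # keep the jittered tumor inside the right hemisphere and the image
  ac <- cfg$tumor_semi_axes[2]
  cfg$tumor_center[2] <- min(max(cfg$tumor_center[2], mid + ac + 2), w - ac - 4)
  ar <- cfg$tumor_semi_axes[1]
  cfg$tumor_center[1] <- min(max(cfg$tumor_center[1], ar + 4), h - ar - 4)
  # ... and its padded ROI well inside the brain ellipse, away from the
  # bright brain/air rim, pulling the centre inward if jitter pushed it out
  for (i in 1:30) {
    if (roi_corner_radius(cfg) <= 0.95) break
    step <- sign(cfg$brain_center - cfg$tumor_center)
    cfg$tumor_center <- cfg$tumor_center + step
  }
  validate_phantom_config(cfg)
  cfg
}

# Largest normalized brain-ellipse radius reached by a corner of the
# padded ground-truth ROI at the tumor's central slice.
roi_corner_radius <- function(cfg) {
  dr <- abs(cfg$tumor_center[1] - cfg$brain_center[1]) +
    cfg$tumor_semi_axes[1] + cfg$roi_pad_px
  dc <- abs(cfg$tumor_center[2] - cfg$brain_center[2]) +
    cfg$tumor_semi_axes[2] + cfg$roi_pad_px
  sqrt((dr / cfg$brain_semi_axes[1])^2 + (dc / cfg$brain_semi_axes[2])^2)
}

#' Write a phantom subject to disk
#'
#' Emits the stack as 8-bit PNG (or BMP) slices with the standard JSON
#' sidecar, the ground-truth masks as PNGs, an auto-generated ROI config
#' (YAML) naming the affected slices, and a truth JSON recording the
#' group label and the full generator configuration — so the command-line
#' pipeline can consume phantoms exactly like real data.
#'
#' @param subject A `phantom_subject`.
#' @param dir Output directory.
#' @param format `"png"` or `"bmp"` for the slices.
#' @param overwrite Refuse to overwrite an existing subject unless `TRUE`.
#' @return Invisibly, the directory.
#' @export
write_phantom <- function(subject, dir, format = c("png", "bmp"), overwrite = FALSE) {
  format <- match.arg(format)
  if (!inherits(subject, "phantom_subject")) {
    stop_input("`subject` must be a phantom_subject")
  }
  id <- subject$stack$subject_id
  truth_path <- file.path(dir, sprintf("%s_truth.json", id))
  if (file.exists(truth_path) && !overwrite) {
    stop_input("phantom '%s' already exists in %s; pass overwrite = TRUE to replace it",
               id, dir)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_slice_stack(subject$stack, dir, format = format)
  levels <- slice_levels(subject$stack)
  for (i in seq_along(levels)) {
    m <- subject$tumor_mask[[i]]
    if (any(m)) {
      png::writePNG((m + 0), file.path(dir, sprintf("%s_mask%02d.png", id, levels[i])))
    }
  }
  write_roi_config(subject$true_roi, file.path(dir, sprintf("%s_roi.yaml", id)),
                   subject_id = id)
  jsonlite::write_json(
    list(
      subject_id = id,
      group_label = subject$group_label,
      config = unclass(subject$config),
      package_version = as.character(utils::packageVersion("dwisig"))
    ),
    truth_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}
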