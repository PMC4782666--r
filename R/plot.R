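#' Plot one axial slice with optional ROI overlays
#'
#' Renders a slice as a grayscale raster (radiological-style, row 1 at
#' the top) and overlays the tumor ROI and, optionally, its mirrored
#' contralateral twin.
#'
#' @param stack A [slice_stack()].
#' @param level Axial level to plot.
#' @param roi Optional tumor-side [roi_spec()] to outline.
#' @param show_mirror Also outline the mirrored contralateral ROI.
#' @return A ggplot object.
#' @export
plot_slice <- function(stack, level, roi = NULL, show_mirror = TRUE) {
  check_stack(stack)
  s <- get_slice(stack, level)
  df <- tidyr::expand_grid(row = seq_len(nrow(s)), col = seq_len(ncol(s)))
  df$intensity <- as.vector(t(s))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 255)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s, axial level %d", stack$subject_id, level),
                  x = NULL, y = NULL, fill = "DW\nintensity") +
    ggplot2::theme_minimal()
  add_roi_rect <- function(p, r, colour) {
    p + ggplot2::annotate(
      "rect",
      xmin = r$col_start + 0.5, xmax = r$col_start + r$width + 0.5,
      ymin = r$row_start + 0.5, ymax = r$row_start + r$height + 0.5,
      colour = colour, fill = NA, linewidth = 0.6
    )
  }
  if (!is.null(roi)) {
    p <- add_roi_rect(p, roi, "red")
    if (show_mirror) {
      p <- add_roi_rect(p, mirror_roi(roi, ncol(s)), "cyan")
    }
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-slice resultant SIGs for one subject
#'
#' One line per side (tumor vs contralateral) across the analysed axial
#' levels, with the decisive (mean) values as dashed horizontal rules.
#'
#' @param object A `subject_sig` result from [analyze_subject()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.subject_sig <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$per_slice,
    cols = c("resultant_sig_tumor", "resultant_sig_contralateral"),
    names_to = "side", names_prefix = "resultant_sig_", values_to = "sig"
  )
  dec <- tibble(
    side = c("tumor", "contralateral"),
    sig = c(object$decisive_sig_tumor, object$decisive_sig_contralateral)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$slice_level, y = .data$sig,
                                     colour = .data$side)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(data = dec,
                        ggplot2::aes(yintercept = .data$sig, colour = .data$side),
                        linetype = "dashed", show.legend = FALSE) +
    ggplot2::labs(
      title = sprintf("%s: RSIG %.2f (%s)", object$subject_id, object$rsig,
                      object$label),
      x = "axial level", y = "resultant SIG", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot a cohort report
#'
#' Group mean RSIG with +/- 1 sd error bars.
#'
#' @param object A `cohort_report` from [cohort_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cohort_report <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$group, y = .data$rsig_mean)) +
    ggplot2::geom_col(fill = "grey70", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$rsig_mean - .data$rsig_sd,
                   ymax = .data$rsig_mean + .data$rsig_sd),
      width = 0.15
    ) +
    ggplot2::labs(x = NULL, y = "mean RSIG (+/- sd)") +
    ggplot2::theme_minimal()
}
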