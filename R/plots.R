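#' Plot a concentration field
#'
#' Raster heat map of the dye concentration with the domain boundary implied
#' by the mask.
#'
#' @param object A [conc_field()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.conc_field <- function(object, ...) {
  n <- dim(object$grid)
  co <- grid_coords(n[1], n[2], object$grid_spacing_mm)
  df <- tidyr::expand_grid(y = co$y, x = co$x)
  df$c <- as.vector(t(object$grid))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$c)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(name = "mass/cell") +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = sprintf("t = %.1f h", object$time_h))
}

#' Plot an eye image
#'
#' @param object An [eye_image()].
#' @param ... Unused.
#' @return A ggplot showing the RGB photograph.
#' @export
autoplot.eye_image <- function(object, ...) {
  px <- object$pixels / 255
  n <- dim(px)
  df <- tidyr::expand_grid(y = seq_len(n[1]) - 1, x = seq_len(n[2]) - 1)
  df$col <- grDevices::rgb(as.vector(t(px[, , 1])), as.vector(t(px[, , 2])),
                           as.vector(t(px[, , 3])))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(fill = df$col) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)")
}

#' Threshold-sweep area curve
#'
#' Lit-pixel count (or area) against threshold, the curve used to pick the
#' working threshold.
#'
#' @param sweep Output of [sweep_thresholds()].
#' @return A ggplot.
#' @export
plot_threshold_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(.data$threshold, .data$n_pixels)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "threshold (intensity units)",
                  y = "pixels at or above threshold")
}

#' Bar chart of group means for a cohort report
#'
#' Mean response per dye and time point with SD error bars — the standard
#' presentation for fluorescent-area percentages across dye sizes.
#'
#' @param object A [cohort_report()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cohort_report <- function(object, ...) {
  s <- object$summary
  s$dye_label <- factor(s$dye_label, levels = dye_catalog()$label)
  ggplot2::ggplot(
    s, ggplot2::aes(.data$dye_label, .data$mean, fill = factor(.data$time_h))
  ) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25
    ) +
    ggplot2::labs(x = NULL, y = "mean response", fill = "time (h)")
}
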