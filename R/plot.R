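# Plotting helpers for measurement series and frames.

#' Plot a measurement series
#'
#' Fascicle length and pennation angle against frame index, optionally
#' overlaid with a reference series (e.g. phantom ground truth).
#'
#' @param series Measurement tibble from [run_pipeline()].
#' @param reference Optional tibble with `frame`, `fl_mm`, `pa_deg`.
#' @return A ggplot object (facetted: FL in mm, PA in degrees).
#' @export
plot_measurements <- function(series, reference = NULL) {
  shape_long <- function(df, which) {
    rbind(
      data.frame(frame = df$frame, value = df$fl_mm,
                 quantity = "fascicle length (mm)", series = which),
      data.frame(frame = df$frame, value = df$pa_deg,
                 quantity = "pennation angle (deg)", series = which)
    )
  }
  d <- shape_long(series, "measured")
  if (!is.null(reference)) d <- rbind(d, shape_long(reference, "reference"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$frame, y = .data$value,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "frame", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Display a frame with the measurement geometry overlaid
#'
#' @param frame A [us_frame].
#' @param series Optional measurement tibble; the row matching the frame's
#'   index contributes the insertion points and fascicle segment.
#' @param init Optional [init_record] whose lines are drawn.
#' @return A ggplot object in pixel coordinates (y down, as in the image).
#' @export
plot_frame <- function(frame, series = NULL, init = NULL) {
  px <- frame$pixels
  d <- data.frame(
    x = rep(0:(ncol(px) - 1), each = nrow(px)),
    y = rep(0:(nrow(px) - 1), times = ncol(px)),
    I = as.numeric(px)
  )
  g <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$I)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::theme_void()
  seg_df <- function(m, what) {
    data.frame(x = m[1, 1], y = m[1, 2], xend = m[2, 1], yend = m[2, 2],
               what = what)
  }
  if (!is.null(init)) {
    segs <- rbind(seg_df(init$deep_line, "deep"),
                  seg_df(init$superficial_line, "superficial"),
                  seg_df(init$fascicle_line, "fascicle"))
    g <- g + ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, colour = .data$what),
      inherit.aes = FALSE, linewidth = 0.4
    )
  }
  if (!is.null(series)) {
    row <- series[series$frame == frame$index, ]
    if (nrow(row) == 1) {
      pts <- data.frame(x = c(row$ax, row$bx), y = c(row$ay, row$by))
      g <- g +
        ggplot2::geom_segment(
          data = pts[1, ],
          ggplot2::aes(x = .data$x, y = .data$y),
          xend = pts$x[2], yend = pts$y[2],
          inherit.aes = FALSE, colour = "yellow", linewidth = 0.5
        ) +
        ggplot2::geom_point(data = pts, ggplot2::aes(x = .data$x, y = .data$y),
                            inherit.aes = FALSE, colour = "red", size = 1.5)
    }
  }
  g
}
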