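# Plots: the split-read dot plot (read offset vs mapped unit position,
# with an unmapped lane), repeat-length histograms and the active-copy
# fit.

#' Split-read dot plot of one read
#'
#' Each mapped section is drawn at (read offset, unit position), coloured
#' by strand; unmapped sections sit in a lane below zero (UM). Optional
#' binned methylation bars are overlaid along the read.
#'
#' @param map An `rdna_read_map`.
#' @param ref The `rdna_reference`.
#' @param methylation Optional [bin_methylation()] tibble for the read.
#' @return A ggplot object.
#' @export
plot_read_dotplot <- function(map, ref, methylation = NULL) {
  s <- map$splits
  L <- ref$unit_length
  um_lane <- -0.06 * L
  s$y <- ifelse(is.na(s$ref_pos), um_lane, s$ref_pos)
  s$state <- ifelse(is.na(s$ref_pos), "unmapped", s$strand)
  p <- ggplot2::ggplot(s, ggplot2::aes(
    x = .data$read_offset, y = .data$y,
    colour = .data$state
  )) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(
      yintercept = c(0, ref$coding_interval[2], L),
      linetype = "dashed", linewidth = 0.3, colour = "grey50"
    ) +
    ggplot2::scale_colour_manual(values = c(
      "+" = "#1b6ca8", "-" = "#c23b22", "unmapped" = "grey60"
    )) +
    ggplot2::labs(
      x = "position in read (bases)",
      y = "mapped position in unit (bases; UM lane below 0)",
      colour = NULL,
      title = sprintf("%s (%d bases)", map$read_id, map$read_length)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(methylation) && nrow(methylation) > 0L) {
    mb <- methylation
    mb$h <- mb$avg_freq * 0.05 * L
    p <- p + ggplot2::geom_rect(
      data = mb, inherit.aes = FALSE,
      ggplot2::aes(
        xmin = .data$bin_start, xmax = .data$bin_start + 200,
        ymin = um_lane * 2, ymax = um_lane * 2 + .data$h
      ),
      fill = "magenta"
    )
  }
  p
}

#' @method autoplot rdna_read_map
#' @export
autoplot.rdna_read_map <- function(object, ref, ...) {
  plot_read_dotplot(object, ref, ...)
}

#' Histograms of per-copy repeat-length deltas
#'
#' @param estimates Tibble from [estimate_repeat_lengths()].
#' @param binwidth Histogram bin width in bases.
#' @return A ggplot object (one facet per repeat).
#' @export
plot_repeat_deltas <- function(estimates, binwidth = 200) {
  long <- tidyr::pivot_longer(
    estimates[, c("delta_r", "delta_bl")],
    dplyr::everything(),
    names_to = "metric", values_to = "delta"
  )
  long <- long[!is.na(long$delta), , drop = FALSE]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$delta)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "#1b6ca8") +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(
      x = "length difference from reference (bases)",
      y = "copies"
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot rdna_active_fit
#' @export
autoplot.rdna_active_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble(
    copies_per_cell = seq(min(d$copies_per_cell), max(d$copies_per_cell),
      length.out = 100
    )
  )
  grid$fit <- object$A / grid$copies_per_cell
  grid$ref <- object$reference_constant / grid$copies_per_cell
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$copies_per_cell,
    y = .data$unmethylated_proportion
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_line(
      data = grid, ggplot2::aes(y = .data$fit),
      colour = "#1b6ca8"
    ) +
    ggplot2::geom_line(
      data = grid, ggplot2::aes(y = .data$ref),
      colour = "grey50", linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "rDNA copies per cell",
      y = "unmethylated proportion",
      title = sprintf(
        "fitted constant active copies A = %.0f (dashed: %d)",
        object$A, object$reference_constant
      )
    ) +
    ggplot2::theme_minimal()
}
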