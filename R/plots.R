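#' Plot a delta-index genome scan
#'
#' Per-site delta indexes as points, the sliding-window mean as a line, and
#' the calling threshold as a horizontal rule, faceted by chromosome — the
#' standard way to eyeball where a pooled scan peaks.
#'
#' @param object A `bsa_profile` from [sliding_window_profile()].
#' @param stats Optional per-site statistics tibble to draw as points.
#' @param threshold Optional threshold line.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bsa_profile
#' @export
autoplot.bsa_profile <- function(object, stats = NULL, threshold = NULL, ...) {
  window <- attr(object, "window")
  p <- ggplot2::ggplot()
  if (!is.null(stats)) {
    p <- p + ggplot2::geom_point(
      data = stats,
      ggplot2::aes(x = .data$pos, y = .data$delta_index),
      colour = "grey60", size = 0.4, alpha = 0.6
    )
  }
  mid <- dplyr::mutate(
    tibble::as_tibble(object),
    mid = .data$start + window / 2
  )
  p <- p + ggplot2::geom_line(
    data = mid[!is.na(mid$mean_delta), ],
    ggplot2::aes(x = .data$mid, y = .data$mean_delta),
    colour = "red", linewidth = 0.7
  )
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, colour = "blue", linetype = 2)
  }
  p +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = expression(Delta * " marker index")) +
    ggplot2::theme_minimal()
}

#' Manhattan plot of per-site G values
#'
#' @param stats Per-site statistics tibble with `g_value`.
#' @param q Highlight the top quantile of sites (default 0.001); `NULL`
#'   disables highlighting.
#' @return A ggplot object.
#' @export
plot_g_manhattan <- function(stats, q = 0.001) {
  assert_columns(stats, c("chrom", "pos", "g_value"))
  p <- ggplot2::ggplot(stats, ggplot2::aes(x = .data$pos, y = .data$g_value)) +
    ggplot2::geom_point(size = 0.4, colour = "grey40") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "G value") +
    ggplot2::theme_minimal()
  if (!is.null(q) && nrow(stats) > 0) {
    top <- top_quantile_sites(stats, q)
    p <- p + ggplot2::geom_point(data = top, colour = "red", size = 0.8)
  }
  p
}
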