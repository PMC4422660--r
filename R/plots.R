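#' Plot cross-validation metrics
#'
#' Bar chart of the seven metrics' fold means with +/- 1 sd error bars.
#'
#' @param object An `mld_cv` from [mld_cross_validate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mld_cv <- function(object, ...) {
  s <- dplyr::mutate(object$summary,
                     metric = factor(.data$metric, levels = .data$metric))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$metric, y = 100 * .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = 100 * (.data$mean - .data$sd),
                   ymax = 100 * (.data$mean + .data$sd)),
      width = 0.2
    ) +
    ggplot2::labs(
      x = NULL, y = "percent",
      title = sprintf("%d-fold cross-validation (%s, N = %d, M = %d)",
                      object$config$k, object$config$classifier,
                      object$config$n_trees, object$config$mtry)
    ) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Plot a hyperparameter sweep
#'
#' Mean CV accuracy against ensemble size N, one line per feature-subset
#' size M (or against M when a single N was swept).
#'
#' @param object An `mld_sweep` from [mld_sweep()].
#' @param metric Which metric column to plot (default `"acc"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mld_sweep <- function(object, metric = "acc", ...) {
  if (length(unique(object$n_trees)) > 1L) {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$n_trees,
                                         y = 100 * .data[[metric]],
                                         colour = factor(.data$mtry))) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::labs(x = "ensemble size N", y = paste(metric, "(%)"),
                    colour = "M") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$mtry,
                                         y = 100 * .data[[metric]])) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::labs(x = "features per split M", y = paste(metric, "(%)")) +
      ggplot2::theme_minimal()
  }
}

#' Diagram of the multi-scale region layout
#'
#' Shows each contiguous region as a horizontal bar over the segment axis —
#' the region layout the encoder concatenates descriptors over.
#'
#' @param n_segments,include_full Passed to [build_region_masks()].
#' @return A ggplot object.
#' @export
plot_region_masks <- function(n_segments = 4L, include_full = FALSE) {
  masks <- build_region_masks(n_segments, include_full)
  ggplot2::ggplot(masks) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$seg_start - 1, xend = .data$seg_end,
                   y = .data$region, yend = .data$region),
      linewidth = 4, colour = "steelblue"
    ) +
    ggplot2::geom_text(ggplot2::aes(x = n_segments + 0.4, y = .data$region,
                                    label = .data$mask), hjust = 0, size = 3) +
    ggplot2::scale_y_reverse(breaks = masks$region) +
    ggplot2::scale_x_continuous(breaks = 0:n_segments, limits = c(0, n_segments + 1.2)) +
    ggplot2::labs(x = "segment boundary", y = "region",
                  title = sprintf("%d contiguous regions over %d segments",
                                  nrow(masks), n_segments)) +
    ggplot2::theme_minimal()
}
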