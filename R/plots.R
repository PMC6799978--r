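## ggplot2 displays for the main result types.

#' Plot delta-F/F traces by ROI
#'
#' @param ts A [trace_set()].
#' @param rois Optional subset of ROI labels.
#' @return A ggplot.
#' @export
plot_traces <- function(ts, rois = NULL) {
  df <- tidy(ts)
  if (!is.null(rois)) df <- dplyr::filter(df, .data$roi %in% rois)
  value <- names(df)[3]
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data[[value]])) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$roi)) +
    ggplot2::labs(x = "time (s)",
                  y = if (value == "dff") expression(Delta * f / f) else "raw") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.corr_map <- function(object, ...) {
  n <- length(object$labels)
  df <- tibble::tibble(
    i = rep(seq_len(n), times = n), j = rep(seq_len(n), each = n),
    r = as.vector(object$r)
  )
  breaks <- cumsum(rle(object$labels)$lengths)
  ggplot2::ggplot(df, ggplot2::aes(.data$i, .data$j, fill = .data$r)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-1, 1)) +
    ggplot2::geom_hline(yintercept = breaks + 0.5, linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = breaks + 0.5, linewidth = 0.2) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "r",
                  title = "Voxel cross-correlogram (region-ordered)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.bin_stats <- function(object, ...) {
  conf <- attr(object, "conf") %||% 0.9
  ggplot2::ggplot(object, ggplot2::aes(.data$bin_start, .data$p_hat)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo,
                                          ymax = .data$ci_hi)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "P(hunting bout)",
                  title = sprintf("Hunting-bout probability (%d%% CI)",
                                  round(conf * 100))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sta <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$lag, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "lag (s)", y = expression(Delta * f / f),
                  title = sprintf("Spike-triggered average (n = %d)",
                                  attr(object, "n_used"))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.rank_enrichment <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$rank, .data$ratio,
                               color = .data$target)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, color = "gray50") +
    ggplot2::facet_wrap(ggplot2::vars(.data$source)) +
    ggplot2::labs(x = "anti-correlation rank", y = "probability / chance",
                  title = "Most anti-correlated partner region, by rank") +
    ggplot2::theme_minimal()
}
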