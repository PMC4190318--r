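#' Manhattan plot of an association scan
#'
#' @param object a `recmapr_scan` from [assoc_scan()]
#' @param threshold optional genome-wide significance line on the -log10
#'   scale (defaults to the Bonferroni level 0.05 / m)
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.recmapr_scan <- function(object, threshold = NULL, ...) {
  d <- tibble::as_tibble(object)
  d$chrom <- factor(d$chrom, levels = unique(d$chrom))
  offsets <- d |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(len = max(.data$pos)) |>
    dplyr::mutate(offset = cumsum(dplyr::lag(.data$len, default = 0)))
  d <- dplyr::left_join(d, offsets[, c("chrom", "offset")], by = "chrom")
  thr <- threshold %||% -log10(0.05 / attr(object, "m"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$offset + .data$pos,
                                  y = -log10(.data$p_raw),
                                  colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::labs(x = "genome position", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}

#' Plot runs of homozygosity across samples
#'
#' One horizontal bar per ROH segment, samples on the y axis; optionally
#' overlays a critical interval.
#'
#' @param segments tibble from [detect_roh()] (possibly several samples
#'   bound together)
#' @param interval optional one-row tibble from
#'   [shared_autozygous_segment()]
#' @return a ggplot
#' @export
plot_roh_segments <- function(segments, interval = NULL) {
  p <- ggplot2::ggplot(segments) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$start_bp / 1e6, xend = .data$end_bp / 1e6,
      y = .data$sample_id, yend = .data$sample_id),
      linewidth = 3, colour = "steelblue") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(interval) && nrow(interval) == 1) {
    p <- p + ggplot2::annotate(
      "rect", xmin = interval$left_bound_bp / 1e6,
      xmax = interval$right_bound_bp / 1e6,
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "firebrick")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
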