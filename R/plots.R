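#' Plot per-position methylation distributions around a region
#'
#' Whisker-bounded boxplot summaries per group for every retained position in
#' a window, mirroring the per-position statistics the filters act on.
#'
#' @param stats Per-position statistics from [site_statistics()] (or
#'   `msp_result$stats`).
#' @param chrom,start,end Optional window restriction.
#' @return A ggplot.
#' @export
plot_site_methylation <- function(stats, chrom = NULL, start = NULL, end = NULL) {
  df <- stats
  if (!is.null(chrom)) df <- dplyr::filter(df, .data$chrom == !!chrom)
  if (!is.null(start)) df <- dplyr::filter(df, .data$start >= !!start)
  if (!is.null(end)) df <- dplyr::filter(df, .data$start < !!end)
  df <- dplyr::filter(df, .data$n > 0L)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start, group = interaction(.data$start, .data$group),
                                   fill = .data$group)) +
    ggplot2::geom_boxplot(
      ggplot2::aes(ymin = .data$p0, lower = .data$p25, middle = .data$p50,
                   upper = .data$p75, ymax = .data$p100),
      stat = "identity", width = 0.9, linewidth = 0.2
    ) +
    ggplot2::labs(x = "position (0-based)", y = "methylation [%]", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot MSP region scores along the genome
#'
#' @param regions Regions tibble ([pair_primers()] output or
#'   `tidy(msp_result)`).
#' @return A ggplot; the flagged best region is highlighted.
#' @export
plot_region_scores <- function(regions) {
  ggplot2::ggplot(regions,
                  ggplot2::aes(x = (.data$start + .data$end) / 2, y = .data$score)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start, xend = .data$end,
                                       yend = .data$score, colour = .data$is_best)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "position (0-based)", y = "MSP region score") +
    ggplot2::theme_minimal()
}

#' @rdname plot_region_scores
#' @param object An `msp_result`.
#' @param ... Unused.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.msp_result <- function(object, ...) {
  plot_region_scores(object$regions)
}

#' @export
ggplot2::autoplot
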