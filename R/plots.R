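#' Plot LRR of a region with segment means and calls
#'
#' Scatter of per-locus log R ratios with the segment-mean projection
#' overlaid in red and, optionally, HMM call extents marked — the standard
#' view for judging whether a putative CNV is supported in both members of a
#' sample pair.
#'
#' @param sample A sample series tibble.
#' @param segments Optional [segment_sample()] output to overlay.
#' @param calls Optional call tibble to mark.
#' @param chrom Chromosome to show (default: first).
#' @param xlim Optional bp window.
#' @return A ggplot object.
#' @export
plot_lrr <- function(sample, segments = NULL, calls = NULL, chrom = NULL,
                     xlim = NULL) {
  chrom <- chrom %||% sample$chrom[1]
  dat <- sample[sample$chrom == chrom, , drop = FALSE]
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$pos / 1e6,
                                         y = .data$lrr)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5, colour = "grey40") +
    ggplot2::labs(x = sprintf("chromosome %s position (Mb)", chrom),
                  y = "log R ratio") +
    ggplot2::theme_minimal()
  if (!is.null(segments)) {
    seg <- segments[segments$chrom == chrom, , drop = FALSE]
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$start_bp / 1e6, xend = .data$end_bp / 1e6,
                   y = .data$seg_mean, yend = .data$seg_mean),
      colour = "red", linewidth = 0.9, inherit.aes = FALSE)
  }
  if (!is.null(calls) && nrow(calls) > 0) {
    cc <- calls[calls$chrom == chrom, , drop = FALSE]
    if (nrow(cc) > 0)
      p <- p + ggplot2::geom_rect(
        data = cc,
        ggplot2::aes(xmin = .data$start_bp / 1e6, xmax = .data$end_bp / 1e6),
        ymin = -Inf, ymax = Inf, fill = "steelblue", alpha = 0.15,
        inherit.aes = FALSE)
  }
  if (!is.null(xlim)) p <- p + ggplot2::coord_cartesian(xlim = xlim / 1e6)
  p
}

#' Plot a concordance report
#'
#' Boxplots of per-pair Pearson correlations by relatedness and tissue
#' combination, one panel per method — the visual form of the category
#' ordering (self above mother-child above unrelated).
#'
#' @param object A `concordance_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.concordance_report <- function(object, ...) {
  dat <- object$pairs
  dat$relatedness <- factor(dat$relatedness,
                            levels = c("self", "mother_child", "unrelated"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$relatedness, y = .data$r,
                                    fill = .data$tissue_combo)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(x = NULL, y = "Pearson r of LRR series",
                  fill = "tissues") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Plot CNV counts per subject across LBF thresholds
#'
#' @param summary Output of [summarize_cnvs()].
#' @return A ggplot object.
#' @export
plot_call_counts <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = factor(.data$lbf_threshold),
                               y = .data$mean_calls_per_subject,
                               fill = .data$tissue)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "LBF threshold", y = "mean CNV calls per subject",
                  fill = "tissue") +
    ggplot2::theme_minimal()
}
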