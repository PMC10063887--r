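#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Manhattan-style plot of scan scores
#'
#' @param object A `scan_scores` tibble ([ihs()] / [xpehh()], optionally
#'   after [scan_significance()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.scan_scores <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$pos,
                                            y = .data$score)) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "position (bp)",
                  y = paste(attr(object, "method"), "(standardized)")) +
    ggplot2::theme_minimal()
  if ("significant" %in% names(object)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$significant),
                            size = 0.6) +
      ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                              `TRUE` = "firebrick"))
  } else {
    p + ggplot2::geom_point(size = 0.6, colour = "grey40")
  }
}

#' LD decay curve
#'
#' @param ld An [ld_decay()] tibble.
#' @return A ggplot of mean r-squared against distance.
#' @export
plot_ld_decay <- function(ld) {
  ggplot2::ggplot(ld, ggplot2::aes(x = .data$dist_bin / 1000,
                                   y = .data$mean_r2)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "distance (kb)", y = expression(mean ~ r^2)) +
    ggplot2::theme_minimal()
}

#' MAF spectrum barplot
#'
#' @param spectrum A [maf_spectrum()] tibble.
#' @return A ggplot.
#' @export
plot_maf_spectrum <- function(spectrum) {
  ggplot2::ggplot(spectrum, ggplot2::aes(x = .data$bin, y = .data$n_sites)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "minor allele frequency", y = "sites") +
    ggplot2::theme_minimal()
}

#' Windowed Tajima's D track
#'
#' @param windows A [tajimas_d()] tibble.
#' @param d_tail Tail fraction drawn as threshold lines.
#' @return A ggplot.
#' @export
plot_tajima <- function(windows, d_tail = 0.05) {
  thr <- quantile(windows$tajima_d, c(d_tail, 1 - d_tail), na.rm = TRUE)
  ggplot2::ggplot(windows, ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                        y = .data$tajima_d)) +
    ggplot2::geom_point(size = 0.7, colour = "grey40") +
    ggplot2::geom_hline(yintercept = thr, linetype = 2, colour = "firebrick") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "Tajima's D") +
    ggplot2::theme_minimal()
}

#' PCoA scatter
#'
#' @param object A [pcoa()] result.
#' @param groups Optional tibble with `sample`, `population` for colour.
#' @param ... Unused.
#' @return A ggplot of the first two axes.
#' @export
autoplot.pcoa_result <- function(object, groups = NULL, ...) {
  pts <- object$points
  if (!is.null(groups)) pts <- dplyr::left_join(pts, groups, by = "sample")
  aes <- if (!is.null(groups)) {
    ggplot2::aes(x = .data$axis1, y = .data$axis2,
                 colour = .data$population)
  } else ggplot2::aes(x = .data$axis1, y = .data$axis2)
  ggplot2::ggplot(pts, aes) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("PCo1 (%.1f%%)", 100 * object$rel_eig[1]),
      y = sprintf("PCo2 (%.1f%%)", 100 * object$rel_eig[2])) +
    ggplot2::theme_minimal()
}
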