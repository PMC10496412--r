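# Diagnostic plots: Nc-GC3s with the neutral expectation curve, the
# neutrality regression, and the PR2 quadrant scatter.

#' Nc-GC3s plot with the neutral expectation curve
#'
#' Scatter of per-gene Nc against GC3s with Wright's expected curve under a
#' neutral mutation model; genes far below the curve are candidates for
#' translational selection.
#'
#' @param metrics A [codon_metrics()] tibble; an optional
#'   [assign_bias_categories()] partition colors genes by category.
#' @param partition Optional bias partition.
#' @return A ggplot object.
#' @export
plot_nc_gc3s <- function(metrics, partition = NULL) {
  d <- metrics[!is.na(metrics$nc) & !is.na(metrics$gc3s), , drop = FALSE]
  if (!is.null(partition)) {
    d$category <- partition$category[match(d$gene_id, partition$gene_id)]
  }
  curve <- tibble::tibble(gc3s = seq(0.01, 0.99, 0.01))
  curve$nc <- pmin(expected_nc(curve$gc3s), 61)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$gc3s, y = .data$nc)) +
    (if (is.null(partition)) ggplot2::geom_point(alpha = 0.4, size = 0.8)
     else ggplot2::geom_point(ggplot2::aes(color = .data$category),
                              alpha = 0.5, size = 0.8)) +
    ggplot2::geom_line(data = curve, linewidth = 0.7) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(20, 61)) +
    ggplot2::labs(x = "GC3s", y = "Nc")
  p
}

#' Neutrality plot (GC12 vs GC3) with the fitted line
#'
#' @param x A `cub_neutrality` fit from [neutrality_fit()].
#' @return A ggplot object.
#' @export
plot_neutrality <- function(x) {
  ggplot2::ggplot(x$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = x$slope, intercept = x$intercept,
                         linewidth = 0.7) +
    ggplot2::labs(
      x = toupper(x$x), y = toupper(x$y),
      subtitle = sprintf("y = %.3fx + %.3f, r = %.3f", x$slope, x$intercept,
                         x$r)
    )
}

#' @export
autoplot.cub_neutrality <- function(object, ...) plot_neutrality(object)

#' Parity rule 2 plot
#'
#' G3/(G3+C3) against A3/(A3+T3) with crosshairs at the no-strand-bias
#' center (0.5, 0.5).
#'
#' @param pr2 A [pr2_analysis()] tibble.
#' @return A ggplot object.
#' @export
plot_pr2 <- function(pr2) {
  ggplot2::ggplot(pr2, ggplot2::aes(x = .data$x, y = .data$y,
                                    color = .data$quadrant)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "G3/(G3+C3)", y = "A3/(A3+T3)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
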