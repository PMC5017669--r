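#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a 5'-end pileup track
#'
#' Single-nucleotide read-count profile along the reference; minus-strand
#' tracks are drawn downward, matching the convention of drawing the plus
#' strand above and the minus strand below the genome axis.
#'
#' @param object An `srna_track`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.srna_track <- function(object, ...) {
  sgn <- if (attr(object, "strand") == "-") -1 else 1
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$pos, y = sgn * .data$count)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$pos, yend = 0)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::xlim(0, attr(object, "ref_length")) +
    ggplot2::labs(
      x = sprintf("position on %s (nt)", attr(object, "ref_id")),
      y = sprintf("5'-end read count (%s strand)", attr(object, "strand")),
      title = sprintf("%s [%s], %s", attr(object, "ref_id"),
                      attr(object, "strand"), attr(object, "weighting"))) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.srna_track
#' @export
autoplot.srna_binned <- function(object, ...) {
  sgn <- if (attr(object, "strand") == "-") -1 else 1
  w <- attr(object, "width")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$bin_start + w / 2,
                               y = sgn * .data$count)) +
    ggplot2::geom_col(width = w) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::xlim(0, attr(object, "ref_length")) +
    ggplot2::labs(
      x = sprintf("position on %s (nt, %d-nt bins)",
                  attr(object, "ref_id"), w),
      y = sprintf("read count (%s strand)", attr(object, "strand"))) +
    ggplot2::theme_minimal()
}

#' Fold-change scatter of miRNA expression between two samples
#'
#' Log-log scatter of normalised miRNA levels with the equal-expression
#' diagonal in red, solid lines at the first band limit (2-fold), dashed
#' lines at the second (5-fold), a dashed square marking the
#' representativeness floor, and the beyond-5-fold miRNAs highlighted and
#' labelled.
#'
#' @param object An `srna_fold_change` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.srna_fold_change <- function(object, ...) {
  pc <- attr(object, "pseudocount")
  bands <- attr(object, "bands")
  floor <- attr(object, "floor")
  smp <- attr(object, "samples")
  df <- tibble::tibble(
    a = object$norm_a + pc, b = object$norm_b + pc,
    class = object$class, mirna = object$mirna)
  hi <- df[object$class == "beyond_5fold", ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
    ggplot2::geom_abline(slope = 1, intercept = log10(bands[1]),
                         colour = "grey50") +
    ggplot2::geom_abline(slope = 1, intercept = -log10(bands[1]),
                         colour = "grey50") +
    ggplot2::geom_abline(slope = 1, intercept = log10(bands[2]),
                         colour = "grey50", linetype = "dashed") +
    ggplot2::geom_abline(slope = 1, intercept = -log10(bands[2]),
                         colour = "grey50", linetype = "dashed") +
    ggplot2::annotate("rect", xmin = pc, xmax = floor, ymin = pc,
                      ymax = floor, fill = NA, colour = "grey40",
                      linetype = "dashed") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$class), size = 0.8) +
    ggplot2::geom_point(data = hi, colour = "red", size = 1.6) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = smp[["a"]], y = smp[["b"]],
                  colour = "regulation") +
    ggplot2::theme_minimal()
  if (nrow(hi) > 0) {
    p <- p + ggplot2::geom_text(data = hi,
                                ggplot2::aes(label = .data$mirna),
                                vjust = -1, size = 3)
  }
  p
}
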