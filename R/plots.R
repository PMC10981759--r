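#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a novelty result
#'
#' Histogram of per-cell novelty scores coloured by the novel call, with
#' the threshold marked.
#'
#' @param object A `novelty_result` from [call_novel()] or
#'   [detect_novel()].
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.novelty_result <- function(object, bins = 40, ...) {
  lambda <- attr(object, "lambda")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$novelty_score,
                               fill = .data$is_novel)) +
    ggplot2::geom_histogram(bins = bins, position = "identity",
                            alpha = 0.8) +
    ggplot2::geom_vline(xintercept = lambda, linetype = "dashed") +
    ggplot2::labs(x = "novelty score (1 - confidence)", y = "cells",
                  fill = "called novel",
                  title = sprintf("%s mode, lambda = %.2f",
                                  toupper(object$mode[1]), lambda)) +
    ggplot2::theme_minimal()
}

#' Plot an evaluation report
#'
#' AUROC per score mode, faceted by holdout size when several `c_novel`
#' values are present.
#'
#' @param object An `eval_report` from [run_experiment()].
#' @param metric Column to plot (`"auroc"`, `"aupr"` or `"fpr95"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, metric = "auroc", ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = toupper(.data$mode),
                                    y = .data[[metric]])) +
    ggplot2::geom_col() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "score mode", y = metric) +
    ggplot2::theme_minimal()
  if (length(unique(object$c_novel)) > 1) {
    p <- p + ggplot2::facet_wrap(~c_novel, labeller = ggplot2::label_both)
  }
  p
}

#' Volcano plot of a two-group differential-expression result
#'
#' @param de A `de_result` from [group_de()].
#' @param label_top Number of top significant genes to label.
#' @return A ggplot object.
#' @export
plot_volcano <- function(de, label_top = 8) {
  stopifnot(inherits(de, "de_result"))
  de$neglog10p <- -log10(pmax(de$p_adj, 1e-300))
  p <- ggplot2::ggplot(de, ggplot2::aes(x = .data$log2fc,
                                        y = .data$neglog10p,
                                        colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "log2 fold-change",
                  y = "-log10 adjusted p",
                  colour = "significant") +
    ggplot2::theme_minimal()
  sig <- de[de$significant, ]
  if (nrow(sig) > 0) {
    sig <- sig[order(sig$p_adj), ]
    sig <- sig[seq_len(min(label_top, nrow(sig))), ]
    p <- p + ggplot2::geom_text(data = sig,
                                ggplot2::aes(label = .data$gene_id),
                                vjust = -0.6, size = 3,
                                show.legend = FALSE)
  }
  p
}
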