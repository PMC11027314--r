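# Diagnostic plots: the NMB-NAB scatter colored by category, the
# bias-by-allele-length plot with median/quartile whiskers, and ROC/PR
# curves for site-bias rankings.

CATEGORY_COLORS <- c(balanced = "forestgreen", loss = "darkorange",
                     flux = "steelblue", local = "purple",
                     outlier = "gray50", unclassifiable = "gray85")

#' NMB-NAB scatter plot
#'
#' Each point is a HET site placed by its normalized mapping balance
#' (horizontal) and normalized assignment balance (vertical), colored by
#' bias category (balanced green, loss orange, flux blue, local purple,
#' outliers gray).
#'
#' @param records output of [balance_table()].
#' @param classifier a [classifier_config()] (drawn as the balanced circle).
#' @return a ggplot object.
#' @export
plot_nmb_nab <- function(records, classifier = classifier_config()) {
  df <- records[!is.na(records$NMB) & !is.na(records$NAB), , drop = FALSE]
  th <- seq(0, 2 * pi, length.out = 181)
  circ <- data.frame(x = classifier$balanced_radius * cos(th),
                     y = classifier$balanced_radius * sin(th))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$NMB, y = .data$NAB,
                                   color = .data$category)) +
    ggplot2::geom_hline(yintercept = 0, color = "gray80") +
    ggplot2::geom_vline(xintercept = 0, color = "gray80") +
    ggplot2::geom_path(data = circ, ggplot2::aes(x = .data$x, y = .data$y),
                       inherit.aes = FALSE, color = "gray60",
                       linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.7, size = 1.4) +
    ggplot2::scale_color_manual(values = CATEGORY_COLORS, drop = TRUE) +
    ggplot2::coord_equal(xlim = c(-1, 1), ylim = c(-1, 1)) +
    ggplot2::labs(x = "NMB (MB - SB)", y = "NAB (AB - SB)",
                  color = "category") +
    ggplot2::theme_minimal()
}

#' Bias-by-allele-length plot
#'
#' Dots are per-stratum medians of the ALT fraction, whiskers the first and
#' third quartiles; variant length runs along the x axis (negative =
#' deletions, 0 = SNVs, positive = insertions; lengths beyond 25 bp are
#' collapsed).
#'
#' @param summary output of [bias_by_length()].
#' @return a ggplot object.
#' @export
plot_bias_by_length <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$stratum, y = .data$median,
                                        color = .data$measure)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$q1, ymax = .data$q3),
                           width = 0.4, alpha = 0.6,
                           position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(width = 0.5),
                       alpha = 0.4) +
    ggplot2::labs(x = "variant length (bp; - deletion, + insertion)",
                  y = "ALT fraction") +
    ggplot2::theme_minimal()
}

#' ROC curves for the two score modes
#' @param evaluation list with `mul` and `add` [evaluate_ranking()] results.
#' @return a ggplot object.
#' @export
plot_roc <- function(evaluation) {
  df <- rbind(cbind(evaluation$mul$roc, mode = "mul"),
              cbind(evaluation$add$roc, mode = "add"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                   color = .data$mode)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, color = "gray80",
                         linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}

#' Precision-recall curves for the two score modes
#' @inheritParams plot_roc
#' @return a ggplot object.
#' @export
plot_pr <- function(evaluation) {
  df <- rbind(cbind(evaluation$mul$pr, mode = "mul"),
              cbind(evaluation$add$pr, mode = "add"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$recall, y = .data$precision,
                                   color = .data$mode)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "recall", y = "precision") +
    ggplot2::theme_minimal()
}

save_plot <- function(p, path, width = 6, height = 5) {
  tryCatch(ggplot2::ggsave(path, p, width = width, height = height, dpi = 120),
           error = function(e) warning("could not save plot ", path, ": ",
                                       conditionMessage(e)))
  invisible(path)
}
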