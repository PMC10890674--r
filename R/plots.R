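# ggplot2 helpers for the main result types.

#' Calibration curves of validated proportion against score
#'
#' For labeled scores, plots the proportion of sites at or above each
#' score threshold that are concordant ("validated") and discordant
#' ("false positive"), with the acceptance threshold marked if given —
#' the classic picture used to fix the filter at a target false-positive
#' proportion.
#'
#' @param scores A data frame with `log_bf` and `label` columns (e.g.
#'   from [simulate_labeled_scores()]).
#' @param threshold Optional threshold to mark (e.g. from
#'   [calibrate_threshold()]).
#' @return A ggplot object.
#' @export
plot_calibration <- function(scores, threshold = NULL) {
  scores <- as_tibble(scores)
  ord <- order(scores$log_bf, decreasing = TRUE)
  s <- scores$log_bf[ord]
  disc <- cumsum(scores$label[ord] == "discordant") / seq_along(s)
  df <- tibble(score = rep(s, 2),
               proportion = c(1 - disc, disc),
               class = rep(c("concordant", "discordant"), each = length(s)))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$score,
                                        y = .data$proportion,
                                        colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(
      values = c(concordant = "black", discordant = "red")) +
    ggplot2::labs(x = "log Bayes factor threshold",
                  y = "proportion among accepted sites",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(threshold) && is.finite(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold, linetype = "dashed")
  }
  p
}

#' @describeIn best_network Histogram of the permutation null with the
#'   observed cluster score marked.
#' @param object A `cluster_result`.
#' @export
autoplot.cluster_result <- function(object, ...) {
  df <- tibble(score = object$null_scores)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$score, colour = "red") +
    ggplot2::labs(
      title = sprintf("k = %d: score %.3g, p_raw = %.3g, z = %.2f",
                      object$k, object$score, object$p_raw, object$z),
      x = "null cluster score", y = "permutations") +
    ggplot2::theme_minimal()
}

#' Bar chart of an annotation enrichment result
#'
#' @param chart Output of [annotation_chart()].
#' @param top_n Number of top terms to show.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(chart, top_n = 15) {
  chart <- head(arrange(as_tibble(chart), .data$p_adj), top_n)
  chart$term <- factor(chart$term_name, levels = rev(chart$term_name))
  ggplot2::ggplot(chart, ggplot2::aes(x = -log10(.data$p_adj),
                                      y = .data$term)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = expression(-log[10]~adjusted~italic(p)), y = NULL) +
    ggplot2::theme_minimal()
}
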