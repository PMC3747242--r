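#' Scatterplot of binding-site vs Pol2 dimorphism scores
#'
#' One point per gene: its best-magnitude peak score against its Pol2
#' gene-body score, coloured by the final call. Genes in the upper-right /
#' lower-left quadrants beyond the threshold satisfy the combined
#' criterion.
#'
#' @param result a `dimorphism_result` (see [run_classify()]).
#' @param threshold score threshold drawn as guide lines.
#' @return A ggplot object.
#' @export
plot_score_scatter <- function(result, threshold = 6) {
  d <- filter(result$calls, !is.na(.data$best_peak_score),
              !is.na(.data$pol2_score))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$best_peak_score,
                                  y = .data$pol2_score,
                                  colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = c(-threshold, threshold),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_vline(xintercept = c(-threshold, threshold),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(male_dominant = "#2166ac",
                                            female_dominant = "#b2182c",
                                            none = "grey70")) +
    ggplot2::labs(x = "best peak score (signed)",
                  y = "Pol2 gene-body score (signed)", colour = "call") +
    ggplot2::theme_minimal()
}

#' Bar chart of score strata per condition set
#'
#' @param scores a `dimorphism_scores` or `dimorphism_result`.
#' @return A ggplot object.
#' @export
plot_strata <- function(scores) {
  ggplot2::ggplot(scores$strata,
                  ggplot2::aes(x = factor(.data$stratum,
                                          c("High", "Medium", "Low")),
                               y = .data$n, fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "score stratum", y = "peaks", fill = "peak set") +
    ggplot2::theme_minimal()
}

#' Histogram of signed peak scores
#'
#' @param object a `scored_peaks` tibble (see [score_peaks()]).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot scored_peaks
#' @export
autoplot.scored_peaks <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey40") +
    ggplot2::geom_vline(xintercept = c(-6, 6), linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = "signed dimorphism score", y = "peaks") +
    ggplot2::theme_minimal()
}

#' Score vs expression scatterplot
#'
#' @param object a `score_expression_cor`
#'   (see [score_expression_correlation()]).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot score_expression_cor
#' @export
autoplot.score_expression_cor <- function(object, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(x = .data$score,
                                             y = .data$log2_fc)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::labs(x = "chromatin score (signed)",
                  y = "expression log2 fold change (male/female)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_score_scatter
#' @param object a `dimorphism_result`.
#' @param ... unused.
#' @method autoplot dimorphism_result
#' @export
autoplot.dimorphism_result <- function(object, ...) plot_score_scatter(object, ...)
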