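# ggplot2 autoplot() methods for the package's result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the detector weights as a position-by-factor map
#'
#' Positive weights point up, negative down, one panel per Atchley factor —
#' large negative weights on a factor mean snippets with negative values
#' there push the score toward a positive diagnosis.
#'
#' @param object A `snippet_fit` with the Atchley encoding.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot snippet_fit
autoplot.snippet_fit <- function(object, ...) {
  wm <- weight_map(object)
  ggplot2::ggplot(wm, ggplot2::aes(x = factor(.data$position),
                                   y = .data$weight,
                                   fill = .data$weight > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_wrap(~factor, nrow = 1,
                        labeller = ggplot2::label_both) +
    ggplot2::scale_fill_manual(values = c("TRUE" = "#b2182b",
                                          "FALSE" = "#2166ac")) +
    ggplot2::labs(x = "snippet position", y = "weight",
                  title = "Detector weights by position and Atchley factor")
}

#' @export
#' @method autoplot snippet_roc
autoplot.snippet_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$auc))
}

#' @export
#' @method autoplot score_histogram
autoplot.score_histogram <- function(object, ...) {
  ggplot2::ggplot(object$bins,
                  ggplot2::aes(x = .data$bin_low + 0.025, y = .data$n,
                               fill = .data$group)) +
    ggplot2::geom_col(position = "identity", alpha = 0.6, width = 0.05) +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = 2) +
    ggplot2::scale_y_sqrt() +
    ggplot2::scale_fill_manual(values = c(case = "#b2182b",
                                          control = "#2166ac")) +
    ggplot2::labs(x = "snippet score", y = "snippets",
                  title = "Snippet score distribution by diagnosis group")
}

#' @export
#' @method autoplot snippet_permutation
autoplot.snippet_permutation <- function(object, ...) {
  df <- tibble(n_correct = object$permuted_n_correct)
  ggplot2::ggplot(df, ggplot2::aes(.data$n_correct)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey70",
                            colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$observed_n_correct,
                        colour = "#b2182b", linewidth = 1) +
    ggplot2::labs(x = "correct diagnoses under permuted labels",
                  y = "permutations",
                  title = sprintf("Permutation null (p = %.3f)",
                                  object$p_value))
}
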