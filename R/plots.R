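# autoplot() methods for the package's result objects.

#' Plot a confusion matrix
#'
#' Heatmap of the confusion matrix of a `classification_metrics` object.
#'
#' @param object A `classification_metrics`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot classification_metrics
#' @export
autoplot.classification_metrics <- function(object, ...) {
  df <- as.data.frame(object$confusion)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$Freq)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$Freq), colour = "white") +
    ggplot2::scale_fill_gradient(low = "grey30", high = "firebrick") +
    ggplot2::labs(x = "Predicted class", y = "True class",
                  title = sprintf("Accuracy %.1f, macro F %.1f",
                                  object$accuracy, object$f)) +
    ggplot2::theme_minimal()
}

#' Plot ranked effects for a query
#'
#' Horizontal bar chart of effect scores, best-ranked on top.
#'
#' @param object A `ranked_effects` tibble from [rank_effects()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ranked_effects
#' @export
autoplot.ranked_effects <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score,
                                   y = stats::reorder(.data$effect,
                                                      .data$score))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "NPMI score", y = NULL,
                  title = paste0("Effects for query '",
                                 attr(object, "query") %||% "", "'")) +
    ggplot2::theme_minimal()
}

#' Plot cumulative category scores
#'
#' Stacked bar per category; the sections of each bar are the per-effect
#' NPMI contributions to the category total.
#'
#' @param object A `category_scores` tibble from
#'   [cumulative_category_score()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot category_scores
#' @export
autoplot.category_scores <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$contribution,
                                   y = .data$category,
                                   fill = .data$effect)) +
    ggplot2::geom_col(colour = "white", linewidth = 0.2) +
    ggplot2::labs(x = "Cumulative NPMI score", y = NULL,
                  title = paste0("Risk-perception categories for query '",
                                 attr(object, "query") %||% "", "'"),
                  fill = "Effect") +
    ggplot2::theme_minimal()
}

#' Plot match coverage of a gold lexicon
#'
#' @param object A `match_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot match_report
#' @export
autoplot.match_report <- function(object, ...) {
  df <- object$summary
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$match_type,
                                                      .data$percent),
                                   y = .data$percent)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%d (%.1f%%)", .data$n,
                                                    .data$percent)),
                       hjust = -0.05, size = 3) +
    ggplot2::coord_flip() +
    ggplot2::scale_y_continuous(limits = c(0, 110)) +
    ggplot2::labs(x = NULL, y = "Gold phrases covered (%)",
                  title = "Match-type coverage of the gold lexicon") +
    ggplot2::theme_minimal()
}

#' Plot the filter-chain accounting of a pipeline run
#'
#' @param object A `pipeline_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pipeline_report
#' @export
autoplot.pipeline_report <- function(object, ...) {
  df <- object$stage_counts %>%
    mutate(stage = factor(.data$stage, levels = unique(.data$stage)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$n,
                                   fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Messages", fill = "Predicted class",
                  title = "Messages surviving each filter stage") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20, hjust = 1))
}
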