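# broom-style tidiers for the package's fitted/reported objects.

#' Tidy a classification metrics object
#'
#' @param x A `classification_metrics` from [evaluate_classifier()].
#' @param ... Unused.
#' @return Per-class metrics tibble (`class`, `precision`, `recall`, `f`,
#'   `support`), 0-100 scale.
#' @method tidy classification_metrics
#' @export
tidy.classification_metrics <- function(x, ...) {
  x$per_class
}

#' @rdname tidy.classification_metrics
#' @return `glance()` returns a one-row tibble with the macro-averaged
#'   metrics.
#' @method glance classification_metrics
#' @export
glance.classification_metrics <- function(x, ...) {
  tibble(accuracy = x$accuracy, precision = x$precision, recall = x$recall,
         f = x$f, n = x$n)
}

#' Tidy a trained veracity classifier
#'
#' @param x A `veracity_classifier`.
#' @param ... Unused.
#' @return The per-epoch training history for neural kinds (`epoch`,
#'   `train_loss`, `val_f`); a one-row summary for the baselines.
#' @method tidy veracity_classifier
#' @export
tidy.veracity_classifier <- function(x, ...) {
  if (x$kind %in% c("cnn", "bilstm")) x$fit$history
  else tibble(kind = x$kind, n_features = nrow(x$vocabulary) - 2L)
}

#' @rdname tidy.veracity_classifier
#' @return `glance()` returns a one-row tibble: kind, vocabulary size and
#'   (for neural kinds) best epoch and its validation F.
#' @method glance veracity_classifier
#' @export
glance.veracity_classifier <- function(x, ...) {
  neural <- x$kind %in% c("cnn", "bilstm")
  tibble(
    kind = x$kind,
    vocabulary_size = nrow(x$vocabulary),
    best_epoch = if (neural) x$fit$best_epoch else NA_integer_,
    best_val_f = if (neural) x$fit$best_val_f else NA_real_
  )
}

#' Tidy a match report
#'
#' @param x A `match_report` from [match_statistics()].
#' @param ... Unused.
#' @return The aggregate coverage tibble (`match_type`, `n`, `percent`).
#' @method tidy match_report
#' @export
tidy.match_report <- function(x, ...) {
  x$summary
}

#' @rdname tidy.match_report
#' @method glance match_report
#' @export
glance.match_report <- function(x, ...) {
  wide <- setNames(as.list(x$summary$n), paste0("n_", x$summary$match_type))
  bind_rows(tibble(n_gold = x$n_gold, n_candidates = x$n_candidates)) %>%
    dplyr::bind_cols(as_tibble(wide))
}

#' Tidy an effect clustering
#'
#' @param x An `effect_clustering`.
#' @param ... Unused.
#' @return The assignment tibble (`effect`, `cluster`, `is_core`).
#' @method tidy effect_clustering
#' @export
tidy.effect_clustering <- function(x, ...) {
  x$assignment
}

#' @rdname tidy.effect_clustering
#' @method glance effect_clustering
#' @export
glance.effect_clustering <- function(x, ...) {
  cl <- x$assignment$cluster
  tibble(n_phrases = length(cl),
         n_clusters = length(unique(cl[!is.na(cl)])),
         n_noise = sum(is.na(cl)),
         eps = x$eps, min_points = x$min_points)
}

#' Category totals of a cumulative category score
#'
#' @param x A `category_scores` tibble from [cumulative_category_score()].
#' @param ... Unused.
#' @return One row per category: `category`, `total`, `n_effects`.
#' @method glance category_scores
#' @export
glance.category_scores <- function(x, ...) {
  attr(x, "totals")
}
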