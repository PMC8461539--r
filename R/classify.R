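# Veracity classification: data splitting with deduplication, the
# convolutional classifier and BiLSTM (from-scratch implementations), SVM
# and Naive Bayes baselines, evaluation, and the high-confidence filter.

CLASSES <- c("false_info", "true_info")

canonical_label <- function(x) {
  out <- dplyr::case_match(as.character(x),
                           "false" ~ "false_info", "true" ~ "true_info",
                           "false_info" ~ "false_info",
                           "true_info" ~ "true_info",
                           .default = NA_character_)
  if (anyNA(out)) data_error("labels must be 'true'/'false' (or *_info forms)")
  out
}

#' Split a labeled corpus and deduplicate within each split
#'
#' Messages are randomly assigned to train/validation/test at the given
#' ratios first; exact-text duplicates are then removed within each split
#' (so a text occurring in two splits survives in both, and split sizes are
#' no longer exactly proportional after deduplication).
#'
#' @param messages Labeled message tibble (needs `id`, `label` and
#'   `text_norm` or `text`).
#' @param ratios Length-3 numeric vector (train, validation, test) summing
#'   to 1.
#' @param seed Integer seed for the random assignment.
#' @return An object of class `data_split`: list with tibbles `train`,
#'   `validation`, `test` and a `dedup_report` tibble (per-split counts
#'   before/removed/after).
#' @export
split_and_dedupe <- function(messages, ratios = c(0.6, 0.2, 0.2), seed = 1L) {
  messages <- as_tibble(messages)
  if (nrow(messages) < 3) data_error("need at least 3 messages to split")
  if (length(ratios) != 3 || any(ratios < 0) || abs(sum(ratios) - 1) > 1e-8) {
    config_error("`ratios` must be three nonnegative numbers summing to 1")
  }
  text_col <- if ("text_norm" %in% names(messages)) "text_norm" else "text"
  n <- nrow(messages)
  withr::with_seed(seed, {
    ord <- sample.int(n)
    n_train <- floor(ratios[1] * n)
    n_val <- floor(ratios[2] * n)
    assign <- rep("test", n)
    assign[ord[seq_len(n_train)]] <- "train"
    if (n_val > 0) assign[ord[n_train + seq_len(n_val)]] <- "validation"
  })
  dedupe <- function(df) distinct(df, .data[[text_col]], .keep_all = TRUE)
  splits <- lapply(c(train = "train", validation = "validation",
                     test = "test"),
                   function(s) messages[assign == s, , drop = FALSE])
  deduped <- lapply(splits, dedupe)
  report <- tibble(
    split = names(splits),
    before = vapply(splits, nrow, integer(1)),
    after = vapply(deduped, nrow, integer(1))
  ) %>% mutate(removed = .data$before - .data$after)
  structure(list(train = deduped$train, validation = deduped$validation,
                 test = deduped$test, ratios = ratios, seed = seed,
                 dedup_report = report),
            class = "data_split")
}

#' @export
print.data_split <- function(x, ...) {
  cat("<data_split> train/validation/test =",
      nrow(x$train), "/", nrow(x$validation), "/", nrow(x$test),
      "(after exact-text deduplication)\n")
  invisible(x)
}

#' Classifier architecture specification
#'
#' Defaults follow the best-performing configuration for this task family:
#' 256 convolutional filters at kernel widths 3/4/5 with ReLU, max-over-time
#' pooling, a 128-unit dense layer with 0.1 dropout, softmax output,
#' trained with cross-entropy and Adam at learning rate 1e-4 with 0.01
#' decay and batch size 32. `decay` is interpreted as decoupled weight
#' decay by default (`decay_mode = "l2"` switches to a classic L2 penalty).
#' Sequences are padded/truncated to `max_length` tokens. Training stops
#' early when validation F has not improved for `patience` epochs.
#'
#' @param embedding_dim Embedding dimension.
#' @param filters Convolution filters per kernel width.
#' @param kernel_widths Integer vector of convolution widths.
#' @param dense_units Units in the fully connected layer.
#' @param dropout Dropout probability on the dense layer during training.
#' @param learning_rate Adam learning rate.
#' @param weight_decay Decay coefficient.
#' @param decay_mode `"weight_decay"` (decoupled) or `"l2"`.
#' @param batch_size Mini-batch size.
#' @param max_length Sequence length cap in tokens.
#' @param epochs Maximum training epochs.
#' @param patience Early-stopping patience in epochs.
#' @param hidden_units LSTM hidden units per direction (BiLSTM only).
#' @return An object of class `architecture_spec`.
#' @export
architecture_spec <- function(embedding_dim = 300L, filters = 256L,
                              kernel_widths = c(3L, 4L, 5L),
                              dense_units = 128L, dropout = 0.1,
                              learning_rate = 1e-4, weight_decay = 0.01,
                              decay_mode = c("weight_decay", "l2"),
                              batch_size = 32L, max_length = 64L,
                              epochs = 50L, patience = 5L,
                              hidden_units = 64L) {
  decay_mode <- match.arg(decay_mode)
  spec <- list(
    embedding_dim = assert_count(embedding_dim, "embedding_dim", 1L),
    filters = assert_count(filters, "filters", 1L),
    kernel_widths = vapply(kernel_widths, assert_count, integer(1),
                           name = "kernel_widths", min = 1L),
    dense_units = assert_count(dense_units, "dense_units", 1L),
    dropout = assert_probability(dropout, "dropout"),
    learning_rate = learning_rate,
    weight_decay = weight_decay,
    decay_mode = decay_mode,
    batch_size = assert_count(batch_size, "batch_size", 1L),
    max_length = assert_count(max_length, "max_length", 1L),
    epochs = assert_count(epochs, "epochs", 1L),
    patience = assert_count(patience, "patience", 1L),
    hidden_units = assert_count(hidden_units, "hidden_units", 1L)
  )
  if (learning_rate <= 0 || weight_decay < 0) {
    config_error("learning_rate must be positive and weight_decay nonnegative")
  }
  if (any(spec$kernel_widths > spec$max_length)) {
    config_error("kernel widths must not exceed max_length")
  }
  structure(spec, class = "architecture_spec")
}

# Binary document-term matrix for the classical baselines.
binary_dtm <- function(token_list, vocabulary) {
  terms <- vocabulary$term[!vocabulary$term %in% c("<pad>", "<oov>")]
  X <- matrix(0L, nrow = length(token_list), ncol = length(terms),
              dimnames = list(NULL, terms))
  for (i in seq_along(token_list)) {
    hit <- intersect(token_list[[i]], terms)
    if (length(hit) > 0) X[i, hit] <- 1L
  }
  X
}

#' Train a veracity classifier
#'
#' Trains the requested model on a [split_and_dedupe()] split. Neural kinds
#' (`"cnn"`, `"bilstm"`) are the package's from-scratch implementations,
#' trained with Adam on cross-entropy and selected on validation F (early
#' stopping); `"svm"` and `"naive_bayes"` are baselines over a binary
#' document-term matrix. Deterministic given `seed`.
#'
#' @param split A `data_split` whose messages carry `tokens` (run
#'   [normalize_messages()] first).
#' @param spec An [architecture_spec()].
#' @param model_kind One of `"cnn"`, `"bilstm"`, `"svm"`, `"naive_bayes"`.
#' @param seed Integer seed controlling initialisation, shuffling and
#'   dropout.
#' @param embeddings Optional pretrained embeddings for the neural kinds: a
#'   [pretrain_embeddings()] model, another embedding provider, or a matrix
#'   with terms as rownames. `NULL` trains the embedding layer from random
#'   initialisation.
#' @return An object of class `veracity_classifier`.
#' @export
train_classifier <- function(split, spec = architecture_spec(),
                             model_kind = c("cnn", "bilstm", "svm",
                                            "naive_bayes"),
                             seed = 1L, embeddings = NULL) {
  model_kind <- match.arg(model_kind)
  stopifnot(inherits(split, "data_split"), inherits(spec, "architecture_spec"))
  train <- split$train
  if (nrow(train) == 0) data_error("training set is empty")
  if (!"tokens" %in% names(train)) {
    data_error("split messages need a `tokens` column; run normalize_messages() first")
  }
  y_train <- canonical_label(train$label)
  if (length(unique(y_train)) < 2) {
    data_error("training data contains a single class; cannot fit a classifier")
  }
  vocabulary <- build_vocabulary(train)
  majority <- names(sort(table(y_train), decreasing = TRUE))[1]

  fit <- switch(model_kind,
    cnn = ,
    bilstm = train_neural(train, split$validation, vocabulary, spec,
                          model_kind, seed, embeddings),
    svm = {
      X <- binary_dtm(train$tokens, vocabulary)
      withr::with_seed(seed, {
        e1071::svm(x = X, y = factor(y_train, levels = CLASSES),
                   kernel = "linear", probability = TRUE, scale = FALSE)
      })
    },
    naive_bayes = {
      X <- as.data.frame(lapply(as.data.frame(binary_dtm(train$tokens,
                                                         vocabulary)),
                                factor, levels = c(0L, 1L)))
      e1071::naiveBayes(x = X, y = factor(y_train, levels = CLASSES),
                        laplace = 1)
    }
  )
  structure(
    list(kind = model_kind, spec = spec, vocabulary = vocabulary, fit = fit,
         majority = majority, seed = seed, classes = CLASSES),
    class = "veracity_classifier"
  )
}

# Shared training loop for the neural kinds.
train_neural <- function(train, validation, vocabulary, spec, kind, seed,
                         embeddings) {
  y <- canonical_label(train$label)
  Y <- cbind(as.numeric(y == CLASSES[1]), as.numeric(y == CLASSES[2]))
  idx <- tokens_to_indices(train$tokens, vocabulary, spec$max_length)
  mask <- matrix(as.numeric(idx > 1L), nrow = nrow(idx))  # pad rows are 1
  has_val <- !is.null(validation) && nrow(validation) > 0
  if (has_val) {
    idx_val <- tokens_to_indices(validation$tokens, vocabulary,
                                 spec$max_length)
    mask_val <- matrix(as.numeric(idx_val > 1L), nrow = nrow(idx_val))
    y_val <- canonical_label(validation$label)
  }
  forward <- function(params, E, id, msk, dm = NULL, keep = FALSE) {
    if (kind == "cnn") cnn_forward(params, E, id, spec, dm, keep)
    else bilstm_forward(params, E, id, msk, spec, dm, keep)
  }
  backward <- function(params, E, id, msk, fwd, yb, dm) {
    if (kind == "cnn") cnn_backward(params, E, id, spec, fwd, yb, dm)
    else bilstm_backward(params, E, id, msk, spec, fwd, yb, dm)
  }
  withr::with_seed(seed, {
    params <- if (kind == "cnn") cnn_init(spec, nrow(vocabulary))
              else bilstm_init(spec, nrow(vocabulary))
    params$E <- init_embedding_matrix(vocabulary, spec$embedding_dim,
                                      embeddings)
    decay_on <- if (kind == "cnn") cnn_decay_params(params)
                else bilstm_decay_params(params)
    state <- adam_init(params)
    n <- nrow(idx)
    best <- list(f = -Inf, params = params, epoch = 0L)
    wait <- 0L
    history <- list()
    for (epoch in seq_len(spec$epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1L, n, by = spec$batch_size)) {
        rows <- ord[start:min(start + spec$batch_size - 1L, n)]
        dm <- if (spec$dropout > 0) {
          matrix(stats::rbinom(length(rows) * spec$dense_units, 1,
                               1 - spec$dropout) / (1 - spec$dropout),
                 nrow = length(rows))
        }
        E <- params$E
        p_core <- params[setdiff(names(params), "E")]
        fwd <- forward(p_core, E, idx[rows, , drop = FALSE],
                       mask[rows, , drop = FALSE], dm, keep = TRUE)
        losses <- c(losses, cnn_loss(fwd$P, Y[rows, , drop = FALSE]))
        grads <- backward(p_core, E, idx[rows, , drop = FALSE],
                          mask[rows, , drop = FALSE], fwd,
                          Y[rows, , drop = FALSE], dm)
        upd <- adam_step(params, grads, state, lr = spec$learning_rate,
                         weight_decay = spec$weight_decay,
                         decay_params = decay_on,
                         decay_mode = spec$decay_mode)
        params <- upd$params
        state <- upd$state
        params$E[1, ] <- 0
      }
      val_f <- if (has_val) {
        p_core <- params[setdiff(names(params), "E")]
        P <- forward(p_core, params$E, idx_val, mask_val)$P
        macro_f(y_val, CLASSES[max.col(P, ties.method = "first")], CLASSES)
      } else {
        p_core <- params[setdiff(names(params), "E")]
        P <- forward(p_core, params$E, idx, mask)$P
        macro_f(y, CLASSES[max.col(P, ties.method = "first")], CLASSES)
      }
      history[[epoch]] <- tibble(epoch = epoch, train_loss = mean(losses),
                                 val_f = val_f)
      if (val_f > best$f + 1e-9) {
        best <- list(f = val_f, params = params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= spec$patience) break
      }
    }
    list(params = best$params, best_epoch = best$epoch, best_val_f = best$f,
         history = bind_rows(history), kind = kind)
  })
}

#' Predict veracity labels for messages
#'
#' Returns one prediction per message: the predicted class and the
#' predicted-class probability from the softmax (or the model's probability
#' estimate for the baselines), so confidence is always in `[0.5, 1]` for
#' this binary task. Predictions are per-message and therefore independent
#' of batch order. Messages with no tokens get the training-majority label
#' at confidence 0.5, with a warning.
#'
#' @param object A [train_classifier()] model.
#' @param messages Normalized message tibble with `id` and `tokens`.
#' @param ... Unused.
#' @return A tibble with columns `id`, `label`, `confidence`, `p_false`.
#' @export
predict.veracity_classifier <- function(object, messages, ...) {
  messages <- as_tibble(messages)
  if (!all(c("id", "tokens") %in% names(messages))) {
    data_error("`messages` must have `id` and `tokens` columns")
  }
  n <- nrow(messages)
  empty <- lengths(messages$tokens) == 0
  if (any(empty)) {
    warn(sprintf("%d message(s) normalized to an empty token sequence; %s",
                 sum(empty),
                 "assigning the training-majority label at confidence 0.5"))
  }
  p_false <- rep(NA_real_, n)
  live <- which(!empty)
  if (length(live) > 0) {
    toks <- messages$tokens[live]
    spec <- object$spec
    p_false[live] <- switch(object$kind,
      cnn = ,
      bilstm = {
        idx <- tokens_to_indices(toks, object$vocabulary, spec$max_length)
        mask <- matrix(as.numeric(idx > 1L), nrow = nrow(idx))
        p_core <- object$fit$params[setdiff(names(object$fit$params), "E")]
        P <- if (object$kind == "cnn") {
          cnn_forward(p_core, object$fit$params$E, idx, spec)$P
        } else {
          bilstm_forward(p_core, object$fit$params$E, idx, mask, spec)$P
        }
        P[, 1]
      },
      svm = {
        X <- binary_dtm(toks, object$vocabulary)
        pr <- attr(predict(object$fit, X, probability = TRUE), "probabilities")
        pr[, "false_info"]
      },
      naive_bayes = {
        X <- as.data.frame(lapply(as.data.frame(binary_dtm(toks,
                                                           object$vocabulary)),
                                  factor, levels = c(0L, 1L)))
        predict(object$fit, X, type = "raw")[, "false_info"]
      }
    )
  }
  label <- ifelse(empty, object$majority,
                  ifelse(p_false >= 0.5, CLASSES[1], CLASSES[2]))
  confidence <- ifelse(empty, 0.5, pmax(p_false, 1 - p_false))
  p_false[empty] <- 0.5
  tibble(id = messages$id, label = label, confidence = confidence,
         p_false = p_false)
}

#' Evaluate a classifier on a labeled test set
#'
#' Computes accuracy, macro-averaged precision, recall and F score on the
#' 0-100 scale, plus the confusion matrix.
#'
#' @param classifier A [train_classifier()] model.
#' @param messages Labeled normalized message tibble.
#' @return An object of class `classification_metrics`.
#' @export
evaluate_classifier <- function(classifier, messages) {
  if (nrow(messages) == 0) data_error("test set is empty")
  preds <- suppressWarnings(predict(classifier, messages))
  compute_metrics(canonical_label(messages$label), preds$label)
}

#' Classification metrics from labels
#'
#' @param truth,pred Character vectors of class labels.
#' @return An object of class `classification_metrics`: accuracy,
#'   macro-averaged precision/recall/F on the 0-100 scale, per-class
#'   metrics and the confusion matrix.
#' @export
compute_metrics <- function(truth, pred) {
  truth <- canonical_label(truth)
  pred <- canonical_label(pred)
  stopifnot(length(truth) == length(pred))
  conf <- table(truth = factor(truth, levels = CLASSES),
                predicted = factor(pred, levels = CLASSES))
  per_class <- purrr::map(CLASSES, function(cl) {
    tp <- conf[cl, cl]
    fp <- sum(conf[, cl]) - tp
    fn <- sum(conf[cl, ]) - tp
    precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
    recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f <- if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
    tibble(class = cl, precision = 100 * precision, recall = 100 * recall,
           f = 100 * f, support = sum(conf[cl, ]))
  }) %>% bind_rows()
  structure(
    list(
      accuracy = 100 * sum(diag(conf)) / length(truth),
      precision = mean(per_class$precision),
      recall = mean(per_class$recall),
      f = mean(per_class$f),
      per_class = per_class,
      confusion = conf,
      n = length(truth)
    ),
    class = "classification_metrics"
  )
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf(paste0("<classification_metrics> n = %d\n  accuracy %.3f  ",
                     "precision %.3f  recall %.3f  F %.3f (0-100, macro)\n"),
              x$n, x$accuracy, x$precision, x$recall, x$f))
  print(x$confusion)
  invisible(x)
}

#' High-confidence prediction filter with accounting
#'
#' Keeps predictions whose confidence reaches the threshold (both classes
#' by default) and reports a per-class accounting table: counts before the
#' filter and counts/percentages after, percentages taken over the
#' unfiltered class totals.
#'
#' @param predictions Prediction tibble from [predict.veracity_classifier()].
#' @param threshold Minimum confidence in `[0.5, 1]`.
#' @param classes Classes the filter applies to; predictions of other
#'   classes are dropped from the output (the narrative use case keeps only
#'   high-confidence false-information messages).
#' @return An object of class `filtered_predictions`: list with `kept` (the
#'   surviving predictions) and `accounting` (tibble: `stage`, `class`,
#'   `n`, `percent`).
#' @export
filter_by_confidence <- function(predictions, threshold = 0.998,
                                 classes = CLASSES) {
  if (!is.numeric(threshold) || threshold < 0.5 || threshold > 1) {
    config_error("`threshold` must be in [0.5, 1]")
  }
  predictions <- as_tibble(predictions)
  base_counts <- vapply(CLASSES, function(cl) sum(predictions$label == cl),
                        integer(1))
  kept <- predictions %>%
    filter(.data$label %in% classes, .data$confidence >= threshold)
  kept_counts <- vapply(CLASSES, function(cl) sum(kept$label == cl),
                        integer(1))
  accounting <- bind_rows(
    tibble(stage = "no_filter", class = CLASSES, n = unname(base_counts),
           percent = 100),
    tibble(stage = "confidence_threshold", class = CLASSES,
           n = unname(kept_counts),
           percent = unname(ifelse(base_counts == 0, 0,
                                   round(100 * kept_counts / base_counts,
                                         2))))
  )
  structure(list(kept = kept, accounting = accounting,
                 threshold = threshold),
            class = "filtered_predictions")
}

#' ROC curve for the false-information score
#'
#' Receiver operating characteristic of `p_false` against the true labels,
#' computed with pROC.
#'
#' @param predictions Prediction tibble including `p_false`.
#' @param truth Character vector of true labels aligned with `predictions`.
#' @return A tibble with columns `threshold`, `fpr`, `tpr`; the area under
#'   the curve is in the `auc` attribute.
#' @export
roc_curve <- function(predictions, truth) {
  truth <- canonical_label(truth)
  r <- pROC::roc(response = factor(truth, levels = CLASSES),
                 predictor = predictions$p_false, levels = rev(CLASSES),
                 direction = "<", quiet = TRUE)
  out <- tibble(threshold = r$thresholds, fpr = 1 - r$specificities,
                tpr = r$sensitivities)
  attr(out, "auc") <- as.numeric(r$auc)
  out
}

#' Repeat a train/evaluate run over several seeds
#'
#' Reproduces the mean (SD) reporting protocol for a model family: for each
#' seed the corpus is re-split, a model trained and evaluated on the test
#' split, and the run metrics collected.
#'
#' @param messages Labeled normalized message tibble.
#' @param spec An [architecture_spec()].
#' @param model_kind Model kind, see [train_classifier()].
#' @param seeds Integer vector of seeds.
#' @param ratios Split ratios.
#' @param embeddings Optional embeddings forwarded to [train_classifier()].
#' @return A tibble with one row per seed (accuracy/precision/recall/f);
#'   the mean/SD summary is in the `summary` attribute.
#' @export
benchmark_classifier <- function(messages, spec = architecture_spec(),
                                 model_kind = "cnn", seeds = 1:5,
                                 ratios = c(0.6, 0.2, 0.2),
                                 embeddings = NULL) {
  runs <- purrr::map(seeds, function(s) {
    split <- split_and_dedupe(messages, ratios, seed = s)
    model <- train_classifier(split, spec, model_kind, seed = s,
                              embeddings = embeddings)
    m <- evaluate_classifier(model, split$test)
    tibble(seed = s, accuracy = m$accuracy, precision = m$precision,
           recall = m$recall, f = m$f)
  }) %>% bind_rows()
  summary <- runs %>%
    tidyr::pivot_longer(-"seed", names_to = "metric") %>%
    group_by(.data$metric) %>%
    summarise(mean = mean(.data$value), sd = sd(.data$value),
              .groups = "drop")
  attr(runs, "summary") <- summary
  runs
}
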