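small_spec <- function(epochs = 10L, ...) {
  architecture_spec(embedding_dim = 16L, filters = 16L, dense_units = 16L,
                    hidden_units = 6L, epochs = epochs, learning_rate = 1e-3,
                    max_length = 32L, ...)
}

test_that("splitting uses the stated ratios then dedupes within splits", {
  msgs <- tibble::tibble(id = sprintf("m%02d", 1:10),
                         text = sprintf("unique message %02d", 1:10),
                         label = rep(c("true", "false"), 5))
  sp <- split_and_dedupe(msgs, c(0.6, 0.2, 0.2), seed = 1)
  expect_identical(vapply(list(sp$train, sp$validation, sp$test), nrow,
                          integer(1)), c(6L, 2L, 2L))
  expect_length(intersect(sp$train$id, sp$test$id), 0)

  # duplicates are removed within (not across) splits; recount independently
  dup <- msgs
  dup$text <- rep(sprintf("dup %d", 1:5), each = 2)
  sp <- split_and_dedupe(dup, c(0.6, 0.2, 0.2), seed = 4)
  for (s in list(sp$train, sp$validation, sp$test)) {
    expect_false(any(duplicated(s$text)))
  }
  rep_tab <- sp$dedup_report
  expect_identical(sum(rep_tab$before), 10L)
  expect_identical(rep_tab$after, rep_tab$before - rep_tab$removed)

  sp2 <- split_and_dedupe(dup, c(0.6, 0.2, 0.2), seed = 4)
  expect_identical(sp, sp2)
  expect_error(split_and_dedupe(msgs[1:2, ]), class = "riskmine_data_error")
  expect_error(split_and_dedupe(msgs, c(0.5, 0.2, 0.2)),
               class = "riskmine_config_error")
})

test_that("hand-derived network gradients match finite differences", {
  spec <- architecture_spec(embedding_dim = 5L, filters = 4L,
                            kernel_widths = c(2L, 3L), dense_units = 6L,
                            dropout = 0, max_length = 7L, hidden_units = 4L)
  withr::with_seed(7, {
    n_vocab <- 9L
    idx <- matrix(sample(1:n_vocab, 3 * 7, replace = TRUE), nrow = 3)
    idx[1, 6:7] <- 1L
    idx[2, 4:7] <- 1L
    mask <- matrix(as.numeric(idx > 1L), nrow = 3)
    y <- cbind(c(1, 0, 1), c(0, 1, 0))
    E <- matrix(rnorm(n_vocab * 5, sd = 0.5), n_vocab)
    E[1, ] <- 0
    for (kind in c("cnn", "bilstm")) {
      params <- if (kind == "cnn") riskmine:::cnn_init(spec, n_vocab)
                else riskmine:::bilstm_init(spec, n_vocab)
      loss_of <- function(p, Emb) {
        fwd <- if (kind == "cnn") {
          riskmine:::cnn_forward(p, Emb, idx, spec)
        } else {
          riskmine:::bilstm_forward(p, Emb, idx, mask, spec)
        }
        riskmine:::cnn_loss(fwd$P, y)
      }
      fwd <- if (kind == "cnn") {
        riskmine:::cnn_forward(params, E, idx, spec, keep = TRUE)
      } else {
        riskmine:::bilstm_forward(params, E, idx, mask, spec, keep = TRUE)
      }
      grads <- if (kind == "cnn") {
        riskmine:::cnn_backward(params, E, idx, spec, fwd, y)
      } else {
        riskmine:::bilstm_backward(params, E, idx, mask, spec, fwd, y)
      }
      eps <- 1e-6
      errs <- numeric(0)
      for (nm in c(names(params), "E")) {
        P <- if (nm == "E") E else params[[nm]]
        G <- grads[[nm]]
        picks <- sample(length(P), min(5, length(P)))
        for (i in picks) {
          if (nm == "E" && (i - 1) %% n_vocab + 1 == 1) next  # frozen pad
          Pp <- P; Pp[i] <- Pp[i] + eps
          Pm <- P; Pm[i] <- Pm[i] - eps
          num <- if (nm == "E") {
            (loss_of(params, Pp) - loss_of(params, Pm)) / (2 * eps)
          } else {
            pp <- params; pp[[nm]] <- Pp
            pm <- params; pm[[nm]] <- Pm
            (loss_of(pp, E) - loss_of(pm, E)) / (2 * eps)
          }
          errs <- c(errs, abs(num - G[i]) / max(1e-6, abs(num) + abs(G[i])))
        }
      }
      # a systematically wrong gradient fails everywhere; isolated ReLU /
      # max-pool kink crossings under the finite difference are tolerated
      expect_lt(stats::median(errs), 1e-6)
      expect_gte(mean(errs < 1e-4), 0.9)
    }
  })
})

test_that("the convolutional model separates disjoint class vocabularies", {
  corp <- separable_corpus(400, seed = 21)
  split <- split_and_dedupe(corp, seed = 21)
  model <- train_classifier(split, small_spec(), "cnn", seed = 21)
  metrics <- evaluate_classifier(model, split$test)
  expect_gte(metrics$f, 95)

  model2 <- train_classifier(split, small_spec(), "cnn", seed = 21)
  expect_identical(model$fit$params, model2$fit$params)
  expect_identical(tidy(model), tidy(model2))

  # the Naive Bayes baseline also yields a valid metrics object; on a
  # bag-of-words-separable corpus it is near Bayes-optimal, so no ordering
  # against the CNN is asserted
  nb <- train_classifier(split, small_spec(), "naive_bayes", seed = 21)
  nb_metrics <- evaluate_classifier(nb, split$test)
  expect_s3_class(nb_metrics, "classification_metrics")
  expect_gte(nb_metrics$f, 95)

  expect_error(train_classifier(split, small_spec(), "nonsense"),
               regexp = "arg")
  one_class <- split
  one_class$train$label <- "false"
  expect_error(train_classifier(one_class, small_spec(), "cnn"),
               class = "riskmine_data_error")
})

test_that("the bilstm baseline trains and predicts sane probabilities", {
  corp <- separable_corpus(200, seed = 33)
  split <- split_and_dedupe(corp, seed = 33)
  spec <- architecture_spec(embedding_dim = 16L, filters = 16L,
                            dense_units = 16L, hidden_units = 6L,
                            epochs = 6L, learning_rate = 3e-3,
                            max_length = 32L)
  model <- train_classifier(split, spec, "bilstm", seed = 33)
  preds <- suppressWarnings(predict(model, split$test))
  expect_true(all(preds$confidence >= 0.5 & preds$confidence <= 1))
  expect_true(all(preds$label %in% c("false_info", "true_info")))
  m <- evaluate_classifier(model, split$test)
  expect_gte(m$accuracy, 80)
})

test_that("predictions are batch-order independent with an empty-token fallback", {
  corp <- separable_corpus(200, seed = 9)
  split <- split_and_dedupe(corp, seed = 9)
  model <- train_classifier(split, small_spec(epochs = 3L), "cnn", seed = 9)
  test <- split$test
  preds <- suppressWarnings(predict(model, test))
  perm <- withr::with_seed(1, sample(nrow(test)))
  preds_perm <- suppressWarnings(predict(model, test[perm, ]))
  joined <- dplyr::left_join(preds, preds_perm, by = "id")
  expect_equal(joined$confidence.x, joined$confidence.y)
  expect_identical(joined$label.x, joined$label.y)
  expect_true(all(preds$confidence >= 0.5 & preds$confidence <= 1))

  empty <- tibble::tibble(id = "e1", tokens = list(character(0)))
  expect_warning(p <- predict(model, empty), regexp = "empty token")
  expect_equal(p$confidence, 0.5)
  expect_identical(p$label, model$majority)
})

test_that("metrics match their definitions and printed examples", {
  perfect <- compute_metrics(rep(c("true", "false"), 5),
                             rep(c("true", "false"), 5))
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$f, 100)
  expect_equal(sum(perfect$confusion), 10)

  # F is the harmonic mean of precision and recall per class before averaging
  truth <- c(rep("false", 6), rep("true", 4))
  pred <- c(rep("false", 4), "true", "true", rep("true", 3), "false")
  m <- compute_metrics(truth, pred)
  pc <- m$per_class
  for (i in 1:2) {
    expect_equal(pc$f[i], 2 * pc$precision[i] * pc$recall[i] /
                   (pc$precision[i] + pc$recall[i]))
  }
  expect_equal(m$f, mean(pc$f))
  expect_equal(sum(m$confusion), length(truth))

  # label-permutation invariance: permuting cases leaves metrics unchanged
  perm <- withr::with_seed(2, sample(length(truth)))
  m2 <- compute_metrics(truth[perm], pred[perm])
  expect_equal(glance(m), glance(m2))

  # random guessing on a balanced test set sits near 50
  withr::with_seed(11, {
    truth <- rep(c("true", "false"), 500)
    pred <- sample(c("true", "false"), 1000, replace = TRUE)
  })
  expect_lt(abs(compute_metrics(truth, pred)$accuracy - 50), 5)
  expect_error(evaluate_classifier(structure(list(), class = "x"),
                                   tibble::tibble()),
               class = "riskmine_data_error")
})

test_that("confidence filtering keeps thresholds honest and monotone", {
  preds <- tibble::tibble(
    id = c("a", "b"), label = c("false_info", "false_info"),
    confidence = c(0.999, 0.99), p_false = c(0.999, 0.99))
  expect_identical(nrow(filter_by_confidence(preds, 0.998)$kept), 1L)
  expect_identical(nrow(filter_by_confidence(preds, 0.5)$kept), 2L)
  expect_error(filter_by_confidence(preds, 0.3),
               class = "riskmine_config_error")

  withr::with_seed(19, {
    preds <- tibble::tibble(
      id = sprintf("p%03d", 1:300),
      label = sample(c("false_info", "true_info"), 300, replace = TRUE),
      confidence = runif(300, 0.5, 1))
  })
  preds$p_false <- ifelse(preds$label == "false_info", preds$confidence,
                          1 - preds$confidence)
  kept_ids <- lapply(c(0.5, 0.9, 0.998), function(th) {
    filter_by_confidence(preds, th)$kept$id
  })
  expect_true(all(kept_ids[[2]] %in% kept_ids[[1]]))
  expect_true(all(kept_ids[[3]] %in% kept_ids[[2]]))

  # accounting equals a brute-force recount
  fl <- filter_by_confidence(preds, 0.9)
  for (cl in c("false_info", "true_info")) {
    base <- sum(preds$label == cl)
    kept <- sum(preds$label == cl & preds$confidence >= 0.9)
    acc <- fl$accounting
    expect_identical(acc$n[acc$stage == "no_filter" & acc$class == cl], base)
    expect_identical(acc$n[acc$stage == "confidence_threshold" &
                             acc$class == cl], kept)
    expect_equal(acc$percent[acc$stage == "confidence_threshold" &
                               acc$class == cl],
                 round(100 * kept / base, 2))
  }
})

test_that("roc utility recovers perfect and chance separability", {
  preds <- tibble::tibble(p_false = c(0.9, 0.8, 0.2, 0.1))
  truth <- c("false", "false", "true", "true")
  roc <- roc_curve(preds, truth)
  expect_equal(attr(roc, "auc"), 1)
  expect_true(all(roc$tpr >= 0 & roc$tpr <= 1))

  withr::with_seed(3, {
    preds <- tibble::tibble(p_false = runif(400))
    truth <- sample(c("false", "true"), 400, replace = TRUE)
  })
  expect_lt(abs(attr(roc_curve(preds, truth), "auc") - 0.5), 0.1)
})

test_that("the seed-repetition protocol reports mean and spread", {
  corp <- separable_corpus(200, seed = 44)
  runs <- benchmark_classifier(corp, small_spec(epochs = 3L),
                               "naive_bayes", seeds = 1:3)
  expect_identical(nrow(runs), 3L)
  s <- attr(runs, "summary")
  expect_setequal(s$metric, c("accuracy", "precision", "recall", "f"))
  expect_equal(s$mean[s$metric == "f"], mean(runs$f))
  expect_equal(s$sd[s$metric == "f"], sd(runs$f))
})
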