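# End-to-end orchestration: simulate/load -> normalize -> classify ->
# confidence filter -> cue screen -> extract -> co-occurrence model ->
# collapse -> rank -> match. Stages communicate through files in `out_dir`
# so any stage can be inspected or re-run; the report carries the filter
# accounting (per predicted class) and the per-query rankings.

#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. The
#' classifier defaults to a compact convolutional architecture suited to
#' desk-scale corpora; pass `spec = architecture_spec()` for the full-size
#' configuration.
#'
#' @param corpus A labeled message tibble, a path to a JSON Lines corpus, or
#'   `NULL` to simulate one from `generator`.
#' @param generator A [generator_config()] used when `corpus` is `NULL`.
#' @param classify Run the classifier + confidence-filter stages; when
#'   `FALSE`, mining runs on all messages.
#' @param model_kind Classifier kind, see [train_classifier()].
#' @param spec An [architecture_spec()] for the classifier.
#' @param ratios Train/validation/test split ratios.
#' @param threshold Confidence-filter threshold.
#' @param mining_classes Predicted classes whose messages feed the mining
#'   stages (default both).
#' @param cues Causal-cue lexicon.
#' @param alpha,log_base Co-occurrence smoothing constant and PMI log base.
#' @param eps,min_points Collapsing (DBSCAN) parameters.
#' @param embedding_provider Provider for effect-phrase embeddings:
#'   `"hash"` (default) or any [token_vectors()] provider.
#' @param embedding_dim Dimension for the hashing provider.
#' @param queries Character vector of ranking queries.
#' @param top_k Effects returned per query.
#' @param gold Gold lexicon tibble, CSV path, or `NULL` to skip matching.
#' @param stopwords Stopword list.
#' @param seed Integer seed for every stochastic stage.
#' @param out_dir Directory for intermediate artifacts (created if needed);
#'   `NULL` uses a session temporary directory.
#' @return An object of class `pipeline_config`.
#' @export
riskmine_config <- function(corpus = NULL,
                            generator = generator_config(),
                            classify = TRUE,
                            model_kind = "cnn",
                            spec = architecture_spec(embedding_dim = 32L,
                                                     filters = 32L,
                                                     dense_units = 32L,
                                                     epochs = 30L,
                                                     learning_rate = 1e-3),
                            ratios = c(0.6, 0.2, 0.2),
                            threshold = 0.998,
                            mining_classes = c("false_info", "true_info"),
                            cues = NULL,
                            alpha = 1,
                            log_base = exp(1),
                            eps = 0.1,
                            min_points = 1L,
                            embedding_provider = "hash",
                            embedding_dim = 64L,
                            queries = character(0),
                            top_k = 10L,
                            gold = NULL,
                            stopwords = riskmine_stopwords(),
                            seed = 1L,
                            out_dir = NULL) {
  if (!is.numeric(threshold) || threshold < 0.5 || threshold > 1) {
    config_error("`threshold` must be in [0.5, 1]")
  }
  if (is.character(corpus) && !file.exists(corpus)) {
    config_error(paste0("corpus file not found: ", corpus))
  }
  if (is.character(gold) && !file.exists(gold)) {
    config_error(paste0("gold lexicon file not found: ", gold))
  }
  structure(
    list(corpus = corpus, generator = generator, classify = classify,
         model_kind = model_kind, spec = spec, ratios = ratios,
         threshold = threshold, mining_classes = mining_classes,
         cues = cues, alpha = alpha, log_base = log_base, eps = eps,
         min_points = min_points, embedding_provider = embedding_provider,
         embedding_dim = embedding_dim, queries = queries,
         top_k = top_k, gold = gold, stopwords = stopwords,
         seed = assert_count(seed, "seed", 0L), out_dir = out_dir),
    class = "pipeline_config"
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
          class = "riskmine_stage_error", parent = e)
  })
}

#' Run the full mining pipeline
#'
#' Executes normalize, classifier training and prediction, the
#' high-confidence filter, causal-cue screening, candidate-pair extraction,
#' co-occurrence modelling, effect collapsing, per-query ranking and gold
#' lexicon matching, per the configuration. All intermediate artifacts are
#' written under `out_dir`; the run is deterministic given the seed.
#'
#' @param config A [riskmine_config()].
#' @return An object of class `pipeline_report`: list with `stage_counts`
#'   (per-class filter-chain accounting), `rankings` (one tibble per
#'   query), `collapsed`, `match` (a `match_report` or `NULL`), `paths` of
#'   persisted artifacts and `meta`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir %||% file.path(tempdir(), "riskmine-run")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  t0 <- Sys.time()
  cues <- config$cues %||%
    (if (is.null(config$corpus)) config$generator$cue_list
     else default_cue_lexicon())

  corpus <- stage("simulate", {
    x <- config$corpus
    if (is.null(x)) x <- generate_corpus(config$generator)
    if (is.character(x)) x <- read_messages_jsonl(x)
    paths$corpus <- file.path(out_dir, "corpus.jsonl")
    write_messages_jsonl(x, paths$corpus)
    x
  })
  if (nrow(corpus) == 0) data_error("pipeline received an empty corpus")

  normalized <- stage("normalize", {
    out <- normalize_messages(corpus)
    paths$normalized <- file.path(out_dir, "normalized.jsonl")
    write_messages_jsonl(out, paths$normalized)
    out
  })

  if (config$classify) {
    model <- stage("train", {
      split <- split_and_dedupe(normalized, config$ratios, seed = config$seed)
      train_classifier(split, config$spec, config$model_kind,
                       seed = config$seed)
    })
    predictions <- stage("predict", {
      out <- suppressWarnings(predict(model, normalized))
      paths$predictions <- file.path(out_dir, "predictions.tsv")
      readr::write_tsv(out, paths$predictions, progress = FALSE)
      out
    })
    filtered <- stage("confidence_filter", {
      out <- filter_by_confidence(predictions, config$threshold,
                                  classes = config$mining_classes)
      paths$kept <- file.path(out_dir, "kept.tsv")
      readr::write_tsv(out$kept, paths$kept, progress = FALSE)
      out
    })
    mining_input <- normalized %>%
      filter(.data$id %in% filtered$kept$id)
    pred_class <- setNames(predictions$label, predictions$id)
    accounting <- filtered$accounting
  } else {
    model <- NULL
    predictions <- NULL
    mining_input <- normalized
    pred_class <- setNames(rep(NA_character_, nrow(normalized)),
                           normalized$id)
    accounting <- tibble(stage = "no_filter", class = "all",
                         n = nrow(normalized), percent = 100)
  }

  screened <- stage("cue_screen", {
    mining_input[has_causal_cue(mining_input$text_norm, cues), ,
                 drop = FALSE]
  })
  if (config$classify) {
    base_counts <- accounting %>% filter(.data$stage == "no_filter")
    cue_counts <- vapply(base_counts$class, function(cl) {
      sum(pred_class[screened$id] == cl, na.rm = TRUE)
    }, integer(1))
    accounting <- bind_rows(
      accounting,
      tibble(stage = "contains_causal_cue", class = base_counts$class,
             n = unname(cue_counts),
             percent = unname(ifelse(base_counts$n == 0, 0,
                                     round(100 * cue_counts / base_counts$n,
                                           2))))
    )
  } else {
    accounting <- bind_rows(
      accounting,
      tibble(stage = "contains_causal_cue", class = "all",
             n = nrow(screened),
             percent = round(100 * nrow(screened) /
                               max(1, nrow(mining_input)), 2))
    )
  }

  pairs <- stage("extract", {
    out <- extract_candidate_pairs(screened, cues)
    paths$pairs <- file.path(out_dir, "pairs.jsonl")
    write_candidate_pairs(out, paths$pairs)
    out
  })
  if (nrow(pairs) == 0) {
    data_error("no candidate pairs extracted; nothing to mine")
  }

  model_cooc <- stage("cooccurrence", {
    vocabs <- build_phrase_vocabularies(pairs, config$stopwords)
    out <- build_cooccurrence_model(pairs, vocabs, alpha = config$alpha,
                                    log_base = config$log_base)
    paths$model <- file.path(out_dir, "cooccurrence")
    write_cooccurrence_model(out, paths$model)
    out
  })

  collapsed <- stage("collapse", {
    provider <- config$embedding_provider
    if (identical(provider, "hash")) {
      provider <- hash_embedding_provider(config$embedding_dim,
                                          seed = config$seed)
    }
    effects <- model_cooc$v_e
    emb <- embed_effect_phrases(effects, provider)
    clustering <- cluster_effect_phrases(emb, eps = config$eps,
                                         min_points = config$min_points)
    freqs <- setNames(colSums(model_cooc$counts), colnames(model_cooc$counts))
    out <- collapse_to_representatives(clustering, frequencies = freqs)
    paths$clusters <- file.path(out_dir, "clusters.tsv")
    readr::write_tsv(out %>% select(-"members"), paths$clusters,
                     progress = FALSE)
    out
  })

  rankings <- stage("rank", {
    out <- lapply(config$queries, function(q) {
      rank_effects(q, collapsed, model_cooc, k = config$top_k)
    })
    names(out) <- config$queries
    for (q in names(out)) {
      p <- file.path(out_dir, paste0("ranked_", gsub("[^a-z0-9]+", "_",
                                                     tolower(q)), ".tsv"))
      readr::write_tsv(out[[q]], p, progress = FALSE)
      paths$rankings <- c(paths$rankings, p)
    }
    out
  })

  match <- if (!is.null(config$gold)) {
    stage("match", {
      gold <- config$gold
      if (is.character(gold)) gold <- read_gold_lexicon(gold)
      out <- match_statistics(gold, collapsed$representative,
                              stopwords = config$stopwords)
      paths$match <- file.path(out_dir, "match")
      write_match_report(out, paths$match)
      out
    })
  }

  report <- structure(
    list(stage_counts = accounting, rankings = rankings,
         collapsed = collapsed, match = match,
         n_messages = nrow(corpus), n_pairs = nrow(pairs),
         paths = paths,
         meta = list(seed = config$seed,
                     classifier = if (config$classify) config$model_kind else NA,
                     threshold = config$threshold, alpha = config$alpha,
                     eps = config$eps, min_points = config$min_points,
                     elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                     units = "secs")))),
    class = "pipeline_report"
  )
  jsonlite::write_json(
    list(stage_counts = report$stage_counts, n_messages = report$n_messages,
         n_pairs = report$n_pairs,
         rankings = lapply(rankings, function(r) as.data.frame(r)),
         seed = config$seed),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> ", x$n_messages, " messages, ", x$n_pairs,
      " candidate pairs\n", sep = "")
  print(x$stage_counts)
  if (length(x$rankings) > 0) {
    for (q in names(x$rankings)) {
      cat("\nTop effects for query '", q, "':\n", sep = "")
      print(head(x$rankings[[q]], 5))
    }
  }
  if (!is.null(x$match)) print(x$match)
  invisible(x)
}
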