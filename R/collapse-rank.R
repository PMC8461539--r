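# Collapsing near-duplicate effect phrases and ranking effects for a query.
#
# Effect phrases are embedded as the mean of their per-token vectors,
# clustered with DBSCAN under cosine distance (reachability 0.1, minimum
# points 1, so no phrase is noise), and each cluster is collapsed to its
# medoid. Ranking scores an effect against a query as the average NPMI over
# all (query term, effect term) pairs.

#' Deterministic hashing embedding provider
#'
#' Maps every token to a fixed pseudo-random unit-length vector derived only
#' from the token's bytes and the provider seed, so identical tokens always
#' share a vector and distinct tokens are nearly orthogonal in moderate
#' dimension. Useful wherever phrase identity (not meaning) drives the
#' analysis, and in tests, since it needs no model fitting.
#'
#' @param dim Embedding dimension.
#' @param seed Integer seed folded into every token hash.
#' @return A provider object for [token_vectors()].
#' @export
hash_embedding_provider <- function(dim = 64L, seed = 0L) {
  dim <- assert_count(dim, "dim", min = 1L)
  structure(list(dim = dim, seed = as.integer(seed)),
            class = c("hash_embedding_provider", "embedding_provider"))
}

#' Token vectors from an embedding provider
#'
#' Provider contract: given a character vector of tokens, return a numeric
#' matrix with one row per token. Implementations ship for
#' [hash_embedding_provider()], trained [word_embeddings()] models, plain
#' functions and named matrices.
#'
#' @param provider An embedding provider.
#' @param tokens Character vector of tokens.
#' @return Numeric matrix, `length(tokens)` rows.
#' @export
token_vectors <- function(provider, tokens) {
  UseMethod("token_vectors")
}

#' @export
token_vectors.hash_embedding_provider <- function(provider, tokens) {
  out <- matrix(0, nrow = length(tokens), ncol = provider$dim,
                dimnames = list(tokens, NULL))
  for (i in seq_along(tokens)) {
    h <- hash_string(tokens[i], provider$seed)
    v <- withr::with_seed(h %% 2147483647, rnorm(provider$dim))
    out[i, ] <- v / sqrt(sum(v^2))
  }
  out
}

#' @export
token_vectors.function <- function(provider, tokens) {
  out <- provider(tokens)
  if (!is.matrix(out) || nrow(out) != length(tokens)) {
    data_error("embedding provider function must return one row per token")
  }
  out
}

#' @export
token_vectors.matrix <- function(provider, tokens) {
  missing <- setdiff(tokens, rownames(provider))
  if (length(missing) > 0) {
    data_error(paste0("no vector for token(s): ", paste(missing, collapse = ", ")))
  }
  provider[tokens, , drop = FALSE]
}

phrase_tokens <- function(phrase) {
  unlist(strsplit(phrase, "[_ ]+"), use.names = FALSE)
}

#' Embed an effect phrase
#'
#' The phrase vector is the arithmetic mean of its per-token vectors from
#' the provider. Underscore-joined multi-word terms are split back into
#' their component tokens first.
#'
#' @param phrase A single effect phrase (underscore- or space-separated) or
#'   a character vector of tokens.
#' @param provider An embedding provider (see [token_vectors()]).
#' @return A numeric vector.
#' @export
embed_effect_phrase <- function(phrase, provider) {
  tokens <- if (length(phrase) > 1) phrase else phrase_tokens(phrase)
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0) data_error("cannot embed an empty phrase")
  vecs <- tryCatch(token_vectors(provider, tokens), error = function(e) {
    data_error(paste0("embedding provider failed on phrase '",
                      paste(tokens, collapse = " "), "': ",
                      conditionMessage(e)))
  })
  if (any(!is.finite(vecs))) {
    bad <- tokens[which(rowSums(!is.finite(vecs)) > 0)[1]]
    data_error(paste0("embedding provider returned non-finite values for token '",
                      bad, "'"))
  }
  colMeans(vecs)
}

#' Embed a collection of effect phrases
#'
#' @param phrases Character vector of effect phrases.
#' @param provider An embedding provider.
#' @return A numeric matrix with one row per phrase, rownames = phrases.
#' @export
embed_effect_phrases <- function(phrases, provider) {
  if (length(phrases) == 0) data_error("no phrases to embed")
  out <- t(vapply(phrases, embed_effect_phrase,
                  numeric(length(embed_effect_phrase(phrases[1], provider))),
                  provider = provider))
  rownames(out) <- phrases
  out
}

# Plain DBSCAN. `dist` is a full symmetric distance matrix. Points with at
# least `min_points` neighbours within `eps` (self included) are core;
# clusters grow from core points; non-core points within reach of a cluster
# join it as border points; the rest are noise (cluster NA).
dbscan_labels <- function(dist, eps, min_points) {
  n <- nrow(dist)
  neighbours <- lapply(seq_len(n), function(i) which(dist[i, ] <= eps))
  core <- vapply(neighbours, length, integer(1)) >= min_points
  cluster <- rep(NA_integer_, n)
  next_id <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || !is.na(cluster[i])) next
    next_id <- next_id + 1L
    cluster[i] <- next_id
    frontier <- setdiff(neighbours[[i]], i)
    while (length(frontier) > 0) {
      j <- frontier[1]
      frontier <- frontier[-1]
      if (is.na(cluster[j])) {
        cluster[j] <- next_id
        if (core[j]) {
          nb <- neighbours[[j]]
          frontier <- union(frontier, nb[is.na(cluster[nb])])
        }
      }
    }
  }
  list(cluster = cluster, core = core)
}

#' Cluster effect-phrase embeddings
#'
#' Density-based clustering (DBSCAN) of effect-phrase vectors under cosine
#' distance, with the reachability and minimum-points settings used for
#' collapsing near-duplicate phrases (`eps = 0.1`, `min_points = 1`). With
#' `min_points = 1` every phrase is a core point, so nothing is labelled
#' noise and identical vectors always share a cluster.
#'
#' @param embeddings Matrix from [embed_effect_phrases()] (rownames are the
#'   phrases).
#' @param eps Reachability: maximum distance for two points to be
#'   density-connected.
#' @param min_points Minimum neighbourhood size (self included) for a core
#'   point.
#' @param metric `"cosine"` (default) or `"euclidean"`.
#' @return An object of class `effect_clustering`: a list with `assignment`
#'   (tibble: `effect`, `cluster`, `is_core`), the distance matrix and the
#'   parameters.
#' @export
cluster_effect_phrases <- function(embeddings, eps = 0.1, min_points = 1L,
                                   metric = c("cosine", "euclidean")) {
  metric <- match.arg(metric)
  if (!is.matrix(embeddings) || nrow(embeddings) < 1) {
    data_error("`embeddings` must be a matrix with at least one row")
  }
  if (any(!is.finite(embeddings))) data_error("embeddings contain non-finite values")
  if (!is.numeric(eps) || eps <= 0) config_error("`eps` must be positive")
  min_points <- assert_count(min_points, "min_points", min = 1L)
  dist <- if (metric == "cosine") {
    cosine_distance(embeddings)
  } else {
    as.matrix(stats::dist(embeddings))
  }
  lab <- dbscan_labels(dist, eps, min_points)
  structure(
    list(
      assignment = tibble(effect = rownames(embeddings),
                          cluster = lab$cluster, is_core = lab$core),
      dist = dist, eps = eps, min_points = min_points, metric = metric
    ),
    class = "effect_clustering"
  )
}

#' @export
print.effect_clustering <- function(x, ...) {
  k <- length(unique(x$assignment$cluster[!is.na(x$assignment$cluster)]))
  cat("<effect_clustering> ", nrow(x$assignment), " phrases in ", k,
      " clusters (eps = ", x$eps, ", min_points = ", x$min_points, ", ",
      x$metric, " distance)\n", sep = "")
  invisible(x)
}

#' Collapse a clustering to one representative phrase per cluster
#'
#' The representative is the cluster medoid: the member with minimum summed
#' distance to the other members, ties broken by higher phrase frequency
#' (when supplied) and then lexicographically. Noise points (possible only
#' when `min_points > 1`) represent themselves.
#'
#' @param clustering An `effect_clustering` from [cluster_effect_phrases()].
#' @param frequencies Optional named vector of phrase frequencies for tie
#'   breaking.
#' @return A tibble with columns `cluster`, `representative`, `size`,
#'   `members` (list-column).
#' @export
collapse_to_representatives <- function(clustering, frequencies = NULL) {
  stopifnot(inherits(clustering, "effect_clustering"))
  asg <- clustering$assignment
  noise <- which(is.na(asg$cluster))
  if (length(noise) > 0) {
    max_id <- max(asg$cluster, na.rm = TRUE) %|NA|% 0L
    max_id <- if (is.finite(max_id)) max_id else 0L
    asg$cluster[noise] <- max_id + seq_along(noise)
  }
  split_idx <- split(seq_len(nrow(asg)), asg$cluster)
  rows <- purrr::imap(split_idx, function(idx, cl) {
    members <- asg$effect[idx]
    if (length(idx) == 1) {
      med <- members
    } else {
      d <- clustering$dist[idx, idx, drop = FALSE]
      tot <- rowSums(d)
      freq <- if (is.null(frequencies)) rep(0, length(members)) else
        (frequencies[members] %|NA|% 0)
      ord <- order(tot, -freq, members)
      med <- members[ord[1]]
    }
    tibble(cluster = as.integer(cl), representative = med,
           size = length(idx), members = list(members))
  })
  bind_rows(rows) %>% arrange(.data$cluster)
}

#' Score an effect phrase against a query
#'
#' The score is the mean NPMI over all (query term, effect term) pairs with
#' both members in the model vocabularies. Out-of-vocabulary pairs are
#' skipped by default; with `oov = "zero"` they contribute 0 instead. If no
#' pair remains the score is undefined (`NA`).
#'
#' @param query Character vector of query terms (looked up on the cause
#'   side), e.g. the output of [query_terms()].
#' @param effect An effect phrase (underscore-joined multi-word terms are
#'   treated as single vocabulary terms).
#' @param model A [build_cooccurrence_model()] object.
#' @param oov Out-of-vocabulary handling: `"skip"` (default) or `"zero"`.
#' @return A single number, or `NA` when undefined.
#' @export
score_effect <- function(query, effect, model, oov = c("skip", "zero")) {
  oov <- match.arg(oov)
  if (length(query) == 0 || all(!nzchar(query))) {
    data_error("query must be nonempty")
  }
  effect_terms <- unique(unlist(strsplit(effect, " ", fixed = TRUE)))
  q_in <- intersect(unique(query), model$v_c)
  e_in <- intersect(effect_terms, model$v_e)
  n_total <- length(unique(query)) * length(effect_terms)
  n_in <- length(q_in) * length(e_in)
  if (n_in == 0) return(NA_real_)
  grid <- expand.grid(q = q_in, e = e_in, stringsAsFactors = FALSE)
  vals <- npmi(model, grid$q, grid$e)
  denom <- if (oov == "zero") n_total else n_in
  sum(vals) / denom
}

#' Normalize a free-text query into query terms
#'
#' Runs the query through the same lexical normalization as messages and
#' drops stopwords, so `"HPV Vaccine"` becomes `c("hpv", "vaccine")`.
#'
#' @param query A single query string.
#' @param stopwords Stopword list.
#' @return Character vector of query terms.
#' @export
query_terms <- function(query, stopwords = riskmine_stopwords()) {
  toks <- tokenize(normalize_text(query))[[1]]
  toks <- toks[!toks %in% stopwords]
  if (length(toks) == 0) data_error("query normalized to nothing")
  toks
}

#' Rank collapsed effects for a query
#'
#' Effects with a defined score are sorted by descending score (ties broken
#' lexicographically) and the top `k` returned.
#'
#' @param query Query string or character vector of query terms.
#' @param effects Character vector of (collapsed) effect phrases, or the
#'   tibble returned by [collapse_to_representatives()].
#' @param model A [build_cooccurrence_model()] object.
#' @param k Number of effects to return; `Inf` for all.
#' @param oov Out-of-vocabulary handling, see [score_effect()].
#' @return A tibble of class `ranked_effects` with columns `rank`, `effect`,
#'   `score`; the query is stored in the `query` attribute. Effects with
#'   undefined scores are excluded.
#' @export
rank_effects <- function(query, effects, model, k = Inf,
                         oov = c("skip", "zero")) {
  oov <- match.arg(oov)
  if (is.data.frame(effects)) effects <- effects$representative
  if (length(effects) == 0) data_error("no effects to rank")
  if (length(query) == 1 && grepl("[ A-Z]", query)) query <- query_terms(query)
  scores <- unname(vapply(effects, score_effect, numeric(1),
                          query = query, model = model, oov = oov))
  defined <- !is.na(scores)
  if (!any(defined)) {
    data_error(paste0("no effect had a defined score for query '",
                      paste(query, collapse = " "),
                      "' (all query-effect term pairs out of vocabulary)"))
  }
  out <- tibble(effect = effects[defined], score = scores[defined]) %>%
    arrange(desc(.data$score), .data$effect) %>%
    mutate(rank = row_number()) %>%
    select("rank", "effect", "score")
  if (is.finite(k)) out <- slice_head(out, n = as.integer(k))
  attr(out, "query") <- paste(query, collapse = " ")
  class(out) <- c("ranked_effects", class(out))
  out
}

#' Cumulative NPMI score per effect category
#'
#' Sums the query-effect scores over the effects assigned to each category,
#' keeping the per-effect contributions so the category totals can be
#' decomposed (stacked-bar style).
#'
#' @param query Query string or character vector of query terms.
#' @param assignment Tibble with columns `effect` and `category` (each
#'   effect in at most one category).
#' @param model A [build_cooccurrence_model()] object.
#' @param oov Out-of-vocabulary handling, see [score_effect()].
#' @return A tibble of class `category_scores` with columns `category`,
#'   `effect`, `contribution`; category totals are available via
#'   [glance.category_scores()] or `attr(, "totals")`.
#' @export
cumulative_category_score <- function(query, assignment, model,
                                      oov = c("skip", "zero")) {
  oov <- match.arg(oov)
  assignment <- as_tibble(assignment)
  if (!all(c("effect", "category") %in% names(assignment))) {
    data_error("`assignment` must have columns `effect` and `category`")
  }
  if (anyDuplicated(assignment$effect)) {
    data_error("each effect may be assigned to at most one category")
  }
  if (length(query) == 1 && grepl("[ A-Z]", query)) query <- query_terms(query)
  contrib <- assignment %>%
    mutate(contribution = unname(vapply(.data$effect, score_effect,
                                        numeric(1), query = query,
                                        model = model, oov = oov))) %>%
    filter(!is.na(.data$contribution)) %>%
    select("category", "effect", "contribution") %>%
    arrange(.data$category, desc(.data$contribution))
  totals <- contrib %>%
    group_by(.data$category) %>%
    summarise(total = sum(.data$contribution), n_effects = n(), .groups = "drop") %>%
    arrange(desc(.data$total))
  attr(contrib, "totals") <- totals
  attr(contrib, "query") <- paste(query, collapse = " ")
  class(contrib) <- c("category_scores", class(contrib))
  contrib
}
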