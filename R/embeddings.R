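# Subword-augmented word embeddings: skip-gram with negative sampling where
# a term's input vector is its word vector averaged with the vectors of its
# character n-gram buckets. The subword component lets the model compose a
# vector for out-of-vocabulary terms, which matters for noisy social-media
# text. Training is plain mini-batched SGD over (center, context) pairs
# drawn with a shrinking window, negatives drawn from the unigram^0.75
# distribution.

term_ngrams <- function(term, min_n, max_n) {
  padded <- paste0("<", term, ">")
  n <- nchar(padded)
  out <- character(0)
  for (k in min_n:max_n) {
    if (k > n) break
    out <- c(out, substring(padded, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
  }
  out
}

ngram_buckets <- function(ngrams, buckets, seed = 0L) {
  if (length(ngrams) == 0) return(integer(0))
  unique(vapply(ngrams, function(g) {
    as.integer(hash_string(g, seed) %% buckets) + 1L
  }, integer(1), USE.NAMES = FALSE))
}

#' Pretrain subword-augmented word embeddings
#'
#' Unsupervised skip-gram training with negative sampling over a normalized
#' corpus. Each vocabulary term owns a word vector plus a set of hashed
#' character n-gram bucket vectors; its embedding is the average of all of
#' them, so terms sharing subwords share representation mass and unseen
#' terms can still be embedded through their n-grams.
#'
#' @param messages Normalized corpus: message tibble with a `tokens` column,
#'   a list of token vectors, or a character vector of normalized texts.
#' @param dim Embedding dimension.
#' @param window Maximum skip-gram window (actual window per center drawn
#'   uniformly from 1..window).
#' @param negative Negative samples per (center, context) pair.
#' @param epochs Training epochs.
#' @param lr Initial learning rate, linearly decayed to 10% over training.
#' @param min_count Minimum corpus frequency for a term to get a word
#'   vector.
#' @param min_n,max_n Character n-gram lengths for the subword component.
#' @param buckets Number of hash buckets for n-gram vectors.
#' @param seed Integer seed; training is deterministic given the seed.
#' @return An object of class `word_embeddings` (also an embedding provider
#'   for [token_vectors()]).
#' @export
pretrain_embeddings <- function(messages, dim = 300L, window = 5L,
                                negative = 5L, epochs = 5L, lr = 0.05,
                                min_count = 1L, min_n = 3L, max_n = 5L,
                                buckets = 4096L, seed = 1L) {
  dim <- assert_count(dim, "dim", min = 1L)
  toks <- extract_token_list(messages)
  toks <- toks[lengths(toks) > 0]
  if (length(toks) == 0) data_error("cannot train embeddings on an empty corpus")
  freq <- table(unlist(toks, use.names = FALSE))
  vocab <- names(freq[freq >= min_count])
  if (length(vocab) < 2) data_error("need at least two vocabulary terms")
  vindex <- setNames(seq_along(vocab), vocab)
  grams <- lapply(vocab, function(term) {
    ngram_buckets(term_ngrams(term, min_n, max_n), buckets, seed)
  })

  withr::with_seed(seed, {
    Win <- matrix(rnorm(length(vocab) * dim, sd = 0.5 / sqrt(dim)),
                  nrow = length(vocab))
    Bkt <- matrix(rnorm(buckets * dim, sd = 0.5 / sqrt(dim)), nrow = buckets)
    Wout <- matrix(0, nrow = length(vocab), ncol = dim)

    # negative-sampling distribution
    counts <- as.numeric(freq[vocab])
    neg_prob <- counts^0.75
    neg_prob <- neg_prob / sum(neg_prob)

    # composed input vector for a set of terms (indices into vocab)
    compose <- function(ti) {
      t(vapply(ti, function(i) {
        ids <- grams[[i]]
        if (length(ids) == 0) Win[i, ]
        else (Win[i, ] + colSums(Bkt[ids, , drop = FALSE])) / (1 + length(ids))
      }, numeric(dim)))
    }

    # skip-gram pairs with per-center window drawn uniformly
    make_pairs <- function() {
      pairs <- list()
      for (s in toks) {
        si <- unname(vindex[s])
        si <- si[!is.na(si)]
        n <- length(si)
        if (n < 2) next
        w <- sample.int(window, n, replace = TRUE)
        lo <- pmax(1L, seq_len(n) - w)
        hi <- pmin(n, seq_len(n) + w)
        pos_list <- mapply(seq, lo, hi, SIMPLIFY = FALSE)
        ctr_pos <- rep.int(seq_len(n), lengths(pos_list))
        ctx_pos <- unlist(pos_list, use.names = FALSE)
        self <- ctr_pos == ctx_pos
        pairs[[length(pairs) + 1L]] <- cbind(si[ctr_pos[!self]],
                                             si[ctx_pos[!self]])
      }
      do.call(rbind, pairs)
    }

    all_pairs <- make_pairs()
    n_pairs <- nrow(all_pairs)
    chunk <- 512L
    total_steps <- max(1L, ceiling(n_pairs / chunk) * epochs)
    step <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n_pairs)
      for (start in seq(1L, n_pairs, by = chunk)) {
        step <- step + 1L
        rate <- lr * max(0.1, 1 - step / total_steps)
        sel <- ord[start:min(start + chunk - 1L, n_pairs)]
        ctr <- all_pairs[sel, 1L]
        ctx <- all_pairs[sel, 2L]
        nneg <- length(sel) * negative
        neg <- sample.int(length(vocab), nneg, replace = TRUE, prob = neg_prob)
        X <- compose(ctr)
        # positive examples
        s_pos <- nn_sigmoid(rowSums(X * Wout[ctx, , drop = FALSE]))
        g_pos <- s_pos - 1
        dX <- g_pos * Wout[ctx, , drop = FALSE]
        dOut_pos <- g_pos * X
        # negative examples (each pair gets `negative` of them)
        Xr <- X[rep(seq_along(sel), each = negative), , drop = FALSE]
        s_neg <- nn_sigmoid(rowSums(Xr * Wout[neg, , drop = FALSE]))
        g_neg <- s_neg
        dXneg <- rowsum(g_neg * Wout[neg, , drop = FALSE],
                        group = rep(seq_along(sel), each = negative),
                        reorder = FALSE)
        dX <- dX + dXneg
        dOut_neg <- g_neg * Xr
        # apply output updates (aggregated by term)
        upd_out <- rowsum(rbind(dOut_pos, dOut_neg), group = c(ctx, neg))
        ridx <- as.integer(rownames(upd_out))
        Wout[ridx, ] <- Wout[ridx, ] - rate * upd_out
        # input updates distribute over the word vector and its buckets
        upd_in <- rowsum(dX, group = ctr)
        for (r in seq_len(nrow(upd_in))) {
          i <- as.integer(rownames(upd_in)[r])
          ids <- grams[[i]]
          share <- 1 / (1 + length(ids))
          Win[i, ] <- Win[i, ] - rate * share * upd_in[r, ]
          if (length(ids) > 0) {
            Bkt[ids, ] <- Bkt[ids, ] -
              matrix(rate * share * upd_in[r, ], nrow = length(ids),
                     ncol = dim, byrow = TRUE)
          }
        }
      }
    }

    composed <- compose(seq_along(vocab))
    rownames(composed) <- vocab
    structure(
      list(vectors = composed, buckets_matrix = Bkt, vocab = vocab,
           dim = dim, min_n = min_n, max_n = max_n, buckets = buckets,
           hash_seed = seed),
      class = c("word_embeddings", "embedding_provider")
    )
  })
}

#' @export
print.word_embeddings <- function(x, ...) {
  cat("<word_embeddings> ", length(x$vocab), " terms, dim ", x$dim,
      ", ", x$buckets, " subword buckets\n", sep = "")
  invisible(x)
}

#' @export
token_vectors.word_embeddings <- function(provider, tokens) {
  out <- matrix(0, nrow = length(tokens), ncol = provider$dim,
                dimnames = list(tokens, NULL))
  known <- tokens %in% provider$vocab
  if (any(known)) out[known, ] <- provider$vectors[tokens[known], , drop = FALSE]
  for (i in which(!known)) {
    ids <- ngram_buckets(term_ngrams(tokens[i], provider$min_n, provider$max_n),
                         provider$buckets, provider$hash_seed)
    if (length(ids) > 0) {
      out[i, ] <- colMeans(provider$buckets_matrix[ids, , drop = FALSE])
    }
  }
  out
}

#' Cosine similarity between two terms under an embedding provider
#'
#' @param provider An embedding provider.
#' @param a,b Terms to compare.
#' @return Cosine similarity in `[-1, 1]` (0 if either vector is zero).
#' @export
embedding_similarity <- function(provider, a, b) {
  v <- token_vectors(provider, c(a, b))
  na <- sqrt(sum(v[1, ]^2))
  nb <- sqrt(sum(v[2, ]^2))
  if (na == 0 || nb == 0) return(0)
  sum(v[1, ] * v[2, ]) / (na * nb)
}
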