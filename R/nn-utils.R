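# Shared numerical machinery for the from-scratch neural classifiers:
# softmax cross-entropy, Adam with decoupled weight decay, and index
# preparation. Everything operates on plain base-R matrices so the training
# loop is deterministic given the RNG seed.

nn_softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

nn_sigmoid <- function(z) 1 / (1 + exp(-z))

# Adam state for a named list of parameter matrices/vectors.
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

# One Adam step. `decay_params` names the parameters that receive weight
# decay (decoupled by default, classic L2 when decay_mode = "l2").
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0, decay_params = character(),
                      decay_mode = c("weight_decay", "l2")) {
  decay_mode <- match.arg(decay_mode)
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (weight_decay > 0 && nm %in% decay_params && decay_mode == "l2") {
      g <- g + weight_decay * params[[nm]]
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    step <- lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    params[[nm]] <- params[[nm]] - step
    if (weight_decay > 0 && nm %in% decay_params && decay_mode == "weight_decay") {
      params[[nm]] <- params[[nm]] - lr * weight_decay * params[[nm]]
    }
  }
  list(params = params, state = state)
}

# Map token sequences to padded 1-based embedding-row indices.
# Row 1 of the embedding matrix is <pad> (kept at zero), row 2 is <oov>.
tokens_to_indices <- function(token_list, vocabulary, max_length) {
  lut <- setNames(vocabulary$index, vocabulary$term)
  t(vapply(token_list, function(toks) {
    idx <- unname(lut[toks])
    idx[is.na(idx)] <- 1L  # <oov>
    idx <- head(idx, max_length)
    c(idx, rep(0L, max_length - length(idx))) + 1L
  }, integer(max_length)))
}

# Initialise an embedding matrix for a vocabulary: either from a provided
# matrix / embedding provider or with small random values. Row 1 (<pad>)
# stays zero.
init_embedding_matrix <- function(vocabulary, dim, embeddings = NULL) {
  n <- nrow(vocabulary)
  E <- matrix(rnorm(n * dim, sd = 0.1), nrow = n)
  if (!is.null(embeddings)) {
    if (inherits(embeddings, "word_embeddings") ||
        inherits(embeddings, "embedding_provider")) {
      E <- token_vectors(embeddings, vocabulary$term)
      if (ncol(E) != dim) {
        config_error("embedding provider dimension does not match spec$embedding_dim")
      }
    } else if (is.matrix(embeddings)) {
      common <- intersect(vocabulary$term, rownames(embeddings))
      E[match(common, vocabulary$term), ] <- embeddings[common, , drop = FALSE]
    } else {
      config_error("`embeddings` must be a matrix or an embedding provider")
    }
  }
  E[vocabulary$term == "<pad>", ] <- 0
  unname(E)
}

# Macro-averaged F on 0-100 scale for early stopping.
macro_f <- function(truth, pred, classes) {
  fs <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, numeric(1))
  100 * mean(fs)
}
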