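# Shared fixtures and independent oracles for the test suite.

# Build a candidate-pair tibble from parallel lists of cause/effect term sets.
make_pairs <- function(causes, effects, id = NULL) {
  n <- length(causes)
  tibble::tibble(
    id = id %||% sprintf("m%03d", seq_len(n)),
    cue = "causes",
    position = 2L,
    cause = lapply(causes, as.character),
    effect = lapply(effects, as.character),
    degenerate = FALSE
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Brute-force probability tables from raw pairs: nested loops, no reuse of
# the package's incremental counting path.
bf_probabilities <- function(pairs, v_c, v_e, alpha) {
  joint <- matrix(0, length(v_c), length(v_e), dimnames = list(v_c, v_e))
  for (i in seq_len(nrow(pairs))) {
    for (wc in unique(pairs$cause[[i]])) {
      for (we in unique(pairs$effect[[i]])) {
        if (wc %in% v_c && we %in% v_e) {
          joint[wc, we] <- joint[wc, we] + 1
        }
      }
    }
  }
  joint <- joint + alpha
  joint <- joint / sum(joint)
  list(joint = joint, p_c = rowSums(joint), p_e = colSums(joint))
}

bf_npmi <- function(pairs, v_c, v_e, alpha, wc, we) {
  p <- bf_probabilities(pairs, v_c, v_e, alpha)
  q <- p$joint[wc, we]
  if (q <= 0) return(-1)
  if (q >= 1) return(1)
  log(q / (p$p_c[[wc]] * p$p_e[[we]])) / (-log(q))
}

bf_pmi <- function(pairs, v_c, v_e, alpha, wc, we) {
  p <- bf_probabilities(pairs, v_c, v_e, alpha)
  log(p$joint[wc, we] / (p$p_c[[wc]] * p$p_e[[we]]))
}

# Random candidate-pair fixture over small vocabularies.
random_pairs <- function(n, n_causes = 6, n_effects = 8) {
  causes <- paste0("c", seq_len(n_causes))
  effects <- paste0("e", seq_len(n_effects))
  make_pairs(
    causes = lapply(seq_len(n), function(i) {
      sample(causes, sample(1:3, 1))
    }),
    effects = lapply(seq_len(n), function(i) {
      sample(effects, sample(1:3, 1))
    })
  )
}

# A tiny labeled corpus with disjoint class vocabularies, ready for the
# classifier (normalized, tokenized).
separable_corpus <- function(n, seed) {
  cfg <- generator_config(n_messages = n, cue_rate = 0,
                          duplicate_rate = 0.1, seed = seed)
  normalize_messages(generate_corpus(cfg))
}

# Deterministic stub providers for embedding tests.
fixed_provider <- function(table) {
  function(tokens) {
    out <- t(vapply(tokens, function(tk) table[[tk]],
                    numeric(length(table[[1]]))))
    rownames(out) <- tokens
    out
  }
}
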