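# Convolutional text classifier: parallel 1-d convolutions over the token
# embedding sequence with several kernel widths, ReLU, max-over-time
# pooling, a dense ReLU layer with dropout and a softmax output. Trained
# with Adam on softmax cross-entropy; gradients are hand-derived and checked
# against finite differences in the test suite.

cnn_init <- function(spec, n_vocab) {
  d <- spec$embedding_dim
  f <- spec$filters
  widths <- spec$kernel_widths
  params <- list()
  for (k in widths) {
    fan_in <- k * d
    params[[paste0("W_conv", k)]] <-
      matrix(rnorm(f * fan_in, sd = sqrt(2 / fan_in)), nrow = f)
    params[[paste0("b_conv", k)]] <- numeric(f)
  }
  total_f <- f * length(widths)
  params$W_dense <- matrix(rnorm(spec$dense_units * total_f,
                                 sd = sqrt(2 / total_f)),
                           nrow = spec$dense_units)
  params$b_dense <- numeric(spec$dense_units)
  params$W_out <- matrix(rnorm(2 * spec$dense_units,
                               sd = sqrt(2 / spec$dense_units)), nrow = 2)
  params$b_out <- numeric(2)
  params
}

cnn_decay_params <- function(params) {
  grep("^W_", names(params), value = TRUE)
}

# Unfold a message's embedded sequence into convolution windows:
# row t = concatenated embeddings of tokens t .. t+k-1.
cnn_unfold <- function(M, k) {
  L <- nrow(M)
  n_pos <- L - k + 1L
  out <- matrix(0, nrow = n_pos, ncol = k * ncol(M))
  for (j in seq_len(k)) {
    out[, ((j - 1L) * ncol(M) + 1L):(j * ncol(M))] <- M[j:(j + n_pos - 1L), , drop = FALSE]
  }
  out
}

# Forward pass over a batch of index rows. Returns probabilities and, when
# `keep = TRUE`, the intermediates needed for the backward pass.
cnn_forward <- function(params, E, idx, spec, dropout_mask = NULL,
                        keep = FALSE) {
  B <- nrow(idx)
  widths <- spec$kernel_widths
  f <- spec$filters
  H <- matrix(0, nrow = B, ncol = f * length(widths))
  cache <- if (keep) vector("list", B)
  for (b in seq_len(B)) {
    M <- E[idx[b, ], , drop = FALSE]
    hb <- numeric(0)
    cb <- if (keep) list(M = M)
    for (w in seq_along(widths)) {
      k <- widths[w]
      Munf <- cnn_unfold(M, k)
      Z <- Munf %*% t(params[[paste0("W_conv", k)]])
      Z <- sweep(Z, 2, params[[paste0("b_conv", k)]], "+")
      A <- pmax(Z, 0)
      amax <- max.col(t(A), ties.method = "first")
      pooled <- A[cbind(amax, seq_len(f))]
      hb <- c(hb, pooled)
      if (keep) {
        cb[[paste0("Munf", k)]] <- Munf
        cb[[paste0("amax", k)]] <- amax
        cb[[paste0("pos", k)]] <- pooled > 0
      }
    }
    H[b, ] <- hb
    if (keep) cache[[b]] <- cb
  }
  A1 <- H %*% t(params$W_dense)
  A1 <- sweep(A1, 2, params$b_dense, "+")
  R1 <- pmax(A1, 0)
  D1 <- if (is.null(dropout_mask)) R1 else R1 * dropout_mask
  O <- D1 %*% t(params$W_out)
  O <- sweep(O, 2, params$b_out, "+")
  P <- nn_softmax(O)
  out <- list(P = P, H = H, R1 = R1, D1 = D1)
  if (keep) out$cache <- cache
  out
}

# Backward pass; `y` is a 0/1 matrix (B x 2). Returns gradients including
# the embedding gradient dE.
cnn_backward <- function(params, E, idx, spec, fwd, y, dropout_mask = NULL) {
  B <- nrow(idx)
  widths <- spec$kernel_widths
  f <- spec$filters
  d <- spec$embedding_dim
  dO <- (fwd$P - y) / B
  grads <- list()
  grads$W_out <- t(dO) %*% fwd$D1
  grads$b_out <- colSums(dO)
  dD1 <- dO %*% params$W_out
  dR1 <- if (is.null(dropout_mask)) dD1 else dD1 * dropout_mask
  dA1 <- dR1 * (fwd$R1 > 0)
  grads$W_dense <- t(dA1) %*% fwd$H
  grads$b_dense <- colSums(dA1)
  dH <- dA1 %*% params$W_dense
  for (k in widths) {
    grads[[paste0("W_conv", k)]] <- params[[paste0("W_conv", k)]] * 0
    grads[[paste0("b_conv", k)]] <- numeric(f)
  }
  dE <- E * 0
  for (b in seq_len(B)) {
    cb <- fwd$cache[[b]]
    dM <- matrix(0, nrow = nrow(cb$M), ncol = d)
    for (w in seq_along(widths)) {
      k <- widths[w]
      g <- dH[b, ((w - 1L) * f + 1L):(w * f)] * cb[[paste0("pos", k)]]
      live <- which(g != 0)
      if (length(live) == 0) next
      amax <- cb[[paste0("amax", k)]]
      Munf <- cb[[paste0("Munf", k)]]
      Wk <- params[[paste0("W_conv", k)]]
      grads[[paste0("W_conv", k)]][live, ] <-
        grads[[paste0("W_conv", k)]][live, , drop = FALSE] +
        Munf[amax[live], , drop = FALSE] * g[live]
      grads[[paste0("b_conv", k)]][live] <-
        grads[[paste0("b_conv", k)]][live] + g[live]
      for (j in live) {
        rows <- amax[j]:(amax[j] + k - 1L)
        dM[rows, ] <- dM[rows, ] +
          g[j] * matrix(Wk[j, ], nrow = k, ncol = d, byrow = TRUE)
      }
    }
    touched <- unique(idx[b, ])
    agg <- rowsum(dM, group = idx[b, ])
    dE[as.integer(rownames(agg)), ] <- dE[as.integer(rownames(agg)), ] + agg
  }
  dE[1, ] <- 0  # <pad> row frozen
  grads$E <- dE
  grads
}

cnn_loss <- function(P, y) {
  -mean(log(pmax(rowSums(P * y), 1e-12)))
}
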