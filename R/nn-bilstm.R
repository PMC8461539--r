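# Bidirectional LSTM baseline: one LSTM over the token sequence in each
# direction, masked mean-pooling of the hidden states, then the same dense
# ReLU + dropout + softmax head as the convolutional model. Gradients are
# hand-derived (backpropagation through time) and finite-difference checked
# in the test suite.

bilstm_init <- function(spec, n_vocab) {
  d <- spec$embedding_dim
  H <- spec$hidden_units
  one_dir <- function() {
    list(
      Wx = matrix(rnorm(4 * H * d, sd = sqrt(1 / d)), nrow = 4 * H),
      Wh = matrix(rnorm(4 * H * H, sd = sqrt(1 / H)), nrow = 4 * H),
      b = c(numeric(H), rep(1, H), numeric(2 * H))  # forget-gate bias 1
    )
  }
  fwd <- one_dir()
  bwd <- one_dir()
  params <- list(
    Wx_f = fwd$Wx, Wh_f = fwd$Wh, b_f = fwd$b,
    Wx_b = bwd$Wx, Wh_b = bwd$Wh, b_b = bwd$b
  )
  total_h <- 2 * H
  params$W_dense <- matrix(rnorm(spec$dense_units * total_h,
                                 sd = sqrt(2 / total_h)),
                           nrow = spec$dense_units)
  params$b_dense <- numeric(spec$dense_units)
  params$W_out <- matrix(rnorm(2 * spec$dense_units,
                               sd = sqrt(2 / spec$dense_units)), nrow = 2)
  params$b_out <- numeric(2)
  params
}

bilstm_decay_params <- function(params) {
  grep("^W", names(params), value = TRUE)
}

# Run one direction over padded index rows `idx` (B x L). `mask` is B x L
# 0/1. Returns pooled states and per-step intermediates for BPTT.
lstm_direction <- function(Wx, Wh, b, E, idx, mask, H, keep = FALSE) {
  B <- nrow(idx)
  L <- ncol(idx)
  h <- matrix(0, B, H)
  cc <- matrix(0, B, H)
  pooled <- matrix(0, B, H)
  lens <- pmax(rowSums(mask), 1)
  steps <- if (keep) vector("list", L)
  for (t in seq_len(L)) {
    m <- mask[, t]
    x <- E[idx[, t], , drop = FALSE]
    G <- x %*% t(Wx) + h %*% t(Wh)
    G <- sweep(G, 2, b, "+")
    i <- nn_sigmoid(G[, 1:H, drop = FALSE])
    f <- nn_sigmoid(G[, (H + 1):(2 * H), drop = FALSE])
    o <- nn_sigmoid(G[, (2 * H + 1):(3 * H), drop = FALSE])
    g <- tanh(G[, (3 * H + 1):(4 * H), drop = FALSE])
    c_new <- f * cc + i * g
    tc <- tanh(c_new)
    h_new <- o * tc
    if (keep) {
      steps[[t]] <- list(x = x, h_prev = h, c_prev = cc, i = i, f = f, o = o,
                         g = g, tc = tc, m = m)
    }
    h <- h_new * m + h * (1 - m)
    cc <- c_new * m + cc * (1 - m)
    pooled <- pooled + h * m  # masked steps contribute nothing
  }
  pooled <- pooled / lens
  list(pooled = pooled, steps = steps, lens = lens)
}

# BPTT for one direction given the gradient of the pooled output.
lstm_direction_backward <- function(Wx, Wh, b, E, idx, mask, H, run, dpooled) {
  B <- nrow(idx)
  L <- ncol(idx)
  dWx <- Wx * 0
  dWh <- Wh * 0
  db <- b * 0
  dE <- E * 0
  dh <- matrix(0, B, H)
  dc <- matrix(0, B, H)
  per_step <- dpooled / run$lens
  for (t in rev(seq_len(L))) {
    st <- run$steps[[t]]
    m <- st$m
    dh_t <- dh + per_step * m
    # state updates were gated by the mask: grads flow through the gate for
    # live rows and straight to the previous state for masked rows
    dh_live <- dh_t * m
    dc_live <- (dc + dh_live * st$o * (1 - st$tc^2)) * m
    do <- dh_live * st$tc
    df <- dc_live * st$c_prev
    di <- dc_live * st$g
    dg <- dc_live * st$i
    dG <- cbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                do * st$o * (1 - st$o),
                dg * (1 - st$g^2))
    dWx <- dWx + t(dG) %*% st$x
    dWh <- dWh + t(dG) %*% st$h_prev
    db <- db + colSums(dG)
    dx <- dG %*% Wx
    agg <- rowsum(dx, group = idx[, t])
    rows <- as.integer(rownames(agg))
    dE[rows, ] <- dE[rows, ] + agg
    dh <- dG %*% Wh + dh_t * (1 - m)
    dc <- dc_live * st$f + dc * (1 - m)
  }
  dE[1, ] <- 0
  list(Wx = dWx, Wh = dWh, b = db, dE = dE)
}

# Reverse each row's valid prefix (padding stays at the end).
reverse_indices <- function(idx, mask) {
  out <- idx
  for (b in seq_len(nrow(idx))) {
    n <- sum(mask[b, ])
    if (n > 1) out[b, seq_len(n)] <- idx[b, n:1]
  }
  out
}

bilstm_forward <- function(params, E, idx, mask, spec, dropout_mask = NULL,
                           keep = FALSE) {
  H <- spec$hidden_units
  idx_rev <- reverse_indices(idx, mask)
  run_f <- lstm_direction(params$Wx_f, params$Wh_f, params$b_f, E, idx, mask,
                          H, keep)
  run_b <- lstm_direction(params$Wx_b, params$Wh_b, params$b_b, E, idx_rev,
                          mask, H, keep)
  Hcat <- cbind(run_f$pooled, run_b$pooled)
  A1 <- Hcat %*% t(params$W_dense)
  A1 <- sweep(A1, 2, params$b_dense, "+")
  R1 <- pmax(A1, 0)
  D1 <- if (is.null(dropout_mask)) R1 else R1 * dropout_mask
  O <- D1 %*% t(params$W_out)
  O <- sweep(O, 2, params$b_out, "+")
  P <- nn_softmax(O)
  out <- list(P = P, Hcat = Hcat, R1 = R1, D1 = D1, idx_rev = idx_rev)
  if (keep) {
    out$run_f <- run_f
    out$run_b <- run_b
  }
  out
}

bilstm_backward <- function(params, E, idx, mask, spec, fwd, y,
                            dropout_mask = NULL) {
  B <- nrow(idx)
  H <- spec$hidden_units
  dO <- (fwd$P - y) / B
  grads <- list()
  grads$W_out <- t(dO) %*% fwd$D1
  grads$b_out <- colSums(dO)
  dD1 <- dO %*% params$W_out
  dR1 <- if (is.null(dropout_mask)) dD1 else dD1 * dropout_mask
  dA1 <- dR1 * (fwd$R1 > 0)
  grads$W_dense <- t(dA1) %*% fwd$Hcat
  grads$b_dense <- colSums(dA1)
  dHcat <- dA1 %*% params$W_dense
  gf <- lstm_direction_backward(params$Wx_f, params$Wh_f, params$b_f, E, idx,
                                mask, H, fwd$run_f,
                                dHcat[, 1:H, drop = FALSE])
  gb <- lstm_direction_backward(params$Wx_b, params$Wh_b, params$b_b, E,
                                fwd$idx_rev, mask, H, fwd$run_b,
                                dHcat[, (H + 1):(2 * H), drop = FALSE])
  grads$Wx_f <- gf$Wx; grads$Wh_f <- gf$Wh; grads$b_f <- gf$b
  grads$Wx_b <- gb$Wx; grads$Wh_b <- gb$Wh; grads$b_b <- gb$b
  grads$E <- gf$dE + gb$dE
  grads$E[1, ] <- 0
  grads
}
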