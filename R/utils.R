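# Internal helpers shared across modules.

# Stop with a classed condition so callers (and the CLI) can distinguish
# configuration errors from data errors.
config_error <- function(msg, ...) {
  abort(msg, class = "riskmine_config_error", ...)
}

data_error <- function(msg, ...) {
  abort(msg, class = "riskmine_data_error", ...)
}

lookup_error <- function(msg, ...) {
  abort(msg, class = "riskmine_lookup_error", ...)
}

assert_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    config_error(sprintf("`%s` must be a single probability in [0, 1], got %s",
                         name, deparse(substitute(x))))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    config_error(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  invisible(as.integer(x))
}

# Deterministic 32-bit string hash (FNV-1a), used by the hashing embedding
# provider and for deriving per-token seeds. Returns a double in [0, 2^31).
hash_string <- function(x, seed = 0L) {
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 2166136261 + as.double(seed)
  h <- h %% 4294967296
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483648), as.integer(b))
    h <- (as.double(h) * 16777619) %% 4294967296
  }
  floor(h %% 2147483648)
}

# Cosine distance matrix between rows of two matrices (or one matrix with
# itself). Guards zero vectors by treating them as distance 1 from everything
# except themselves.
cosine_distance <- function(a, b = NULL) {
  b <- b %||% a
  na <- sqrt(rowSums(a^2))
  nb <- sqrt(rowSums(b^2))
  sim <- tcrossprod(a, b) / (pmax(na, .Machine$double.eps) %o%
                               pmax(nb, .Machine$double.eps))
  sim[sim > 1] <- 1
  sim[sim < -1] <- -1
  d <- 1 - sim
  zero_a <- na == 0
  zero_b <- nb == 0
  if (any(zero_a) || any(zero_b)) {
    d[zero_a, ] <- 1
    d[, zero_b] <- 1
    d[zero_a, zero_b] <- 0
  }
  d
}

`%|NA|%` <- function(x, y) ifelse(is.na(x), y, x)
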