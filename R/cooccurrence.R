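# Cause-effect co-occurrence model with Laplace smoothing, PMI and NPMI.
#
# The counting unit is the candidate (cause phrase, effect phrase) pair: for
# pair i, every (w_c, w_e) with w_c in c_i (intersected with V_c) and w_e in
# e_j (intersected with V_e) increments the joint count once. Probabilities
# come from the smoothed joint table (alpha added to every cell, table
# normalized to sum 1) and the marginals are its row/column sums, which
# guarantees a coherent probability model for any alpha >= 0.

#' Build a cause-effect co-occurrence model
#'
#' @param pairs Candidate-pair tibble from [extract_candidate_pairs()];
#'   degenerate pairs contribute nothing and are tolerated.
#' @param vocabularies List with `v_c` / `v_e` tibbles from
#'   [build_phrase_vocabularies()], or a list of two character vectors.
#' @param alpha Laplace smoothing constant added to every joint cell;
#'   `alpha = 1` is classic Laplace smoothing, `alpha = 0` disables
#'   smoothing (PMI of a zero-count pair is then `-Inf` and its NPMI is -1
#'   by convention).
#' @param log_base Base of the logarithm used by [pmi()]; NPMI is
#'   base-invariant.
#' @return An object of class `cooccurrence_model`.
#' @export
build_cooccurrence_model <- function(pairs, vocabularies, alpha = 1,
                                     log_base = exp(1)) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0) {
    config_error("`alpha` must be a single nonnegative number")
  }
  if (!is.numeric(log_base) || log_base <= 0 || log_base == 1) {
    config_error("`log_base` must be positive and not 1")
  }
  v_c <- if (is.data.frame(vocabularies$v_c)) vocabularies$v_c$term else vocabularies$v_c
  v_e <- if (is.data.frame(vocabularies$v_e)) vocabularies$v_e$term else vocabularies$v_e
  if (length(v_c) == 0 || length(v_e) == 0) {
    config_error("both vocabularies must be nonempty")
  }
  counts <- matrix(0, nrow = length(v_c), ncol = length(v_e),
                   dimnames = list(v_c, v_e))
  m <- 0L
  for (i in seq_len(nrow(pairs))) {
    wc <- intersect(unique(pairs$cause[[i]]), v_c)
    we <- intersect(unique(pairs$effect[[i]]), v_e)
    if (length(wc) > 0 && length(we) > 0) {
      counts[wc, we] <- counts[wc, we] + 1
      m <- m + 1L
    }
  }
  if (m == 0 && alpha == 0) {
    data_error("no candidate pair contributed a counted (cause, effect) term pair")
  }
  structure(
    list(counts = counts, alpha = alpha, log_base = log_base, m = m,
         v_c = v_c, v_e = v_e),
    class = "cooccurrence_model"
  )
}

#' @export
print.cooccurrence_model <- function(x, ...) {
  cat("<cooccurrence_model> ", length(x$v_c), " cause terms x ",
      length(x$v_e), " effect terms, ", x$m,
      " counted pairs, alpha = ", x$alpha, "\n", sep = "")
  invisible(x)
}

# Smoothed probability tables; computed on demand (tables are small).
model_probabilities <- function(model) {
  joint <- model$counts + model$alpha
  total <- sum(joint)
  if (total == 0) data_error("model has no probability mass (alpha = 0, no counts)")
  joint <- joint / total
  list(joint = joint, p_c = rowSums(joint), p_e = colSums(joint))
}

check_terms <- function(model, w_c, w_e) {
  bad_c <- setdiff(w_c, model$v_c)
  bad_e <- setdiff(w_e, model$v_e)
  if (length(bad_c) > 0 || length(bad_e) > 0) {
    lookup_error(paste0("unknown term(s): ",
                        paste(c(bad_c, bad_e), collapse = ", ")))
  }
}

#' Pointwise mutual information of a cause-effect term pair
#'
#' `log( p(w_c, w_e) / (p(w_c) p(w_e)) )` in the model's log base. Finite
#' whenever the model was built with `alpha > 0`; `-Inf` for an unsmoothed
#' zero-count pair. Vectorized over `w_c` / `w_e`.
#'
#' @param model A [build_cooccurrence_model()] object.
#' @param w_c,w_e Cause- and effect-side terms (recycled to equal length).
#' @return Numeric vector of PMI values.
#' @export
pmi <- function(model, w_c, w_e) {
  stopifnot(inherits(model, "cooccurrence_model"))
  check_terms(model, w_c, w_e)
  p <- model_probabilities(model)
  n <- max(length(w_c), length(w_e))
  w_c <- rep_len(w_c, n)
  w_e <- rep_len(w_e, n)
  q <- p$joint[cbind(w_c, w_e)]
  unname(log(q / (p$p_c[w_c] * p$p_e[w_e]), base = model$log_base))
}

#' Normalized pointwise mutual information of a cause-effect term pair
#'
#' `pmi / (-log p(w_c, w_e))`, always in `[-1, 1]` and independent of the
#' log base: -1 means the terms never co-occur (zero-count convention under
#' `alpha = 0`), 0 means they are statistically independent, 1 is complete
#' co-occurrence (including the limit `p(w_c, w_e) = 1`, where the ratio is
#' 0/0). Vectorized over `w_c` / `w_e`.
#'
#' @inheritParams pmi
#' @return Numeric vector of NPMI values in `[-1, 1]`.
#' @export
npmi <- function(model, w_c, w_e) {
  stopifnot(inherits(model, "cooccurrence_model"))
  check_terms(model, w_c, w_e)
  p <- model_probabilities(model)
  n <- max(length(w_c), length(w_e))
  w_c <- rep_len(w_c, n)
  w_e <- rep_len(w_e, n)
  q <- p$joint[cbind(w_c, w_e)]
  out <- numeric(n)
  zero <- q <= 0
  one <- q >= 1
  mid <- !zero & !one
  out[zero] <- -1
  out[one] <- 1
  if (any(mid)) {
    val <- log(q[mid] / (p$p_c[w_c[mid]] * p$p_e[w_e[mid]])) / (-log(q[mid]))
    out[mid] <- pmin(1, pmax(-1, val))
  }
  out
}

#' Persist / load a co-occurrence model
#'
#' The model is written as a sparse triplet TSV (`w_c`, `w_e`, `count`) next
#' to a JSON header carrying `alpha`, `log_base`, `m` and the two
#' vocabularies, at `<path>.tsv` and `<path>.json`.
#'
#' @param model A `cooccurrence_model`.
#' @param path Path prefix (no extension).
#' @return `read_cooccurrence_model()` returns the model object.
#' @export
write_cooccurrence_model <- function(model, path) {
  idx <- which(model$counts > 0, arr.ind = TRUE)
  trip <- tibble(
    w_c = rownames(model$counts)[idx[, 1]],
    w_e = colnames(model$counts)[idx[, 2]],
    count = model$counts[idx]
  )
  readr::write_tsv(trip, paste0(path, ".tsv"), progress = FALSE)
  jsonlite::write_json(
    list(alpha = model$alpha, log_base = model$log_base, m = model$m,
         v_c = model$v_c, v_e = model$v_e),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cooccurrence_model
#' @export
read_cooccurrence_model <- function(path) {
  header <- jsonlite::fromJSON(paste0(path, ".json"))
  trip <- readr::read_tsv(paste0(path, ".tsv"), col_types = "ccd",
                          progress = FALSE)
  counts <- matrix(0, nrow = length(header$v_c), ncol = length(header$v_e),
                   dimnames = list(header$v_c, header$v_e))
  if (nrow(trip) > 0) counts[cbind(trip$w_c, trip$w_e)] <- trip$count
  structure(
    list(counts = counts, alpha = header$alpha, log_base = header$log_base,
         m = header$m, v_c = header$v_c, v_e = header$v_e),
    class = "cooccurrence_model"
  )
}
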