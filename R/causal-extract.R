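# Causal-cue screening and candidate cause/effect phrase extraction.
#
# A candidate causal phrase is the term set on the cause side of a causal
# cue within one message; the effect phrase is the term set on the other
# side. Noun phrases are approximated by a deterministic rule-based chunker
# (maximal runs of content tokens); multi-word chunks are merged into single
# underscore-joined terms so they keep their identity inside term sets.

#' Rule-based noun-phrase chunker
#'
#' Deterministic stand-in for a statistical parser: contiguous runs of
#' content tokens (anything that is not a stopword or a special token) are
#' treated as noun-phrase chunks and merged into single underscore-joined
#' terms. The chunker satisfies the package's parse
#' provider contract, `function(tokens) -> character vector of chunk terms`,
#' so a dependency-parser-backed provider can be swapped in.
#'
#' @param tokens Character vector of normalized tokens.
#' @param stopwords Stopword list acting as chunk boundaries.
#' @return Character vector of chunk terms (possibly empty).
#' @export
rule_chunker <- function(tokens, stopwords = riskmine_stopwords()) {
  if (length(tokens) == 0) return(character(0))
  boundary <- tokens %in% stopwords | tokens %in% c("MENTION", "NUMBER", "RT")
  runs <- rle(boundary)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- !runs$values
  purrr::map2_chr(starts[keep], ends[keep],
                  ~ paste(tokens[.x:.y], collapse = "_"))
}

#' Find causal-cue occurrences in a token sequence
#'
#' Scans left to right for non-overlapping cue occurrences, preferring the
#' longest cue at each position (so `"lead to"` wins over `"to"`).
#'
#' @param tokens Character vector of normalized tokens.
#' @param cues Cue lexicon (character vector; multi-word cues are
#'   space-separated). See [default_cue_lexicon()].
#' @return A tibble with columns `cue`, `position` (1-based index of the
#'   cue's first token) and `length` (cue length in tokens); zero rows if no
#'   cue is present.
#' @export
find_causal_cues <- function(tokens, cues = default_cue_lexicon()) {
  cues <- validate_cue_lexicon(cues)
  cue_tokens <- strsplit(cues, " ", fixed = TRUE)
  first <- vapply(cue_tokens, `[`, character(1), 1L)
  hits <- find_cues_impl(tokens, cue_tokens, first)
  tibble(cue = cues[hits$cue], position = hits$position,
         length = hits$length)
}

# Core cue scanner with the lexicon pre-parsed (hot loop of extraction).
find_cues_impl <- function(tokens, cue_tokens, first) {
  empty <- list(cue = integer(), position = integer(), length = integer())
  n <- length(tokens)
  if (n == 0) return(empty)
  cand <- which(first %in% tokens)
  if (length(cand) == 0) return(empty)
  # all candidate occurrences, then a left-to-right longest-first sweep
  occ_cue <- integer(0)
  occ_pos <- integer(0)
  occ_len <- integer(0)
  for (k in cand) {
    ct <- cue_tokens[[k]]
    len <- length(ct)
    if (len > n) next
    hit <- tokens[seq_len(n - len + 1L)] == ct[1L]
    if (len > 1) {
      for (j in 2:len) {
        hit <- hit & tokens[j:(n - len + j)] == ct[j]
      }
    }
    pos <- which(hit)
    occ_cue <- c(occ_cue, rep.int(k, length(pos)))
    occ_pos <- c(occ_pos, pos)
    occ_len <- c(occ_len, rep.int(len, length(pos)))
  }
  if (length(occ_pos) == 0) return(empty)
  ord <- order(occ_pos, -occ_len)
  keep <- integer(0)
  blocked_until <- 0L
  for (r in ord) {
    if (occ_pos[r] > blocked_until) {
      keep <- c(keep, r)
      blocked_until <- occ_pos[r] + occ_len[r] - 1L
    }
  }
  list(cue = occ_cue[keep], position = occ_pos[keep], length = occ_len[keep])
}

#' Screen texts for causal cues
#'
#' Vectorized corpus-level screen: returns whether each normalized text
#' contains at least one cue from the lexicon. Equivalent to checking
#' `nrow(find_causal_cues(tokens, cues)) > 0` per message, but implemented
#' as a single regular-expression pass so it scales to large corpora.
#'
#' @param texts Character vector of normalized texts (single-spaced tokens).
#' @param cues Cue lexicon.
#' @return Logical vector, one element per text.
#' @export
has_causal_cue <- function(texts, cues = default_cue_lexicon()) {
  cues <- validate_cue_lexicon(cues)
  esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", cues)
  pattern <- paste0("\\b(", paste(esc, collapse = "|"), ")\\b")
  stringr::str_detect(texts, pattern)
}

#' Extract candidate cause/effect pairs from normalized messages
#'
#' For every causal-cue occurrence in every message, the chunker is applied
#' to the tokens left of the cue (candidate causal phrase) and right of the
#' cue (candidate effect phrase). A pair with an empty side is flagged
#' degenerate rather than dropped. One pair is emitted per cue occurrence,
#' so a message with two cues contributes two pairs.
#'
#' @param messages Normalized message tibble with `id` and `tokens` columns
#'   (see [normalize_messages()]).
#' @param cues Cue lexicon.
#' @param chunker Parse provider, `function(tokens) -> chunk terms`; defaults
#'   to [rule_chunker()].
#' @return A tibble with columns `id`, `cue`, `position`, `cause` and
#'   `effect` (list-columns of term sets) and `degenerate`.
#' @export
extract_candidate_pairs <- function(messages, cues = default_cue_lexicon(),
                                    chunker = rule_chunker) {
  messages <- as_tibble(messages)
  if (!all(c("id", "tokens") %in% names(messages))) {
    data_error("`messages` must have `id` and `tokens` columns")
  }
  cues <- validate_cue_lexicon(cues)
  cue_tokens <- strsplit(cues, " ", fixed = TRUE)
  first <- vapply(cue_tokens, `[`, character(1), 1L)
  res <- vector("list", nrow(messages))
  for (mi in seq_len(nrow(messages))) {
    tokens <- messages$tokens[[mi]]
    occ <- find_cues_impl(tokens, cue_tokens, first)
    n_hits <- length(occ$position)
    if (n_hits == 0) next
    cause <- vector("list", n_hits)
    effect <- vector("list", n_hits)
    for (h in seq_len(n_hits)) {
      pos <- occ$position[h]
      len <- occ$length[h]
      left <- if (pos > 1) tokens[seq_len(pos - 1L)] else character(0)
      right_start <- pos + len
      right <- if (right_start <= length(tokens)) {
        tokens[right_start:length(tokens)]
      } else character(0)
      cause[[h]] <- tryCatch(unique(chunker(left)),
                             error = function(e) character(0))
      effect[[h]] <- tryCatch(unique(chunker(right)),
                              error = function(e) character(0))
    }
    res[[mi]] <- list(id = rep.int(messages$id[mi], n_hits),
                      cue = cues[occ$cue], position = occ$position,
                      cause = cause, effect = effect)
  }
  res <- res[!vapply(res, is.null, logical(1))]
  cause <- unlist(lapply(res, `[[`, "cause"), recursive = FALSE)
  effect <- unlist(lapply(res, `[[`, "effect"), recursive = FALSE)
  tibble(
    id = unlist(lapply(res, `[[`, "id")) %||% character(0),
    cue = unlist(lapply(res, `[[`, "cue")) %||% character(0),
    position = unlist(lapply(res, `[[`, "position")) %||% integer(0),
    cause = cause %||% list(),
    effect = effect %||% list(),
    degenerate = (lengths(cause) == 0 | lengths(effect) == 0) %||% logical(0)
  )
}

#' Build cause- and effect-side phrase vocabularies
#'
#' Collects the terms appearing in candidate causal phrases (`V_c`) and
#' candidate effect phrases (`V_e`), counting each term once per pair (set
#' semantics), then removes stopwords and terms with corpus frequency 1.
#'
#' @param pairs Candidate-pair tibble from [extract_candidate_pairs()].
#' @param stopwords Stopword list.
#' @param min_frequency Terms with frequency strictly below this are
#'   dropped; the default 2 excludes hapax terms.
#' @return A list with tibbles `v_c` and `v_e` (columns `term`,
#'   `frequency`).
#' @export
build_phrase_vocabularies <- function(pairs, stopwords = riskmine_stopwords(),
                                      min_frequency = 2L) {
  if (nrow(pairs) == 0) data_error("no candidate pairs supplied")
  side_vocab <- function(col) {
    terms <- unlist(lapply(pairs[[col]], unique), use.names = FALSE)
    terms <- terms[!terms %in% stopwords &
                     !terms %in% c("MENTION", "NUMBER", "RT")]
    if (length(terms) == 0) return(tibble(term = character(), frequency = integer()))
    freq <- table(terms)
    keep <- freq[freq >= min_frequency]
    tibble(term = names(keep), frequency = as.integer(keep)) %>%
      arrange(desc(.data$frequency), .data$term)
  }
  v_c <- side_vocab("cause")
  v_e <- side_vocab("effect")
  if (nrow(v_c) == 0 || nrow(v_e) == 0) {
    data_error(paste0(
      "all candidate terms were filtered out (stopword / minimum-frequency ",
      "rules); v_c has ", nrow(v_c), " terms, v_e has ", nrow(v_e), " terms"))
  }
  list(v_c = v_c, v_e = v_e)
}

#' Read / write candidate pairs as JSON Lines
#'
#' One object per line: `{"id", "cue", "position", "cause": [...],
#' "effect": [...], "degenerate"}`.
#'
#' @param pairs Candidate-pair tibble.
#' @param path File path.
#' @return `read_candidate_pairs()` returns the candidate-pair tibble.
#' @export
write_candidate_pairs <- function(pairs, path) {
  lines <- purrr::pmap_chr(pairs, function(id, cue, position, cause, effect,
                                           degenerate, ...) {
    jsonlite::toJSON(list(id = jsonlite::unbox(id), cue = jsonlite::unbox(cue),
                          position = jsonlite::unbox(position),
                          cause = cause, effect = effect,
                          degenerate = jsonlite::unbox(degenerate)))
  })
  readr::write_lines(lines, path)
  invisible(path)
}

#' @rdname write_candidate_pairs
#' @export
read_candidate_pairs <- function(path) {
  lines <- readr::read_lines(path)
  purrr::map(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    tibble(id = x$id, cue = x$cue, position = as.integer(x$position),
           cause = list(as.character(x$cause)),
           effect = list(as.character(x$effect)),
           degenerate = isTRUE(x$degenerate))
  }) %>% bind_rows()
}
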