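# Rule-based lexical normalization for short social-media messages.
#
# The normalizer is deliberately a fixed ordered rule list (no statistical
# components) so that its output is reproducible byte-for-byte. Special
# tokens (NUMBER, MENTION, RT) are written upper-case so they can never
# collide with normalized content terms, which are all lower-case.

# placeholders keep special tokens safe from the lower-casing and
# punctuation rules, which also makes normalization idempotent
.PH_MENTION <- "\u0001"
.PH_NUMBER <- "\u0002"
.PH_RT <- "\u0003"

#' Contraction expansion table
#'
#' Returns the table of contraction expansions applied during normalization.
#' The default table ships with the package as an editable CSV with columns
#' `pattern`, `replacement` and `anchor` (`word` = match as a whole word,
#' `suffix` = match at a word end, `literal` = match anywhere).
#'
#' @param path Optional path to a replacement CSV with the same columns.
#' @return A tibble with columns `pattern`, `replacement`, `anchor`.
#' @export
riskmine_contractions <- function(path = NULL) {
  path <- path %||% system.file("extdata", "contractions.csv",
                                package = "riskmine", mustWork = TRUE)
  tbl <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         trim_ws = FALSE, progress = FALSE)
  stopifnot(all(c("pattern", "replacement", "anchor") %in% names(tbl)))
  tbl
}

#' Normalize raw message text
#'
#' Applies the package's ordered lexical normalization rules: lower-casing;
#' URL removal; tagging of retweet markers, user mentions and numerals as the
#' special tokens `RT`, `MENTION` and `NUMBER`; contraction expansion from an
#' editable table; hyphen/slash splitting; splitting of joined letter-digit
#' runs ("2x" becomes "NUMBER x"); removal of hashtag marks and remaining
#' punctuation (tag text is kept); whitespace collapsing; and reduction of
#' runs of 3+ MENTION tokens to exactly 2. The function is total and
#' idempotent: any character input yields a (possibly empty) normalized
#' string, and re-normalizing a normalized string is a no-op.
#'
#' @param x Character vector of raw message texts.
#' @param contractions Contraction table, see [riskmine_contractions()].
#' @return Character vector of normalized texts, same length as `x`.
#' @export
#' @examples
#' normalize_text("Can't stop HPV-vaccine lies & myths")
#' normalize_text("@a @b @c gardasil")
normalize_text <- function(x, contractions = riskmine_contractions()) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  # drop stray control characters, then shield existing special tokens
  x <- gsub("[\\x01-\\x08]", " ", x, perl = TRUE)
  x <- gsub("\\bMENTION\\b", .PH_MENTION, x)
  x <- gsub("\\bNUMBER\\b", .PH_NUMBER, x)
  x <- gsub("\\bRT\\b", .PH_RT, x)
  x <- tolower(x)
  # URLs
  x <- gsub("(https?://|www\\.)[^[:space:]]+", " ", x, perl = TRUE)
  # leading retweet marker: "rt" token, optionally "rt @user:"
  x <- sub("^\\s*rt\\b", paste0(" ", .PH_RT, " "), x)
  # user mentions
  x <- gsub("@[a-z0-9_]+", paste0(" ", .PH_MENTION, " "), x)
  # joined letter-digit runs, then numerals (incl. decimals / thousands)
  x <- gsub("([a-z])([0-9])", "\\1 \\2", x)
  x <- gsub("([0-9])([a-z])", "\\1 \\2", x)
  x <- gsub("[0-9]+([.,][0-9]+)*", paste0(" ", .PH_NUMBER, " "), x)
  # contraction expansion
  for (i in seq_len(nrow(contractions))) {
    pat <- contractions$pattern[i]
    rep <- contractions$replacement[i]
    anchor <- contractions$anchor[i]
    if (identical(anchor, "literal")) {
      x <- gsub(pat, rep, x, fixed = TRUE)
    } else {
      esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", pat)
      rx <- if (identical(anchor, "word")) paste0("\\b", esc, "\\b")
            else paste0(esc, "\\b")
      x <- gsub(rx, rep, x, perl = TRUE)
    }
  }
  # hyphens and forward slashes become spaces
  x <- gsub("[-/]", " ", x)
  # hashtag marks and all remaining punctuation removed, tag text kept
  x <- gsub(paste0("[^a-z", .PH_MENTION, .PH_NUMBER, .PH_RT, " ]"), " ", x)
  # whitespace collapse
  x <- gsub("[[:space:]]+", " ", x)
  x <- trimws(x)
  # a leading "rt" can surface only now (e.g. "#rt ..."), so re-apply the
  # retweet rule for idempotence
  x <- sub("^rt\\b ?", paste0(.PH_RT, " "), x)
  x <- trimws(x)
  # runs of 3+ MENTION tokens reduce to exactly 2
  x <- gsub(paste0("(", .PH_MENTION, " )+", .PH_MENTION),
            paste0(.PH_MENTION, " ", .PH_MENTION), x)
  x <- gsub(paste0(.PH_MENTION, "( ", .PH_MENTION, ")+"),
            paste0(.PH_MENTION, " ", .PH_MENTION), x)
  # restore special tokens
  x <- gsub(.PH_MENTION, "MENTION", x, fixed = TRUE)
  x <- gsub(.PH_NUMBER, "NUMBER", x, fixed = TRUE)
  x <- gsub(.PH_RT, "RT", x, fixed = TRUE)
  x
}

#' Tokenize normalized text
#'
#' Splits normalized text on single spaces; special tokens are preserved as
#' single terms. Joining the tokens back with single spaces reproduces the
#' normalized text exactly.
#'
#' @param x Character vector of normalized texts.
#' @return A list of character vectors (one per element of `x`); an empty
#'   string yields `character(0)`.
#' @export
tokenize <- function(x) {
  out <- strsplit(as.character(x), " ", fixed = TRUE)
  lapply(out, function(t) t[nzchar(t)])
}

#' Normalize a message table
#'
#' Tidy wrapper over [normalize_text()] and [tokenize()]: takes a message
#' tibble and returns it with normalized text, a token list-column and
#' special-token counts.
#'
#' @param messages A data frame with at least columns `id` and `text`.
#' @param contractions Contraction table, see [riskmine_contractions()].
#' @return A tibble with the input columns plus `text_norm`, `tokens`
#'   (list-column), `n_number`, `n_mention`, `n_rt`.
#' @export
normalize_messages <- function(messages, contractions = riskmine_contractions()) {
  messages <- as_tibble(messages)
  if (!all(c("id", "text") %in% names(messages))) {
    data_error("`messages` must have columns `id` and `text`")
  }
  norm <- normalize_text(messages$text, contractions)
  toks <- tokenize(norm)
  messages %>%
    mutate(
      text_norm = norm,
      tokens = toks,
      n_number = purrr::map_int(toks, ~ sum(.x == "NUMBER")),
      n_mention = purrr::map_int(toks, ~ sum(.x == "MENTION")),
      n_rt = purrr::map_int(toks, ~ sum(.x == "RT"))
    )
}

#' Build a term vocabulary from a normalized corpus
#'
#' Terms are indexed deterministically: reserved tokens first (`<pad>` at 0,
#' `<oov>` at 1), then all terms with corpus frequency at least `min_count`
#' ordered by frequency (descending) and then lexicographically. The special
#' tokens `NUMBER`, `MENTION` and `RT` are always present.
#'
#' @param messages A normalized message tibble (see [normalize_messages()]) or
#'   a list/character vector of token vectors / normalized texts.
#' @param min_count Minimum corpus frequency for a term to be included.
#' @return A tibble with columns `term`, `index`, `frequency`.
#' @export
build_vocabulary <- function(messages, min_count = 1L) {
  toks <- extract_token_list(messages)
  if (length(toks) == 0) data_error("cannot build a vocabulary from an empty corpus")
  min_count <- assert_count(min_count, "min_count", min = 0L)
  all_tokens <- unlist(toks, use.names = FALSE)
  freq <- table(all_tokens)
  keep <- freq[freq >= min_count]
  terms <- names(keep)
  counts <- as.integer(keep)
  specials <- c("NUMBER", "MENTION", "RT")
  for (s in specials) {
    if (!s %in% terms) {
      terms <- c(terms, s)
      counts <- c(counts, if (s %in% names(freq)) as.integer(freq[[s]]) else 0L)
    }
  }
  ord <- order(-counts, terms)
  tibble(
    term = c("<pad>", "<oov>", terms[ord]),
    index = seq_len(length(terms) + 2L) - 1L,
    frequency = c(0L, 0L, counts[ord])
  )
}

# Accept the various corpus shapes the tidy API produces.
extract_token_list <- function(messages) {
  if (is.data.frame(messages)) {
    if ("tokens" %in% names(messages)) return(messages$tokens)
    if ("text_norm" %in% names(messages)) return(tokenize(messages$text_norm))
    data_error("message table has neither `tokens` nor `text_norm`")
  }
  if (is.list(messages)) return(messages)
  tokenize(messages)
}

#' Frequency odds ratio of terms across veracity classes
#'
#' For each term, computes the odds of a message containing the term in the
#' true-information class against the false-information class, with the
#' Haldane-Anscombe +0.5 correction applied to all four cells of the 2x2
#' table. Values above 1 mean the term is over-represented in true messages.
#'
#' @param messages Normalized message tibble with a `label` column coded
#'   `"true"` / `"false"` and a `tokens` list-column.
#' @param terms Character vector of terms to score; default all corpus terms.
#' @return A tibble with columns `term`, `n_true`, `n_false`, `odds_ratio`,
#'   sorted by descending odds ratio.
#' @export
frequency_odds_ratio <- function(messages, terms = NULL) {
  messages <- as_tibble(messages)
  if (!all(c("label", "tokens") %in% names(messages))) {
    data_error("`messages` must have `label` and `tokens` columns")
  }
  lab <- as.character(messages$label)
  if (!all(c("true", "false") %in% lab)) {
    data_error("both veracity classes must be present to compute an odds ratio")
  }
  token_sets <- lapply(messages$tokens, unique)
  corpus_terms <- unique(unlist(token_sets, use.names = FALSE))
  if (is.null(terms)) {
    terms <- sort(corpus_terms)
  } else if (!all(terms %in% corpus_terms)) {
    lookup_error(paste0("term(s) absent from corpus: ",
                        paste(setdiff(terms, corpus_terms), collapse = ", ")))
  }
  n_true_total <- sum(lab == "true")
  n_false_total <- sum(lab == "false")
  presence <- tibble(
    term = unlist(token_sets, use.names = FALSE),
    label = rep(lab, lengths(token_sets))
  )
  counts <- presence %>%
    filter(.data$term %in% terms) %>%
    count(.data$term, .data$label) %>%
    tidyr::pivot_wider(names_from = "label", values_from = "n",
                       values_fill = 0L)
  counts$true <- counts[["true"]] %||% 0L
  counts$false <- counts[["false"]] %||% 0L
  tibble(term = terms) %>%
    left_join(counts, by = "term") %>%
    mutate(
      n_true = .data$true %|NA|% 0L,
      n_false = .data$false %|NA|% 0L,
      odds_ratio = ((.data$n_true + 0.5) * (n_false_total - .data$n_false + 0.5)) /
        ((n_true_total - .data$n_true + 0.5) * (.data$n_false + 0.5))
    ) %>%
    select("term", "n_true", "n_false", "odds_ratio") %>%
    arrange(desc(.data$odds_ratio))
}

#' Read / write a vocabulary as TSV
#'
#' @param vocabulary A vocabulary tibble from [build_vocabulary()].
#' @param path File path.
#' @return `read_vocabulary()` returns the vocabulary tibble.
#' @export
write_vocabulary <- function(vocabulary, path) {
  readr::write_tsv(vocabulary, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  readr::read_tsv(path, col_types = "cii", progress = FALSE)
}
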