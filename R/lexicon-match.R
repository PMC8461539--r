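# Validation of mined effects against a gold risk-perception lexicon.
#
# Phrases are compared as normalized, stopword-free term sets. A single
# (gold, candidate) comparison is exclusive under the precedence
# exact > proper > reverse > partial; across candidates a gold phrase can
# accumulate several match types, which is what the aggregate coverage
# statistics count.

#' Reduce a phrase to its comparison term set
#'
#' Lower-cases, splits on spaces and underscores, removes stopwords and
#' optionally applies a light suffix stemmer (strips "ing", "ed" and a
#' plural "s"). Used by [classify_match()] and [match_statistics()].
#'
#' @param phrase Phrase string (space- or underscore-separated) or character
#'   vector of terms.
#' @param stopwords Stopword list.
#' @param stem Apply the light suffix stemmer (default off).
#' @return Character vector (a term set, duplicates removed).
#' @export
phrase_term_set <- function(phrase, stopwords = riskmine_stopwords(),
                            stem = FALSE) {
  terms <- if (length(phrase) > 1) phrase else phrase_tokens(tolower(phrase))
  terms <- tolower(terms)
  terms <- terms[nzchar(terms) & !terms %in% stopwords]
  if (stem) {
    terms <- sub("ing$", "", terms)
    terms <- sub("ed$", "", terms)
    terms <- sub("(?<![su])s$", "", terms, perl = TRUE)
  }
  unique(terms)
}

#' Classify the match type of a (gold, candidate) phrase pair
#'
#' With `g` and `e` the stopword-free term sets of the gold and candidate
#' effect phrase: `exact` if the sets are equal; `proper` if the candidate
#' is a strictly more specific form of the gold phrase (`g` a strict subset
#' of `e`, as in mined "early onset menopause" against gold "menopause");
#' `reverse` if the candidate is a strictly more general form (`e` a strict
#' subset of `g`, mined "fatigue" against gold "extreme fatigue");
#' `partial` if the sets merely intersect (mined "prevent throat cancer"
#' against gold "prevent cervical cancer"); otherwise `none`. The
#' precedence exact > proper > reverse > partial makes the result exclusive
#' per pair.
#'
#' @param g Gold phrase (string or character vector of terms).
#' @param e Candidate effect phrase (string or character vector of terms).
#' @param stopwords Stopword list used to reduce both phrases.
#' @param stem Apply the light suffix stemmer before comparison.
#' @return One of `"exact"`, `"proper"`, `"reverse"`, `"partial"`, `"none"`.
#' @export
#' @examples
#' classify_match("menopause", "early onset menopause")   # proper
#' classify_match("extreme fatigue", "fatigue")           # reverse
classify_match <- function(g, e, stopwords = riskmine_stopwords(),
                           stem = FALSE) {
  gs <- phrase_term_set(g, stopwords, stem)
  es <- phrase_term_set(e, stopwords, stem)
  if (length(gs) == 0 || length(es) == 0) {
    data_error("cannot classify a match for an empty phrase")
  }
  if (setequal(gs, es)) return("exact")
  if (all(gs %in% es)) return("proper")
  if (all(es %in% gs)) return("reverse")
  if (length(intersect(gs, es)) > 0) return("partial")
  "none"
}

#' Match coverage statistics of candidate effects against a gold lexicon
#'
#' Classifies every (gold, candidate) pair and aggregates per gold phrase:
#' a gold phrase counts towards match type X if any candidate achieves X
#' against it, so one gold phrase can appear in several type tallies (the
#' per-pair classification stays exclusive). Percentages are over the
#' number of gold phrases; the union row counts gold phrases with a partial
#' or a proper match (or both).
#'
#' @param gold Gold lexicon tibble with columns `phrase` and `category`
#'   (e.g. from [generate_gold_lexicon()] or [read_gold_lexicon()]).
#' @param candidates Character vector of candidate effect phrases
#'   (underscore- or space-separated), e.g. collapsed representatives.
#' @param stopwords Stopword list.
#' @param stem Apply the light suffix stemmer before comparison.
#' @return An object of class `match_report`: a list with `per_gold`
#'   (tibble: `phrase`, `category`, logical columns per type, `best`) and
#'   `summary` (tibble: `match_type`, `n`, `percent`).
#' @export
match_statistics <- function(gold, candidates,
                             stopwords = riskmine_stopwords(), stem = FALSE) {
  gold <- as_tibble(gold)
  if (!all(c("phrase", "category") %in% names(gold)) || nrow(gold) == 0) {
    data_error("`gold` must be a nonempty tibble with `phrase` and `category`")
  }
  candidates <- unique(as.character(candidates))
  if (length(candidates) == 0) {
    warn("empty candidate set: reporting zero coverage")
  }
  types <- c("exact", "proper", "reverse", "partial")
  per_gold <- gold %>%
    mutate(achieved = purrr::map(.data$phrase, function(g) {
      if (length(candidates) == 0) return(character(0))
      unique(vapply(candidates, classify_match, character(1),
                    g = g, stopwords = stopwords, stem = stem))
    }))
  for (t in types) {
    per_gold[[t]] <- purrr::map_lgl(per_gold$achieved, ~ t %in% .x)
  }
  per_gold <- per_gold %>%
    mutate(
      partial_or_proper = .data$partial | .data$proper,
      best = purrr::map_chr(.data$achieved, function(a) {
        hit <- types[types %in% a]
        if (length(hit) == 0) "none" else hit[1]
      })
    ) %>%
    select(-"achieved")
  n_gold <- nrow(per_gold)
  summary <- tibble(
    match_type = c(types, "partial_or_proper"),
    n = unname(vapply(c(types, "partial_or_proper"),
                      function(t) sum(per_gold[[t]]), integer(1)))
  ) %>%
    mutate(percent = round(100 * .data$n / n_gold, 1))
  structure(list(per_gold = per_gold, summary = summary, n_gold = n_gold,
                 n_candidates = length(candidates)),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat("<match_report> ", x$n_gold, " gold phrases vs ", x$n_candidates,
      " candidate effects\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Read / write a gold lexicon as CSV
#'
#' CSV with header `phrase,category` (extra columns are preserved on read).
#'
#' @param gold Gold lexicon tibble.
#' @param path File path.
#' @param keep_extra Also write columns beyond `phrase` and `category`.
#' @return `read_gold_lexicon()` returns the gold lexicon tibble.
#' @export
write_gold_lexicon <- function(gold, path, keep_extra = FALSE) {
  out <- if (keep_extra) gold else gold[, c("phrase", "category")]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_gold_lexicon
#' @export
read_gold_lexicon <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("phrase", "category") %in% names(out))) {
    data_error("gold lexicon CSV must have columns `phrase` and `category`")
  }
  out
}

#' Write a match report
#'
#' Writes the aggregate coverage as JSON and the per-gold-phrase table as
#' TSV at `<path>.json` / `<path>.tsv`.
#'
#' @param report A `match_report`.
#' @param path Path prefix (no extension).
#' @export
write_match_report <- function(report, path) {
  jsonlite::write_json(
    list(n_gold = report$n_gold, n_candidates = report$n_candidates,
         summary = report$summary),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  readr::write_tsv(report$per_gold, paste0(path, ".tsv"), progress = FALSE)
  invisible(path)
}
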