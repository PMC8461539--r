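#' English stopword list
#'
#' A compact English stopword list (Snowball-style function words) used when
#' building cause/effect phrase vocabularies and when comparing phrases to a
#' gold lexicon. Exposed so analyses can extend or replace it.
#'
#' @return A character vector of lower-case stopwords.
#' @export
#' @examples
#' head(riskmine_stopwords())
riskmine_stopwords <- function() {
  c(
    "i", "me", "my", "myself", "we", "our", "ours", "ourselves", "you",
    "your", "yours", "yourself", "yourselves", "he", "him", "his", "himself",
    "she", "her", "hers", "herself", "it", "its", "itself", "they", "them",
    "their", "theirs", "themselves", "what", "which", "who", "whom", "this",
    "that", "these", "those", "am", "is", "are", "was", "were", "be", "been",
    "being", "have", "has", "had", "having", "do", "does", "did", "doing",
    "a", "an", "the", "and", "but", "if", "or", "because", "as", "until",
    "while", "of", "at", "by", "for", "with", "about", "against", "between",
    "into", "through", "during", "before", "after", "above", "below", "to",
    "from", "up", "down", "in", "out", "on", "off", "over", "under", "again",
    "further", "then", "once", "here", "there", "when", "where", "why",
    "how", "all", "any", "both", "each", "few", "more", "most", "other",
    "some", "such", "no", "nor", "not", "only", "own", "same", "so", "than",
    "too", "very", "s", "t", "can", "cannot", "will", "just", "don", "should",
    "now", "would", "could", "may", "might", "must", "shall", "rt"
  )
}

#' Default causal-cue lexicon
#'
#' A small dictionary of lexical markers that signal a cause-effect assertion
#' in informal short text ("causes", "leads to", "due to", ...). It is a
#' user-replaceable stand-in: pass your own lexicon wherever a `cues` argument
#' appears, or load one from a plain-text file with [read_cue_lexicon()].
#'
#' @return A character vector of lower-case cue expressions (single- or
#'   multi-word), longest first.
#' @export
#' @examples
#' default_cue_lexicon()
default_cue_lexicon <- function() {
  cues <- c(
    "cause", "causes", "caused", "causing",
    "lead to", "leads to", "led to",
    "result in", "results in", "resulted in",
    "due to", "because of", "because",
    "linked to", "associated with",
    "prevent", "prevents", "prevented",
    "trigger", "triggers", "triggered"
  )
  validate_cue_lexicon(cues)
}

validate_cue_lexicon <- function(cues) {
  if (length(cues) == 0) config_error("cue lexicon must be nonempty")
  cues <- tolower(trimws(cues))
  cues <- cues[nzchar(cues)]
  if (anyDuplicated(cues)) cues <- unique(cues)
  # longest-first so multi-word cues win over their sub-expressions
  cues[order(-lengths(strsplit(cues, " ", fixed = TRUE)), -nchar(cues), cues)]
}

#' Read / write a causal-cue lexicon
#'
#' Plain-text format: one cue expression per line, `#` starts a comment.
#'
#' @param path File path.
#' @return `read_cue_lexicon()` returns a character vector of cues
#'   (lower-case, de-duplicated, longest first).
#' @export
read_cue_lexicon <- function(path) {
  lines <- readr::read_lines(path)
  lines <- trimws(sub("#.*$", "", lines))
  validate_cue_lexicon(lines[nzchar(lines)])
}

#' @rdname read_cue_lexicon
#' @param cues Character vector of cue expressions.
#' @export
write_cue_lexicon <- function(cues, path) {
  readr::write_lines(validate_cue_lexicon(cues), path)
  invisible(path)
}
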