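# JSON Lines I/O for message corpora.

#' Read / write a message corpus as JSON Lines
#'
#' One object per line: `{"id": str, "text": str, "label": "true" | "false"
#' | null}`. Extra scalar columns present in the tibble (provenance flags
#' from the generator, normalized text) are written too and restored on
#' read; list-columns (tokens, term sets) are not persisted here.
#'
#' @param messages Message tibble with at least `id` and `text`.
#' @param path File path.
#' @param keep_extra Write columns beyond `id`, `text`, `label`.
#' @return `read_messages_jsonl()` returns a message tibble.
#' @export
write_messages_jsonl <- function(messages, path, keep_extra = TRUE) {
  messages <- as_tibble(messages)
  core <- intersect(c("id", "text", "label"), names(messages))
  extra <- if (keep_extra) {
    scalar <- names(messages)[!vapply(messages, is.list, logical(1))]
    setdiff(intersect(names(messages), scalar), core)
  } else character(0)
  cols <- messages[, c(core, extra), drop = FALSE]
  lines <- vapply(seq_len(nrow(cols)), function(i) {
    row <- as.list(cols[i, , drop = FALSE])
    jsonlite::toJSON(row, auto_unbox = TRUE, null = "null", na = "null")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' @rdname write_messages_jsonl
#' @export
read_messages_jsonl <- function(path) {
  lines <- readr::read_lines(path)
  if (length(lines) == 0) {
    return(tibble(id = character(), text = character(), label = character()))
  }
  rows <- purrr::map(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    x <- lapply(x, function(v) {
      if (is.null(v)) NA else if (length(v) > 1) list(v) else v
    })
    as_tibble(x)
  })
  bind_rows(rows)
}
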