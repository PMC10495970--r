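# Rule-based sentence splitting and paragraph deduplication.
#
# The splitter is deliberately self-contained (no external NLP toolkit) so
# that its behaviour is fully specified and testable: a boundary is a
# sentence-terminal character (. ! ?) at parenthesis depth zero, followed by
# whitespace and an uppercase letter or digit, and whose preceding token is
# not a guarded abbreviation.

default_abbreviations <- function() {
  c("e.g.", "i.e.", "etc.", "ca.", "approx.", "vs.", "cf.", "fig.",
    "no.", "ref.", "al.", "wt.", "aq.", "sat.", "conc.", "equiv.", "eq.")
}

#' Split a paragraph into sentences
#'
#' @param paragraph A single non-empty string.
#' @param abbreviations Character vector of abbreviations (with trailing
#'   period) that never end a sentence.
#' @return A list of class \code{sentence_split} with \code{sentences}
#'   (character vector) and \code{spans} (integer matrix of 0-based
#'   half-open \code{[start, end)} character offsets into the paragraph,
#'   one row per sentence).
#' @export
#' @examples
#' split_sentences("The solution was stirred. The mixture was filtered.")
split_sentences <- function(paragraph, abbreviations = default_abbreviations()) {
  if (!is.character(paragraph) || length(paragraph) != 1 ||
      !nzchar(trimws(paragraph)))
    stop_chemactions("empty_input", "empty paragraph")
  chars <- strsplit(paragraph, "", fixed = TRUE)[[1]]
  n <- length(chars)
  depth <- cumsum((chars == "(" | chars == "[") - (chars == ")" | chars == "]"))
  abbr <- tolower(abbreviations)

  boundaries <- integer(0)
  for (i in seq_len(n)) {
    if (!(chars[i] %in% c(".", "!", "?"))) next
    if (depth[i] != 0) next
    # allow a closing quote straight after the terminal mark
    j <- i
    if (j < n && chars[j + 1] %in% c("\"", "'")) j <- j + 1
    if (j >= n) { boundaries <- c(boundaries, j); next }
    if (!grepl("[[:space:]]", chars[j + 1])) next
    k <- j + 1
    while (k <= n && grepl("[[:space:]]", chars[k])) k <- k + 1
    # an opening quote may precede the capital of the next sentence
    if (k < n && chars[k] %in% c("\"", "'")) k <- k + 1
    if (k > n || !grepl("[A-Z0-9]", chars[k])) next
    # preceding token (incl. the period) must not be a guarded abbreviation
    s <- i - 1
    while (s >= 1 && !grepl("[[:space:]]", chars[s])) s <- s - 1
    token <- tolower(paste(chars[(s + 1):i], collapse = ""))
    if (token %in% abbr) next
    boundaries <- c(boundaries, j)
  }
  if (!length(boundaries) || boundaries[length(boundaries)] < n) {
    # trailing text without a terminal mark forms the final sentence
    boundaries <- c(boundaries, n)
  }

  starts <- integer(0); ends <- integer(0); sentences <- character(0)
  prev <- 0L
  for (b in boundaries) {
    st <- prev + 1L
    while (st <= b && grepl("[[:space:]]", chars[st])) st <- st + 1L
    if (st > b) { prev <- b; next }
    sentences <- c(sentences, paste(chars[st:b], collapse = ""))
    starts <- c(starts, st - 1L)   # 0-based
    ends <- c(ends, b)             # half-open
    prev <- b
  }
  structure(list(sentences = sentences,
                 spans = cbind(start = starts, end = ends)),
            class = "sentence_split")
}

#' Remove duplicate paragraphs
#'
#' Duplicate key is the normalized paragraph text (lowercased, whitespace
#' collapsed); the first occurrence is kept.
#'
#' @param records A list of \code{\link{paragraph_record}} objects or a
#'   character vector of paragraphs.
#' @return The deduplicated input, same type as supplied.
#' @export
dedupe_records <- function(records) {
  if (is.character(records)) {
    keys <- tolower(vapply(records, squish, character(1), USE.NAMES = FALSE))
    return(records[!duplicated(keys)])
  }
  texts <- vapply(records, function(r) r$text, character(1))
  keys <- tolower(vapply(texts, squish, character(1), USE.NAMES = FALSE))
  records[!duplicated(keys)]
}
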