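# Structured-action language: types, grammar, parser, serializer.
#
# A structured procedure string is a ";"-separated list of clauses with a
# single trailing period.  Each clause starts with one of 28 action keywords
# (uppercase in canonical form) followed by an action-specific payload and
# optional trailing "at <temperature>" and "for <duration>" modifiers, in
# that canonical order.  The normative EBNF lives in
# inst/extdata/grammar.ebnf and in the methods vignette.

#' The 28 action types of the structured procedure language
#'
#' Returns the canonical table of action types: the CamelCase name, the
#' uppercase surface keyword used in serialized strings, and the payload
#' class that fixes each action's clause grammar.
#'
#' Payload classes:
#' \describe{
#'   \item{item}{a single chemical item (\code{ADD}, \code{YIELD}); the
#'     reserved token \code{SLN} back-references the solution made by a
#'     preceding \code{MAKESOLUTION} clause.}
#'   \item{withlist}{\code{with} + one or more items joined by \code{and}.}
#'   \item{keep}{\code{keep} + an enumerated phase
#'     (\code{FILTER}: precipitate/filtrate;
#'     \code{COLLECTLAYER}: organic/aqueous).}
#'   \item{purify}{\code{":"} + a \code{":"}-separated solvent list with an
#'     optional trailing numeric ratio such as \code{1:1}.}
#'   \item{temp}{a temperature text (\code{SETTEMPERATURE}).}
#'   \item{free}{free parameter text (\code{PH}).}
#'   \item{bare}{no payload.}
#' }
#'
#' @return A data.frame with columns \code{name}, \code{keyword},
#'   \code{payload}.
#' @export
#' @examples
#' nrow(action_types())  # 28
action_types <- function() {
  def <- c(
    Add                  = "item",
    CollectLayer         = "keep",
    Concentrate          = "bare",
    Degas                = "bare",
    DrySolid             = "bare",
    DrySolution          = "withlist",
    Extract              = "withlist",
    Filter               = "keep",
    FollowOtherProcedure = "bare",
    MakeSolution         = "withlist",
    Microwave            = "bare",
    OtherLanguage        = "bare",
    Partition            = "withlist",
    PH                   = "free",
    PhaseSeparation      = "bare",
    InvalidAction        = "bare",
    Purify               = "purify",
    Quench               = "withlist",
    Recrystallize        = "withlist",
    NoAction             = "bare",
    Reflux               = "bare",
    SetTemperature       = "temp",
    Sonicate             = "bare",
    Stir                 = "bare",
    Triturate            = "withlist",
    Wait                 = "bare",
    Wash                 = "withlist",
    Yield                = "item"
  )
  data.frame(
    name = names(def),
    keyword = toupper(names(def)),
    payload = unname(def),
    stringsAsFactors = FALSE
  )
}

.action_table <- NULL

action_table <- function() {
  # memoised copy; cheap but called in inner loops
  tab <- getOption("chemactions.action_table")
  if (is.null(tab)) {
    tab <- action_types()
    options(chemactions.action_table = tab)
  }
  tab
}

keep_phases <- list(
  Filter = c("precipitate", "filtrate"),
  CollectLayer = c("organic", "aqueous")
)

# ---- conditions ------------------------------------------------------------

stop_chemactions <- function(subclass, message, ...) {
  cond <- structure(
    class = c(paste0("chemactions_error_", subclass), "chemactions_error",
              "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

# ---- constructors ----------------------------------------------------------

#' Create a chemical mention
#'
#' @param name Free-text chemical name (IUPAC or trivial), preserved
#'   verbatim.  Must be non-empty unless \code{is_solution_ref}.
#' @param amount Optional free-text quantity with units (e.g. "200 mg"),
#'   preserved verbatim.
#' @param is_solution_ref \code{TRUE} for the reserved \code{SLN} token that
#'   back-references a solution made earlier in the sequence.
#' @return An object of class \code{chemical_mention}.
#' @export
chemical_mention <- function(name = "", amount = NULL, is_solution_ref = FALSE) {
  if (!is_solution_ref && (!is.character(name) || !nzchar(name)))
    stop_chemactions("invalid_sequence", "chemical name must be non-empty")
  structure(
    list(name = if (is_solution_ref) "SLN" else name,
         amount = amount, is_solution_ref = is_solution_ref),
    class = "chemical_mention"
  )
}

#' Create an action clause
#'
#' @param action Action name (CamelCase, one of \code{action_types()$name}).
#' @param chemicals List of \code{\link{chemical_mention}} objects.
#' @param temperature,duration Optional free-text modifiers.
#' @param keep_phase Phase kept by \code{Filter}/\code{CollectLayer}.
#' @param purify_solvents Character vector of solvents (\code{Purify} only).
#' @param purify_ratio Optional ratio text such as \code{"1:1"}.
#' @param free_params Residual parameter text not captured by a named slot.
#' @return An object of class \code{action_clause}.
#' @export
action_clause <- function(action, chemicals = list(), temperature = NULL,
                          duration = NULL, keep_phase = NULL,
                          purify_solvents = NULL, purify_ratio = NULL,
                          free_params = NULL) {
  if (!action %in% action_table()$name)
    stop_chemactions("unknown_action", sprintf("unknown action '%s'", action))
  structure(
    list(action = action, chemicals = chemicals, temperature = temperature,
         duration = duration, keep_phase = keep_phase,
         purify_solvents = purify_solvents, purify_ratio = purify_ratio,
         free_params = free_params),
    class = "action_clause"
  )
}

#' Create an action sequence
#'
#' @param clauses List of \code{\link{action_clause}} objects, in order.
#' @param source_sentence Optional originating free-text sentence.
#' @return An object of class \code{action_sequence}.
#' @export
action_sequence <- function(clauses = list(), source_sentence = NULL) {
  structure(list(clauses = clauses, source_sentence = source_sentence),
            class = "action_sequence")
}

#' @export
print.action_sequence <- function(x, ...) {
  cat("<action_sequence> ", length(x$clauses), " clause(s)\n", sep = "")
  cat("  ", serialize_actions(x), "\n", sep = "")
  invisible(x)
}

#' @export
print.action_clause <- function(x, ...) {
  cat("<action_clause> ", serialize_clause(x), "\n", sep = "")
  invisible(x)
}

# ---- small string helpers --------------------------------------------------

squish <- function(x) {
  x <- gsub("[[:space:]]+", " ", x)
  sub("^ ", "", sub(" $", "", x))
}

# Split on a literal separator only at parenthesis depth 0.
split_top_level <- function(x, sep = " and ") {
  if (!nzchar(x)) return(character(0))
  hits <- gregexpr(sep, x, fixed = TRUE)[[1]]
  if (hits[1] == -1) return(x)
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  keep <- hits[depth[hits] == 0]
  if (!length(keep)) return(x)
  starts <- c(1L, keep + nchar(sep))
  ends <- c(keep - 1L, nchar(x))
  vapply(seq_along(starts),
         function(i) substr(x, starts[i], ends[i]), character(1))
}

amount_like <- function(txt) {
  # quantities: "200 mg", "10 mL", "ca. 5 g", "2 x 50 mL", "0.5 equiv"
  grepl("^(ca\\.\\s*|about\\s+|~\\s*|>\\s*|<\\s*)?\\d", txt)
}

temperature_like <- function(txt) {
  grepl("^(-?\\d|rt\\b|r\\.t\\.|room temperature|ambient|reflux|ice)",
        txt, ignore.case = TRUE)
}

duration_like <- function(txt) {
  grepl("^(about\\s+|~\\s*|ca\\.\\s*)?(\\d|overnight\\b|several\\b|a few\\b)",
        txt, ignore.case = TRUE)
}

# ---- item parsing ----------------------------------------------------------

parse_item <- function(txt, strict) {
  txt <- squish(txt)
  if (!nzchar(txt))
    return(NULL)
  if (txt == "SLN")
    return(chemical_mention(is_solution_ref = TRUE))
  # the amount must be space-separated: "EDC (374 mg)" splits,
  # "tetrakis(triphenylphosphine)palladium(0)" stays one name
  m <- regmatches(txt, regexec("^(.*?)\\s+\\(([^()]*)\\)$", txt))[[1]]
  if (length(m) == 3 && nzchar(m[2]) && amount_like(m[3]))
    return(chemical_mention(name = m[2], amount = m[3]))
  chemical_mention(name = txt)
}

serialize_item <- function(chem) {
  if (isTRUE(chem$is_solution_ref)) return("SLN")
  if (!is.null(chem$amount)) paste0(chem$name, " (", chem$amount, ")")
  else chem$name
}

# ---- clause parsing --------------------------------------------------------

strip_modifiers <- function(payload) {
  temperature <- NULL; duration <- NULL
  # canonical order is "... at <temp> for <dur>"; strip from the right;
  # the prefix may be empty (the whole payload can be a modifier)
  m <- regmatches(payload, regexec("^(?:(.*\\S)\\s+)?for\\s+(\\S.*)$", payload))[[1]]
  if (length(m) == 3 && duration_like(m[3])) {
    payload <- m[2]; duration <- m[3]
  }
  m <- regmatches(payload, regexec("^(?:(.*\\S)\\s+)?at\\s+(\\S.*)$", payload))[[1]]
  if (length(m) == 3 && temperature_like(m[3])) {
    payload <- m[2]; temperature <- m[3]
  }
  list(payload = payload, temperature = temperature, duration = duration)
}

parse_clause <- function(segment, strict) {
  segment <- squish(segment)
  m <- regmatches(segment, regexec("^([A-Za-z]+)\\s*(:?)\\s*(.*)$", segment))[[1]]
  kw <- if (length(m) >= 2) m[2] else ""
  tab <- action_table()
  idx <- match(toupper(kw), tab$keyword)
  if (!nzchar(kw) || is.na(idx)) {
    if (strict)
      stop_chemactions("unknown_action",
                       sprintf("unknown action keyword in clause '%s'", segment))
    return(action_clause("InvalidAction", free_params = segment))
  }
  name <- tab$name[idx]
  ptype <- tab$payload[idx]
  has_colon <- m[3] == ":"
  payload <- m[4]

  if (has_colon && ptype != "purify") {
    if (strict)
      stop_chemactions("malformed_clause",
                       sprintf("unexpected ':' after %s", tab$keyword[idx]))
    return(action_clause("InvalidAction", free_params = segment))
  }

  malformed <- function(msg) {
    if (strict) stop_chemactions("malformed_clause",
                                 sprintf("%s in clause '%s'", msg, segment))
    action_clause("InvalidAction", free_params = segment)
  }

  if (ptype == "purify") {
    if (!has_colon && nzchar(payload)) return(malformed("PURIFY requires ':'"))
    mods <- strip_modifiers(payload)
    body <- squish(mods$payload)
    ratio <- NULL
    rm_ <- regmatches(body, regexec("^(.*\\S)\\s+(\\d+(?:\\.\\d+)?(?::\\d+(?:\\.\\d+)?)+)$",
                                    body))[[1]]
    if (length(rm_) == 3) { body <- rm_[2]; ratio <- rm_[3] }
    solvents <- vapply(strsplit(body, ":", fixed = TRUE)[[1]], squish, character(1),
                       USE.NAMES = FALSE)
    solvents <- solvents[nzchar(solvents)]
    if (!length(solvents) && nzchar(body)) return(malformed("empty solvent list"))
    return(action_clause(name, purify_solvents = solvents, purify_ratio = ratio,
                         temperature = mods$temperature, duration = mods$duration))
  }

  mods <- strip_modifiers(payload)
  payload <- squish(mods$payload)

  cl <- switch(ptype,
    bare = {
      if (nzchar(payload)) return(malformed("unexpected payload for bare action"))
      action_clause(name)
    },
    item = {
      if (!nzchar(payload)) return(malformed("missing item"))
      action_clause(name, chemicals = list(parse_item(payload, strict)))
    },
    withlist = {
      wm <- regmatches(payload, regexec("^[Ww]ith\\s+(\\S.*)$", payload))[[1]]
      if (length(wm) != 2) return(malformed("expected 'with <item list>'"))
      parts <- split_top_level(wm[2], " and ")
      chems <- lapply(parts, parse_item, strict = strict)
      chems <- chems[!vapply(chems, is.null, logical(1))]
      if (!length(chems)) return(malformed("empty item list"))
      action_clause(name, chemicals = chems)
    },
    keep = {
      km <- regmatches(payload, regexec("^[Kk]eep\\s+(\\S+)$", payload))[[1]]
      if (length(km) != 2) return(malformed("expected 'keep <phase>'"))
      phase <- tolower(km[2])
      if (!phase %in% keep_phases[[name]])
        return(malformed(sprintf("phase '%s' not allowed for %s", phase, name)))
      action_clause(name, keep_phase = phase)
    },
    temp = {
      if (!nzchar(payload)) return(malformed("missing temperature"))
      action_clause(name, temperature = payload)
    },
    free = {
      action_clause(name, free_params = if (nzchar(payload)) payload else NULL)
    }
  )
  cl$temperature <- cl$temperature %||% mods$temperature
  cl$duration <- cl$duration %||% mods$duration
  cl
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse a structured procedure string
#'
#' Splits the input on \code{";"}, parses each non-empty segment as one
#' action clause, and returns an \code{\link{action_sequence}}.  In
#' \code{strict} mode unknown action keywords and payloads that violate the
#' action's grammar raise errors; in \code{lenient} mode such segments map to
#' \code{InvalidAction} clauses that keep the raw text in \code{free_params}.
#'
#' @param text A structured-format string, e.g.
#'   \code{"ADD Ethanol; FILTER keep precipitate."}.
#' @param mode \code{"strict"} or \code{"lenient"}.
#' @return An \code{\link{action_sequence}}.
#' @export
#' @examples
#' seq <- parse_structured("ADD Ethanol; ADD water; FILTER keep precipitate.")
#' length(seq$clauses)
parse_structured <- function(text, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  strict <- mode == "strict"
  if (!is.character(text) || length(text) != 1 || !nzchar(squish(text)))
    stop_chemactions("empty_input", "empty structured string")
  body <- squish(text)
  body <- sub("\\.$", "", body)
  segments <- strsplit(body, ";", fixed = TRUE)[[1]]
  segments <- vapply(segments, squish, character(1), USE.NAMES = FALSE)
  segments <- segments[nzchar(segments)]
  if (!length(segments))
    stop_chemactions("empty_input", "no clauses in structured string")
  action_sequence(clauses = lapply(segments, parse_clause, strict = strict))
}

# ---- serialization ---------------------------------------------------------

serialize_clause <- function(cl) {
  tab <- action_table()
  idx <- match(cl$action, tab$name)
  kw <- tab$keyword[idx]
  ptype <- tab$payload[idx]
  body <- switch(ptype,
    bare = kw,
    item = paste0(kw, " ", serialize_item(cl$chemicals[[1]])),
    withlist = paste0(kw, " with ",
                      paste(vapply(cl$chemicals, serialize_item, character(1)),
                            collapse = " and ")),
    keep = paste0(kw, " keep ", cl$keep_phase),
    purify = paste0(kw, ": ", paste(cl$purify_solvents, collapse = ":"),
                    if (!is.null(cl$purify_ratio)) paste0(" ", cl$purify_ratio) else ""),
    temp = paste0(kw, " ", cl$temperature),
    free = if (is.null(cl$free_params)) kw else paste0(kw, " ", cl$free_params)
  )
  if (ptype != "temp" && !is.null(cl$temperature))
    body <- paste0(body, " at ", cl$temperature)
  if (!is.null(cl$duration))
    body <- paste0(body, " for ", cl$duration)
  body
}

#' Serialize an action sequence to the structured format
#'
#' Clauses are joined by \code{"; "} and the string is terminated with a
#' single period.  Action keywords are emitted in canonical uppercase;
#' chemical names and amounts are preserved verbatim.  For every
#' grammar-conforming string \code{s},
#' \code{serialize_actions(parse_structured(s)) == normalize_structured(s)}.
#'
#' @param seq An \code{\link{action_sequence}}.
#' @return A single string.
#' @export
serialize_actions <- function(seq) {
  viol <- validate_actions(seq)
  if (length(viol))
    stop_chemactions("invalid_sequence",
                     paste0("invalid action sequence: ", viol[1]))
  paste0(paste(vapply(seq$clauses, serialize_clause, character(1)),
               collapse = "; "), ".")
}

#' Normalize a structured string
#'
#' Collapses internal whitespace, trims clause segments, uppercases action
#' keywords, and ensures a single trailing period.  This is the normal form
#' produced by \code{\link{serialize_actions}}.
#'
#' @param text A structured-format string.
#' @return The normalized string.
#' @export
normalize_structured <- function(text) {
  body <- squish(text)
  body <- sub("\\.$", "", body)
  segments <- strsplit(body, ";", fixed = TRUE)[[1]]
  segments <- vapply(segments, squish, character(1), USE.NAMES = FALSE)
  segments <- segments[nzchar(segments)]
  tab <- action_table()
  segments <- vapply(segments, function(seg) {
    m <- regmatches(seg, regexec("^([A-Za-z]+)(.*)$", seg))[[1]]
    if (length(m) == 3 && toupper(m[2]) %in% tab$keyword)
      paste0(toupper(m[2]), m[3])
    else seg
  }, character(1), USE.NAMES = FALSE)
  paste0(paste(segments, collapse = "; "), ".")
}

# ---- validation ------------------------------------------------------------

#' Validate an action sequence against the type invariants
#'
#' Total function: returns a character vector of violations (empty when the
#' sequence is well formed).  Each violation names the clause index and the
#' violated rule.
#'
#' @param seq An \code{\link{action_sequence}}.
#' @return Character vector of violation messages.
#' @export
validate_actions <- function(seq) {
  if (!inherits(seq, "action_sequence"))
    return("not an action_sequence")
  v <- character(0)
  add <- function(i, msg) sprintf("clause %d: %s", i, msg)
  if (!length(seq$clauses))
    return("sequence has no clauses")
  tab <- action_table()
  for (i in seq_along(seq$clauses)) {
    cl <- seq$clauses[[i]]
    if (!inherits(cl, "action_clause")) { v <- c(v, add(i, "not an action_clause")); next }
    idx <- match(cl$action, tab$name)
    if (is.na(idx)) { v <- c(v, add(i, "unknown action")); next }
    ptype <- tab$payload[idx]
    if (!is.null(cl$keep_phase)) {
      if (!cl$action %in% names(keep_phases))
        v <- c(v, add(i, "keep_phase only allowed for Filter/CollectLayer"))
      else if (!cl$keep_phase %in% keep_phases[[cl$action]])
        v <- c(v, add(i, sprintf("keep_phase '%s' not allowed for %s",
                                 cl$keep_phase, cl$action)))
    }
    if (ptype == "keep" && is.null(cl$keep_phase))
      v <- c(v, add(i, sprintf("%s requires keep_phase", cl$action)))
    if (!is.null(cl$purify_solvents) && cl$action != "Purify")
      v <- c(v, add(i, "purify_solvents only allowed for Purify"))
    if (ptype == "purify" && !length(cl$purify_solvents))
      v <- c(v, add(i, "Purify requires a solvent list"))
    if (ptype %in% c("item", "withlist")) {
      if (!length(cl$chemicals))
        v <- c(v, add(i, sprintf("%s requires chemicals", cl$action)))
      if (ptype == "item" && length(cl$chemicals) > 1)
        v <- c(v, add(i, sprintf("%s takes a single item", cl$action)))
    }
    if (ptype == "bare" && length(cl$chemicals))
      v <- c(v, add(i, sprintf("%s takes no chemicals", cl$action)))
    if (ptype == "temp" && is.null(cl$temperature))
      v <- c(v, add(i, "SetTemperature requires a temperature"))
    for (ch in cl$chemicals) {
      if (!inherits(ch, "chemical_mention") ||
          (!isTRUE(ch$is_solution_ref) && !nzchar(ch$name)))
        v <- c(v, add(i, "chemical name must be non-empty"))
    }
  }
  v
}
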