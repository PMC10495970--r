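# Admission rules deciding whether a paragraph is a well-formed organic
# synthesis procedure.  Five rules:
#   R1  at least `min_words` whitespace tokens
#   R2  does not end abruptly (terminal punctuation required)
#   R3  no reference to other methods/procedures
#   R4  no bare compound references ("Compound 1", "INTERMEDIATE 2", ...)
#   R5  product euphemisms ("title compound", "white solid", ...) only
#       allowed when a proper IUPAC-like name occurs in the same sentence

#' Create a paragraph record
#'
#' @param id Opaque identifier.
#' @param text Paragraph text (non-null).
#' @param label Optional binary label (1 = synthesis procedure, 0 = other).
#' @param violations Character vector of admission-rule codes.
#' @return An object of class \code{paragraph_record}.
#' @export
paragraph_record <- function(id, text, label = NULL, violations = character(0)) {
  stopifnot(is.character(text), length(text) == 1)
  if (!is.null(label) && !label %in% c(0, 1))
    stop_chemactions("invalid_sequence", "label must be 0 or 1")
  structure(list(id = id, text = text, label = label, violations = violations),
            class = "paragraph_record")
}

#' Configuration for the admission rules
#'
#' Defaults seed the phrase lists with the canonical examples; all lists are
#' user-extensible and matched case-insensitively.
#'
#' @param min_words Minimum whitespace-token count (R1), default 10.
#' @param reference_phrases Lowercase phrases whose presence violates R3.
#' @param compound_ref_patterns Regular expressions for bare compound
#'   references (R4).
#' @param title_phrases Product euphemisms triggering the R5 check.
#' @param iupac_heuristic Logical; when \code{TRUE} (default) R5 is waived if
#'   an IUPAC-like name co-occurs in the same sentence as the euphemism.
#' @return An object of class \code{rule_config}.
#' @export
rule_config <- function(min_words = 10,
                        reference_phrases = c(
                          "following general procedure",
                          "following the general procedure",
                          "as described in",
                          "according to the procedure",
                          "according to general procedure",
                          "in a similar manner to",
                          "was prepared as described",
                          "using the method described",
                          "in analogy to"
                        ),
                        compound_ref_patterns = c(
                          "\\b(compound|intermediate|example|step|preparation)\\s+[0-9]+[a-z]?\\b(?![-(])",
                          "\\b(compound|intermediate|example)\\s+[ivxlc]+\\b(?![-(])"
                        ),
                        title_phrases = c(
                          "title compound", "resultant compound",
                          "desired compound", "desired product",
                          "title product",
                          "white solid", "yellow crystals", "black powder",
                          "white powder", "yellow solid", "colorless oil"
                        ),
                        iupac_heuristic = TRUE) {
  stopifnot(min_words >= 1, length(reference_phrases) > 0,
            length(compound_ref_patterns) > 0, length(title_phrases) > 0)
  structure(list(min_words = min_words,
                 reference_phrases = tolower(reference_phrases),
                 compound_ref_patterns = compound_ref_patterns,
                 title_phrases = tolower(title_phrases),
                 iupac_heuristic = isTRUE(iupac_heuristic)),
            class = "rule_config")
}

#' Heuristic test for IUPAC-like chemical names
#'
#' Scores a text span on surface features characteristic of systematic
#' nomenclature: digit locants with punctuation (\code{"1-"}, \code{"2,3-"}),
#' nested brackets, characteristic morphemes (\code{yl}, \code{oxy},
#' \code{amino}, \code{benzo}, \code{pyridin}, \code{ol}, \code{one},
#' \code{acid}, halogen prefixes, ...), and multiple hyphens.  Returns
#' \code{TRUE} iff at least two features fire.
#'
#' @param x Character vector of candidate spans.
#' @return Logical vector.
#' @export
#' @examples
#' looks_iupac("3-cyano-4-((1-methylethyl)oxy)benzoic acid")  # TRUE
#' looks_iupac("white solid")                                 # FALSE
looks_iupac <- function(x) {
  stopifnot(is.character(x))
  morphemes <- c("yl\\b", "yl[a-z]", "oxy", "amino", "benzo", "pyridin",
                 "pyrrolidin", "piperidin", "imidazol", "phenyl", "meth",
                 "eth(an|yl|ox)", "prop(an|yl)", "but(an|yl)", "chloro",
                 "bromo", "fluoro", "iodo", "nitro", "cyano", "hydroxy",
                 "carbox", "\\bacid\\b", "oate\\b", "ol\\b", "one\\b",
                 "ine\\b", "ide\\b", "ate\\b", "azo", "thio")
  morpheme_re <- paste0("(", paste(morphemes, collapse = "|"), ")")
  f_locant <- grepl("\\b\\d+(,\\d+)*-", x)
  f_bracket <- grepl("\\(\\(|\\)\\)|\\[|\\)-|-\\(", x)
  f_morpheme <- grepl(morpheme_re, x, ignore.case = TRUE)
  f_hyphens <- vapply(gregexpr("-", x, fixed = TRUE),
                      function(g) sum(g > 0) >= 2, logical(1))
  (f_locant + f_bracket + f_morpheme + f_hyphens) >= 2
}

#' Decide whether a paragraph is an admissible synthesis procedure
#'
#' Applies the five admission rules and returns the decision together with
#' the codes of every violated rule.  Total function: never errors.
#'
#' @param p A \code{\link{paragraph_record}} or a single string.
#' @param cfg A \code{\link{rule_config}}.
#' @return A list with \code{decision} (logical) and \code{violations}
#'   (character vector of codes among \code{"R1"}..\code{"R5"}).
#' @export
#' @examples
#' admissible_procedure("Following general procedure A, the mixture was stirred for two hours at reflux.")
admissible_procedure <- function(p, cfg = rule_config()) {
  text <- if (inherits(p, "paragraph_record")) p$text else as.character(p)
  stopifnot(length(text) == 1)
  lower <- tolower(text)
  violations <- character(0)

  # R1: word count
  n_words <- length(strsplit(squish(text), " ", fixed = TRUE)[[1]])
  if (n_words < cfg$min_words) violations <- c(violations, "R1")

  # R2: must not end abruptly - terminal punctuation, optionally followed
  # by a closing quote/bracket
  if (!grepl("[.!?][])\"']?$", trimws(text)))
    violations <- c(violations, "R2")

  # R3: no references to other methods or procedures
  if (any(vapply(cfg$reference_phrases,
                 function(ph) grepl(ph, lower, fixed = TRUE), logical(1))))
    violations <- c(violations, "R3")

  # R4: no bare compound references
  if (any(vapply(cfg$compound_ref_patterns,
                 function(re) grepl(re, text, ignore.case = TRUE, perl = TRUE),
                 logical(1))))
    violations <- c(violations, "R4")

  # R5: product euphemisms require a proper name in the same sentence
  hit <- cfg$title_phrases[vapply(cfg$title_phrases,
                                  function(ph) grepl(ph, lower, fixed = TRUE),
                                  logical(1))]
  if (length(hit)) {
    ok <- !cfg$iupac_heuristic
    if (cfg$iupac_heuristic) {
      sentences <- split_sentences(text)$sentences
      for (s in sentences) {
        if (any(vapply(hit, function(ph) grepl(ph, tolower(s), fixed = TRUE),
                       logical(1)))) {
          if (!looks_iupac(s)) { ok <- FALSE; break }
          ok <- TRUE
        }
      }
    }
    if (!ok) violations <- c(violations, "R5")
  }

  list(decision = length(violations) == 0, violations = violations)
}
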