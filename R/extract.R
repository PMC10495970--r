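# Reactant/product/SMILES extraction from parsed action sequences.
#
# Reactants come from ADD and MAKESOLUTION clauses (the actions that
# introduce material), the product from the YIELD clause.  Solvents that
# appear in those clauses only as reaction medium are removed via a
# configurable stoplist; name-to-SMILES translation goes through a local
# two-column dictionary.

#' Load the shipped solvent stoplist
#' @return Character vector of solvent names.
#' @export
default_stoplist <- function() {
  x <- readLines(system.file("extdata", "solvent_stoplist.txt",
                             package = "chemactions"),
                 encoding = "UTF-8", warn = FALSE)
  x[nzchar(trimws(x))]
}

# strip trailing parenthesized qualifiers such as "(THF)" and lowercase
normalize_chem_name <- function(x) {
  out <- tolower(squish(x))
  repeat {
    stripped <- sub("\\s*\\([^()]*\\)$", "", out)
    if (identical(stripped, out)) break
    out <- stripped
  }
  out
}

#' Collect reactant names from an action sequence
#'
#' Names from Add and MakeSolution clauses, order-preserving, with SLN
#' back-references skipped, duplicates collapsed to the first occurrence,
#' and stoplist members removed (matched case-insensitively after stripping
#' trailing parenthesized qualifiers, so \code{"tetrahydrofuran (THF)"}
#' matches a stoplist entry \code{"tetrahydrofuran"}).
#'
#' @param seq An \code{\link{action_sequence}}.
#' @param stoplist Character vector of solvent names to drop.
#' @return Character vector of reactant names (verbatim).
#' @export
collect_reactants <- function(seq, stoplist = default_stoplist()) {
  stop_norm <- unique(normalize_chem_name(stoplist))
  names <- character(0)
  for (cl in seq$clauses) {
    if (!cl$action %in% c("Add", "MakeSolution")) next
    for (ch in cl$chemicals) {
      if (isTRUE(ch$is_solution_ref)) next
      names <- c(names, ch$name)
    }
  }
  names <- names[!duplicated(names)]
  names[!normalize_chem_name(names) %in% stop_norm]
}

#' Collect the product name from an action sequence
#'
#' The name carried by the first Yield clause; \code{NULL} when the
#' sequence has no Yield.  Additional Yield clauses are ignored with a
#' warning.
#'
#' @param seq An \code{\link{action_sequence}}.
#' @return A single name or \code{NULL}.
#' @export
collect_product <- function(seq) {
  yields <- Filter(function(cl) cl$action == "Yield", seq$clauses)
  if (!length(yields)) return(NULL)
  if (length(yields) > 1)
    warning("sequence has ", length(yields),
            " YIELD clauses; taking the first")
  ch <- yields[[1]]$chemicals[[1]]
  if (isTRUE(ch$is_solution_ref)) NULL else ch$name
}

#' Read a name-to-SMILES dictionary
#'
#' Two-column TSV (name TAB SMILES, UTF-8, no header).
#'
#' @param path File path; defaults to the small shipped dictionary.
#' @return An object of class \code{name_dictionary}.
#' @export
read_name_dictionary <- function(path = system.file("extdata", "name_to_smiles.tsv",
                                                    package = "chemactions")) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2))
    stop_chemactions("dict", "dictionary rows must have exactly 2 tab-separated fields")
  nms <- vapply(parts, `[[`, character(1), 1)
  smi <- vapply(parts, `[[`, character(1), 2)
  if (any(!nzchar(smi)))
    stop_chemactions("dict", "SMILES values must be non-empty")
  entries <- stats::setNames(smi, nms)
  structure(list(entries = entries,
                 lower = stats::setNames(smi, tolower(nms)),
                 normalization = "case-insensitive"),
            class = "name_dictionary")
}

#' Translate chemical names to SMILES via a local dictionary
#'
#' Resolved names carry the dictionary SMILES verbatim; unresolved names are
#' preserved with a flag, never dropped, so the output always has one row
#' per input name.
#'
#' @param names Character vector of chemical names.
#' @param dict A \code{\link{read_name_dictionary}} object.
#' @return data.frame with columns \code{name}, \code{smiles} (NA when
#'   unresolved), \code{resolved}.
#' @export
to_smiles <- function(names, dict = read_name_dictionary()) {
  stopifnot(inherits(dict, "name_dictionary"))
  if (!length(names))
    return(data.frame(name = character(0), smiles = character(0),
                      resolved = logical(0), stringsAsFactors = FALSE))
  smi <- unname(dict$entries[names])
  miss <- is.na(smi)
  smi[miss] <- unname(dict$lower[tolower(names[miss])])
  data.frame(name = names, smiles = smi, resolved = !is.na(smi),
             stringsAsFactors = FALSE)
}

#' Build a procedure record from a paragraph and its structured string
#'
#' @param source_id Record identifier.
#' @param paragraph Original paragraph text.
#' @param structured Structured-format string (paragraph level).
#' @param stoplist Solvent stoplist.
#' @param dict Name dictionary.
#' @return An object of class \code{procedure_record}.
#' @export
procedure_record <- function(source_id, paragraph, structured,
                             stoplist = default_stoplist(),
                             dict = read_name_dictionary()) {
  seq <- parse_structured(structured, mode = "lenient")
  reactants <- collect_reactants(seq, stoplist)
  product <- collect_product(seq)
  structure(list(
    source_id = source_id, paragraph = paragraph, structured = structured,
    reactants = reactants, product = product,
    reactant_smiles = to_smiles(reactants, dict),
    product_smiles = to_smiles(if (is.null(product)) character(0) else product,
                               dict)),
    class = "procedure_record")
}

#' Write procedure records as TSV
#'
#' Columns: source_id, paragraph, structured, reactants, product,
#' reactant_smiles, product_smiles.  List columns are "|"-joined.
#'
#' @param records List of \code{\link{procedure_record}}.
#' @param path Output file.
#' @export
write_procedure_tsv <- function(records, path) {
  join <- function(x) paste(x, collapse = "|")
  df <- data.frame(
    source_id = vapply(records, function(r) as.character(r$source_id), character(1)),
    paragraph = vapply(records, `[[`, character(1), "paragraph"),
    structured = vapply(records, `[[`, character(1), "structured"),
    reactants = vapply(records, function(r) join(r$reactants), character(1)),
    product = vapply(records, function(r) r$product %||% "", character(1)),
    reactant_smiles = vapply(records, function(r)
      join(ifelse(r$reactant_smiles$resolved, r$reactant_smiles$smiles, "?")),
      character(1)),
    product_smiles = vapply(records, function(r)
      join(ifelse(r$product_smiles$resolved, r$product_smiles$smiles, "?")),
      character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write procedure records as JSON Lines
#' @param records List of \code{\link{procedure_record}}.
#' @param path Output file.
#' @export
write_procedure_jsonl <- function(records, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (r in records)
    writeLines(jsonlite::toJSON(unclass(r), auto_unbox = TRUE, null = "null",
                                dataframe = "rows"), con)
  invisible(path)
}
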