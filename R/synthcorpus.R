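# Synthetic paired-corpus generator.
#
# Sentences are composed from per-action templates; each template renders one
# natural-language fragment and exactly one structured clause from the same
# slot values, so slot provenance is exact and every chemical name in the
# structured side (except the SLN back-reference) occurs verbatim in the
# sentence.  The same template table drives the rule-oracle converter
# (see rule_oracle_translate), which inverts generated sentences without any
# trained model.

# ---- lexicons --------------------------------------------------------------

#' Load the shipped seed lexicons
#'
#' @return A list with character vectors \code{compounds}, \code{solvents},
#'   \code{temperature_notations}, \code{duration_units},
#'   \code{drying_agents}.
#' @export
default_lexicons <- function() {
  dir <- system.file("extdata", "lexicons", package = "chemactions")
  read_lex <- function(f) {
    x <- readLines(file.path(dir, f), encoding = "UTF-8", warn = FALSE)
    x[nzchar(trimws(x))]
  }
  list(
    compounds = read_lex("compounds.txt"),
    solvents = read_lex("solvents.txt"),
    temperature_notations = read_lex("temperature_notations.txt"),
    duration_units = read_lex("duration_units.txt"),
    drying_agents = read_lex("drying_agents.txt")
  )
}

#' Default action weights
#'
#' Relative sampling weights for the 28 action types, proportional to the
#' action frequencies observed in large patent-derived procedure corpora
#' (Add dominates, Sonicate and OtherLanguage are rare).
#'
#' @return Named numeric vector over all 28 action names.
#' @export
default_action_weights <- function() {
  c(Add = 2249260, Stir = 671005, Concentrate = 656695, Yield = 618280,
    Wash = 506832, MakeSolution = 476329, CollectLayer = 364382,
    Filter = 352100, DrySolution = 336816, Purify = 323716,
    SetTemperature = 275622, Extract = 245546, NoAction = 207310,
    FollowOtherProcedure = 168541, Reflux = 102683, PH = 95297,
    PhaseSeparation = 67165, Wait = 65751, DrySolid = 64692,
    Recrystallize = 62959, Quench = 49396, InvalidAction = 44904,
    Partition = 34534, Triturate = 29702, Degas = 24100,
    Microwave = 11988, OtherLanguage = 1936, Sonicate = 1447)
}

#' Generator configuration
#'
#' @param n Number of pairs to generate.
#' @param seed Integer seed; all draws are reproducible given it.
#' @param action_weights Named nonnegative weights over the 28 actions.
#' @param lexicons As returned by \code{\link{default_lexicons}}.
#' @param positive_fraction Positive-class probability for classification
#'   sets (default 0.336).
#' @param max_clauses_per_sentence Maximum clauses composed into a sentence.
#' @return An object of class \code{generator_config}.
#' @export
generator_config <- function(n = 1000, seed = 1,
                             action_weights = default_action_weights(),
                             lexicons = default_lexicons(),
                             positive_fraction = 0.336,
                             max_clauses_per_sentence = 3) {
  if (any(action_weights < 0) || sum(action_weights) <= 0)
    stop_chemactions("config", "action weights must be nonnegative with positive sum")
  missing_actions <- setdiff(action_types()$name, names(action_weights))
  if (length(missing_actions))
    stop_chemactions("config", paste("missing action weights:",
                                     paste(missing_actions, collapse = ", ")))
  if (!all(lengths(lexicons[c("compounds", "solvents", "temperature_notations",
                              "duration_units", "drying_agents")]) > 0))
    stop_chemactions("config", "all lexicons must be non-empty")
  if (positive_fraction <= 0 || positive_fraction >= 1)
    stop_chemactions("config", "positive_fraction must lie in (0,1)")
  if (max_clauses_per_sentence < 1)
    stop_chemactions("config", "max_clauses_per_sentence must be >= 1")
  structure(list(n = n, seed = as.integer(seed),
                 action_weights = action_weights, lexicons = lexicons,
                 positive_fraction = positive_fraction,
                 max_clauses_per_sentence = max_clauses_per_sentence),
            class = "generator_config")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# ---- templates -------------------------------------------------------------

# Placeholder classes: c* compound, s* solvent, a* amount, t* temperature,
# d* duration, g* drying agent, r* ratio, p* pH value.
placeholder_class <- function(ph) {
  switch(substr(ph, 1, 1),
         c = "compound", s = "solvent", a = "amount", t = "temperature",
         d = "duration", g = "agent", r = "ratio", p = "ph",
         stop("unknown placeholder ", ph))
}

make_template <- function(action, sentence, structured, reactants = character(0),
                          product = NULL, w = 1) {
  phs <- regmatches(sentence, gregexpr("\\{[a-z][0-9]\\}", sentence))[[1]]
  phs <- unique(c(phs, regmatches(structured,
                                  gregexpr("\\{[a-z][0-9]\\}", structured))[[1]]))
  phs <- gsub("[{}]", "", phs)
  list(action = action, sentence = sentence, structured = structured,
       placeholders = phs,
       classes = vapply(phs, placeholder_class, character(1)),
       reactants = reactants, product = product, w = w)
}

#' The sentence/structure template table
#'
#' One or more templates per action; each renders one sentence fragment and
#' one structured clause from shared slot values.  Used by both the
#' generator and the rule-oracle converter.
#' @return List of template definitions.
#' @keywords internal
corpus_templates <- function() {
  tmpl <- getOption("chemactions.templates")
  if (!is.null(tmpl)) return(tmpl)
  t <- list(
    make_template("Add", "{c1} ({a1}) was added dropwise",
                  "ADD {c1} ({a1})", reactants = "c1", w = 5),
    make_template("Add", "{c1} was added to the mixture",
                  "ADD {c1}", reactants = "c1", w = 4),
    make_template("Add", "the prepared solution was transferred to the reaction vessel",
                  "ADD SLN", w = 1),
    make_template("CollectLayer", "the organic layer was collected",
                  "COLLECTLAYER keep organic", w = 3),
    make_template("CollectLayer", "the aqueous layer was collected",
                  "COLLECTLAYER keep aqueous", w = 1),
    make_template("Concentrate", "the mixture was concentrated under reduced pressure",
                  "CONCENTRATE"),
    make_template("Degas", "the solution was degassed with a stream of nitrogen",
                  "DEGAS"),
    make_template("DrySolid", "the solid was dried in vacuo",
                  "DRYSOLID"),
    make_template("DrySolution", "the organic phase was dried over {g1}",
                  "DRYSOLUTION with {g1}"),
    make_template("Extract", "the aqueous layer was extracted with {s1} ({a1})",
                  "EXTRACT with {s1} ({a1})"),
    make_template("Filter", "the precipitate was collected by filtration",
                  "FILTER keep precipitate", w = 1),
    make_template("Filter", "the mixture was filtered through a pad of celite",
                  "FILTER keep filtrate", w = 1),
    make_template("FollowOtherProcedure",
                  "the reaction was carried out analogously to a previously reported method",
                  "FOLLOWOTHERPROCEDURE"),
    make_template("MakeSolution",
                  "a solution of {c1} ({a1}) in {s1} ({a2}) was prepared",
                  "MAKESOLUTION with {c1} ({a1}) and {s1} ({a2})",
                  reactants = "c1"),
    make_template("Microwave",
                  "the vessel was irradiated in a microwave reactor at {t1} for {d1}",
                  "MICROWAVE at {t1} for {d1}"),
    make_template("OtherLanguage",
                  "das Gemisch wurde unter Rückfluss erhitzt",
                  "OTHERLANGUAGE"),
    make_template("Partition",
                  "the residue was partitioned between {s1} ({a1}) and {s2} ({a2})",
                  "PARTITION with {s1} ({a1}) and {s2} ({a2})"),
    make_template("PH", "the pH was adjusted to {p1} with {c1}",
                  "PH to pH {p1} with {c1}"),
    make_template("PhaseSeparation", "the layers were separated",
                  "PHASESEPARATION"),
    make_template("InvalidAction",
                  "the reaction is believed to proceed via a radical mechanism",
                  "INVALIDACTION"),
    make_template("Purify",
                  "the residue was purified by column chromatography eluting with {s1}:{s2} ({r1})",
                  "PURIFY: {s1}:{s2} {r1}", w = 2),
    make_template("Purify",
                  "the crude material was purified by chromatography eluting with {s1}",
                  "PURIFY: {s1}", w = 1),
    make_template("Quench", "the reaction was quenched with {c1}",
                  "QUENCH with {c1}"),
    make_template("Recrystallize", "the crude product was recrystallized from {s1}",
                  "RECRYSTALLIZE with {s1}"),
    make_template("NoAction",
                  "the product was carried forward without further purification",
                  "NOACTION"),
    make_template("Reflux", "the mixture was heated at reflux for {d1}",
                  "REFLUX for {d1}"),
    make_template("SetTemperature", "the solution was cooled to {t1}",
                  "SETTEMPERATURE {t1}", w = 1),
    make_template("SetTemperature", "the mixture was warmed to {t1}",
                  "SETTEMPERATURE {t1}", w = 1),
    make_template("Sonicate", "the suspension was sonicated for {d1}",
                  "SONICATE for {d1}"),
    make_template("Stir", "the mixture was stirred at {t1} for {d1}",
                  "STIR at {t1} for {d1}", w = 2),
    make_template("Stir", "the mixture was stirred for {d1}",
                  "STIR for {d1}", w = 1),
    make_template("Triturate", "the solid was triturated with {s1}",
                  "TRITURATE with {s1}"),
    make_template("Wait", "the mixture was allowed to stand for {d1}",
                  "WAIT for {d1}"),
    make_template("Wash", "the combined organic layers were washed with {s1} ({a1})",
                  "WASH with {s1} ({a1})"),
    make_template("Yield", "the reaction afforded {c1} ({a1})",
                  "YIELD {c1} ({a1})", product = "c1", w = 2),
    make_template("Yield", "concentration gave {c1}",
                  "YIELD {c1}", product = "c1", w = 1)
  )
  options(chemactions.templates = t)
  t
}

sentence_joiners <- function() c(", then ", " and then ", ", after which ")

# ---- slot sampling ---------------------------------------------------------

sample_slot_value <- function(class, lex) {
  switch(class,
    compound = sample(lex$compounds, 1),
    solvent = sample(lex$solvents, 1),
    agent = sample(lex$drying_agents, 1),
    amount = paste(sample(c(1:20, 25, 30, 40, 50, 60, 75, 80, 100, 120, 150,
                            200, 250, 300, 400, 500), 1),
                   sample(c("mg", "g", "mL", "L", "mmol", "mol", "equiv"), 1)),
    temperature = paste(sample(c(-78, -40, -20, -10, 0, 5, 10, 15, 20, 25, 30,
                                 40, 50, 60, 70, 80, 90, 100, 110, 120, 140,
                                 160, 180, 200), 1),
                        sample(lex$temperature_notations, 1)),
    duration = if (stats::runif(1) < 0.15) "overnight" else
      paste(sample(c(1:12, 15, 16, 18, 20, 24, 30, 36, 45, 48, 60, 90), 1),
            sample(lex$duration_units, 1)),
    ratio = paste0(sample(1:20, 1), ":", sample(1:20, 1)),
    ph = as.character(sample(1:14, 1)),
    stop("unknown slot class ", class)
  )
}

fill_template <- function(pattern, values) {
  out <- pattern
  for (ph in names(values))
    out <- gsub(paste0("{", ph, "}"), values[[ph]], out, fixed = TRUE)
  out
}

# ---- corpus pair -----------------------------------------------------------

#' Create a corpus pair
#'
#' @param sentence Free-text sentence.
#' @param structured Structured-format counterpart.
#' @param slots Named list of slot records (\code{value}, \code{class}).
#' @param origin \code{"template"} or \code{"augmented"}.
#' @param parent_id Identifier of the originating pair for augmented pairs.
#' @param id Pair identifier.
#' @param reactants,product Planted reactant names / product name.
#' @return An object of class \code{corpus_pair}.
#' @export
corpus_pair <- function(sentence, structured, slots = list(),
                        origin = c("template", "augmented"),
                        parent_id = NULL, id = NULL,
                        reactants = character(0), product = NULL) {
  origin <- match.arg(origin)
  structure(list(id = id, sentence = sentence, structured = structured,
                 slots = slots, origin = origin, parent_id = parent_id,
                 reactants = reactants, product = product),
            class = "corpus_pair")
}

#' @export
print.corpus_pair <- function(x, ...) {
  cat("<corpus_pair ", x$id %||% "", ">\n  sentence:   ", x$sentence,
      "\n  structured: ", x$structured, "\n", sep = "")
  invisible(x)
}

generate_one_pair <- function(cfg, templates, tpl_by_action, id) {
  lex <- cfg$lexicons
  k <- sample.int(cfg$max_clauses_per_sentence, 1,
                  prob = 2^-(seq_len(cfg$max_clauses_per_sentence) - 1))
  actions <- sample(names(cfg$action_weights), k, replace = TRUE,
                    prob = cfg$action_weights)
  # natural ordering: solution preparation first, product last
  actions <- c(actions[actions == "MakeSolution"],
               actions[!actions %in% c("MakeSolution", "Yield")],
               actions[actions == "Yield"])
  counters <- new.env(parent = emptyenv())
  slots <- list()
  fragments <- character(k); clauses <- character(k)
  reactants <- character(0); product <- NULL
  first_literal <- TRUE
  for (j in seq_len(k)) {
    cands <- tpl_by_action[[actions[j]]]
    tpl <- templates[[if (length(cands) == 1) cands else
      sample(cands, 1, prob = vapply(templates[cands], `[[`, numeric(1), "w"))]]
    values <- list()
    for (ph in tpl$placeholders) {
      cls <- tpl$classes[[ph]]
      values[[ph]] <- sample_slot_value(cls, lex)
      cnt <- (get0(cls, envir = counters, ifnotfound = 0L)) + 1L
      assign(cls, cnt, envir = counters)
      slots[[paste0(cls, "_", cnt)]] <- list(value = values[[ph]], class = cls)
    }
    fragments[j] <- fill_template(tpl$sentence, values)
    clauses[j] <- fill_template(tpl$structured, values)
    if (j == 1) first_literal <- !startsWith(tpl$sentence, "{")
    if (length(tpl$reactants))
      reactants <- c(reactants, unlist(values[tpl$reactants], use.names = FALSE))
    if (!is.null(tpl$product) && is.null(product))
      product <- values[[tpl$product]]
  }
  joiners <- if (k > 1) sample(sentence_joiners(), k - 1, replace = TRUE) else character(0)
  sent <- fragments[1]
  # chemical names are case-significant: capitalize only a literal opening
  if (first_literal) substr(sent, 1, 1) <- toupper(substr(sent, 1, 1))
  if (k > 1)
    for (j in 2:k) sent <- paste0(sent, joiners[j - 1], fragments[j])
  sent <- paste0(sent, ".")
  corpus_pair(sentence = sent,
              structured = paste0(paste(clauses, collapse = "; "), "."),
              slots = slots, origin = "template", id = id,
              reactants = unique(reactants), product = product)
}

#' Generate a paired (sentence, structured) corpus
#'
#' Deterministic given \code{cfg$seed}.  Every generated pair parses in
#' strict mode and satisfies the pair-consistency contract: each chemical
#' name on the structured side (except \code{SLN}) occurs verbatim in the
#' sentence.
#'
#' @param cfg A \code{\link{generator_config}}.
#' @return List of \code{\link{corpus_pair}} objects of length \code{cfg$n}.
#' @export
#' @examples
#' pairs <- generate_pairs(generator_config(n = 3, seed = 42))
#' pairs[[1]]
generate_pairs <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  templates <- corpus_templates()
  acts <- vapply(templates, `[[`, character(1), "action")
  tpl_by_action <- split(seq_along(templates), acts)
  with_seed(cfg$seed, {
    lapply(seq_len(cfg$n), function(i)
      generate_one_pair(cfg, templates, tpl_by_action, id = sprintf("pair_%06d", i)))
  })
}

# ---- negatives and classification sets ------------------------------------

negative_templates <- function() {
  # each entry: function(lex) -> text violating at least one admission rule
  list(
    # R3: references another procedure
    function(lex) paste0("The title material was prepared following general procedure ",
                         sample(LETTERS[1:6], 1),
                         " using ", sample(lex$compounds, 1),
                         " as the starting material in ", sample(lex$solvents, 1), "."),
    # R4: bare compound reference
    function(lex) paste0("Compound ", sample(1:40, 1),
                         " was treated with ", sample(lex$compounds, 1),
                         " to give Intermediate ", sample(1:20, 1),
                         " which was used directly in the next step."),
    # R1: too short
    function(lex) paste0("Melting point ", sample(60:240, 1), " degrees."),
    # R2: ends abruptly
    function(lex) paste0("A mixture of ", sample(lex$compounds, 1), " and ",
                         sample(lex$compounds, 1), " in ", sample(lex$solvents, 1),
                         " was stirred at room temperature for"),
    # R5: product euphemism without a proper name
    function(lex) paste0("Evaporation of the solvent gave the title compound as a white solid ",
                         "which was dried under high vacuum and stored under nitrogen ",
                         "until required for the next step."),
    # property description (decorated with an R4 violation)
    function(lex) paste0("Example ", sample(1:30, 1),
                         " exhibits favourable aqueous solubility and a melting point of ",
                         sample(80:220, 1),
                         " degrees, and its formulations are stable on storage.")
  )
}

#' Generate negative (non-procedure) paragraphs
#'
#' Paragraphs drawn from negative templates: property descriptions and
#' fragments engineered to violate specific admission rules, so each record
#' is rejected by \code{\link{admissible_procedure}}.
#'
#' @param n Number of paragraphs.
#' @param seed Integer seed.
#' @param cfg A \code{\link{generator_config}} (only lexicons are used).
#' @return List of \code{\link{paragraph_record}} objects with label 0.
#' @export
generate_negatives <- function(n, seed = 1, cfg = generator_config()) {
  if (n < 0) stop_chemactions("config", "n must be >= 0")
  tmpls <- negative_templates()
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      txt <- tmpls[[sample.int(length(tmpls), 1)]](cfg$lexicons)
      paragraph_record(id = sprintf("neg_%06d", i), text = txt, label = 0)
    })
  })
}

#' Generate a labeled classification set
#'
#' Positive paragraphs are built by joining the sentences of 2-4 generated
#' pairs (so they pass the admission rules); negatives come from
#' \code{\link{generate_negatives}}.  The label of each record is drawn
#' independently with \code{P(1) = cfg$positive_fraction}.
#'
#' @param n Number of paragraphs.
#' @param cfg A \code{\link{generator_config}}; \code{cfg$seed} drives all
#'   randomness.
#' @return List of \code{\link{paragraph_record}} objects.
#' @export
generate_classification_set <- function(n, cfg = generator_config()) {
  templates <- corpus_templates()
  acts <- vapply(templates, `[[`, character(1), "action")
  tpl_by_action <- split(seq_along(templates), acts)
  neg_tmpls <- negative_templates()
  with_seed(cfg$seed, {
    lapply(seq_len(n), function(i) {
      if (stats::runif(1) < cfg$positive_fraction) {
        for (try in 1:20) {
          m <- sample(2:4, 1)
          sents <- vapply(seq_len(m), function(j)
            generate_one_pair(cfg, templates, tpl_by_action, id = NA)$sentence,
            character(1))
          txt <- paste(sents, collapse = " ")
          if (admissible_procedure(txt)$decision) break
        }
        paragraph_record(id = sprintf("pos_%06d", i), text = txt, label = 1)
      } else {
        txt <- neg_tmpls[[sample.int(length(neg_tmpls), 1)]](cfg$lexicons)
        paragraph_record(id = sprintf("neg_%06d", i), text = txt, label = 0)
      }
    })
  })
}

# ---- augmentation ----------------------------------------------------------

augmentable_classes <- c("temperature", "duration", "solvent", "compound", "agent")

resample_slot <- function(slot, lex) {
  for (i in 1:50) {
    new <- sample_slot_value(slot$class, lex)
    if (new != slot$value) return(new)
  }
  slot$value
}

#' Augment a corpus pair
#'
#' Produces up to four variants of a pair by substituting slot surfaces from
#' one or more of the four substitution classes: temperature parameters,
#' duration parameters, solvents, and compound names.  Every substituted
#' surface string is replaced identically in the sentence and the structured
#' string, so augmented pairs keep the pair-consistency contract and the
#' action-type sequence of the parent.
#'
#' @param pair A \code{\link{corpus_pair}}.
#' @param k Number of variants, between 0 and 4.
#' @param lexicons Lexicon list used to draw replacement surfaces.
#' @param seed Integer seed.
#' @return List of \code{k} augmented \code{\link{corpus_pair}} objects.
#' @export
augment_pair <- function(pair, k, lexicons = default_lexicons(), seed = 1) {
  stopifnot(inherits(pair, "corpus_pair"))
  if (k < 0 || k > 4)
    stop_chemactions("config", "k must lie in [0, 4]")
  if (k == 0) return(list())
  classes <- unique(vapply(pair$slots, `[[`, character(1), "class"))
  classes <- intersect(classes, augmentable_classes)
  if (!length(classes))
    stop_chemactions("augment", "pair has no augmentable slots")
  with_seed(seed, {
    lapply(seq_len(k), function(v) {
      chosen <- sample(classes, sample.int(length(classes), 1))
      sent <- pair$sentence; struct <- pair$structured
      slots <- pair$slots
      reactants <- pair$reactants; product <- pair$product
      for (nm in names(slots)) {
        slot <- slots[[nm]]
        if (!slot$class %in% chosen) next
        if (!grepl(slot$value, sent, fixed = TRUE) ||
            !(grepl(slot$value, struct, fixed = TRUE) ||
              slot$class %in% c("ratio", "ph")))
          stop_chemactions("augment",
                           sprintf("slot '%s' surface missing from pair", nm))
        new <- resample_slot(slot, lexicons)
        sent <- gsub(slot$value, new, sent, fixed = TRUE)
        struct <- gsub(slot$value, new, struct, fixed = TRUE)
        reactants[reactants == slot$value] <- new
        if (!is.null(product) && identical(product, slot$value)) product <- new
        slots[[nm]]$value <- new
      }
      corpus_pair(sentence = sent, structured = struct, slots = slots,
                  origin = "augmented", parent_id = pair$id,
                  id = paste0(pair$id, "_aug", v),
                  reactants = unique(reactants), product = product)
    })
  })
}

# ---- splitting -------------------------------------------------------------

#' Subset sizes for the 80/10/10 split
#'
#' Rounding rule: \code{val = round(0.1 N)}, \code{test = round(0.1 N)},
#' \code{train = N - val - test}.
#'
#' @param n Dataset size.
#' @return Named integer vector \code{c(train, validation, test)}.
#' @export
#' @examples
#' split_sizes(20199)    # 16159 2020 2020
#' split_sizes(3074038)  # 2459230 307404 307404
split_sizes <- function(n) {
  val <- as.integer(round(0.1 * n))
  test <- as.integer(round(0.1 * n))
  c(train = as.integer(n) - val - test, validation = val, test = test)
}

#' Split a dataset into train/validation/test
#'
#' Seeded shuffle followed by the \code{\link{split_sizes}} rule; the three
#' parts are disjoint and their union is the input.
#'
#' @param dataset A list (or vector) of records, length >= 3.
#' @param seed Integer seed.
#' @return List with elements \code{train}, \code{validation}, \code{test}.
#' @export
split_dataset <- function(dataset, seed = 1) {
  n <- length(dataset)
  if (n < 3) stop_chemactions("size", "dataset must contain at least 3 records")
  sz <- split_sizes(n)
  with_seed(seed, {
    idx <- sample.int(n)
    list(train = dataset[idx[seq_len(sz["train"])]],
         validation = dataset[idx[sz["train"] + seq_len(sz["validation"])]],
         test = dataset[idx[sz["train"] + sz["validation"] + seq_len(sz["test"])]])
  })
}

# ---- corpus IO -------------------------------------------------------------

#' Write pairs as a two-column TSV (sentence, structured)
#' @param pairs List of \code{\link{corpus_pair}}.
#' @param path Output file.
#' @export
write_pairs_tsv <- function(pairs, path) {
  df <- data.frame(
    sentence = vapply(pairs, `[[`, character(1), "sentence"),
    structured = vapply(pairs, `[[`, character(1), "structured"),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a two-column TSV of (sentence, structured) pairs
#' @param path Input file.
#' @return List of \code{\link{corpus_pair}}.
#' @export
read_pairs_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
                          encoding = "UTF-8")
  lapply(seq_len(nrow(df)), function(i)
    corpus_pair(df$sentence[i], df$structured[i], id = sprintf("row_%06d", i)))
}

#' Write pairs as JSON Lines with full provenance
#' @param pairs List of \code{\link{corpus_pair}}.
#' @param path Output file.
#' @export
write_pairs_jsonl <- function(pairs, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (p in pairs)
    writeLines(jsonlite::toJSON(unclass(p), auto_unbox = TRUE, null = "null"),
               con)
  invisible(path)
}
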