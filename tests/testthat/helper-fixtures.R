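# Shared fixtures: the five worked structured/sentence examples, plus
# memoised small corpora and tokenizers so expensive setup runs once per
# test session.

table1_structured <- c(
  paste0("MAKESOLUTION with 3-cyano-4-((1-methylethyl)oxy)benzoic acid ",
         "(200 mg) and tetrahydrofuran (THF) (10 mL); ADD SLN; ",
         "ADD EDC (374 mg); ADD HOBt (299 mg)."),
  "PARTITION with dichloromethane (10 mL) and water (10 mL).",
  "ADD Ethanol; ADD water; FILTER keep precipitate.",
  "QUENCH with saturated aqueous NH4Cl; EXTRACT with CH2Cl2.",
  paste0("FILTER keep filtrate; CONCENTRATE; ",
         "PURIFY: ethyl acetate:petroleum ether; ",
         "YIELD 1-benzyl-2-(chloromethyl)pyrrolidine.")
)

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  v <- get0(key, envir = .fixture_env)
  if (is.null(v)) {
    v <- builder()
    assign(key, v, envir = .fixture_env)
  }
  v
}

small_pairs <- function(n = 300, seed = 42) {
  memo(sprintf("pairs_%d_%d", n, seed),
       function() generate_pairs(generator_config(n = n, seed = seed)))
}

small_tok <- function(vocab = 600) {
  memo(sprintf("tok_%d", vocab), function() {
    pairs <- small_pairs(400, seed = 7)
    corpus <- c(vapply(pairs, `[[`, character(1), "sentence"),
                vapply(pairs, `[[`, character(1), "structured"),
                table1_structured)
    train_subword(corpus, vocab_size = vocab)
  })
}

expect_chem_error <- function(expr, subclass) {
  expect_error(expr, class = paste0("chemactions_error_", subclass))
}

labels_of <- function(records) vapply(records, function(r) r$label, numeric(1))
texts_of <- function(records) vapply(records, function(r) r$text, character(1))
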