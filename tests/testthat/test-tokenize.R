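test_that("training produces exactly the requested vocabulary size", {
  tok <- small_tok(600)
  expect_equal(tok$vocab_size, 600)
  expect_length(tok$pieces, 600)
  expect_length(tok$logp, 600)
})

test_that("training rejects degenerate inputs", {
  expect_chem_error(train_subword("tiny corpus", vocab_size = 500),
                    "corpus_too_small")
  corpus <- strrep("the mixture was stirred and filtered ", 50)
  expect_chem_error(train_subword(corpus, vocab_size = 50), "config")
  expect_chem_error(train_subword(corpus, vocab_size = 50000),
                    "vocab_too_large")
})

test_that("encode/decode round-trips corpus text exactly", {
  tok <- small_tok()
  pairs <- small_pairs(200, seed = 13)
  for (p in pairs) {
    expect_identical(subword_decode(tok, subword_encode(tok, p$sentence)),
                     p$sentence)
    expect_identical(subword_decode(tok, subword_encode(tok, p$structured)),
                     p$structured)
  }
})

test_that("worked example sentences round-trip through the tokenizer", {
  tok <- small_tok()
  for (s in table1_structured)
    expect_identical(subword_decode(tok, subword_encode(tok, s)), s)
})

test_that("empty text encodes to an empty id sequence", {
  tok <- small_tok()
  expect_identical(subword_encode(tok, ""), integer(0))
  expect_identical(subword_decode(tok, integer(0)), "")
})

test_that("digit runs are never split when split_digits is off", {
  tok <- small_tok()
  for (txt in c("10 mL", "374 mg", "25 °C", "120 equiv")) {
    ids <- subword_encode(tok, txt)
    pieces <- tok$pieces[ids + 1]
    num <- regmatches(txt, regexpr("[0-9]+", txt))
    expect_true(any(grepl(num, pieces, fixed = TRUE)),
                info = paste(txt, "->", paste(pieces, collapse = "|")))
  }
})

test_that("out-of-alphabet characters round-trip via byte fallback", {
  tok <- small_tok()
  for (s in c("αβγ-ester 5 mg", "中文 solvent", "naïve château", "Δ9-THC")) {
    ids <- subword_encode(tok, s)
    expect_true(all(ids >= 0 & ids < tok$vocab_size))
    expect_identical(subword_decode(tok, ids), s)
  }
})

test_that("decode rejects out-of-range ids", {
  tok <- small_tok()
  expect_chem_error(subword_decode(tok, c(0L, tok$vocab_size)), "invalid_id")
  expect_chem_error(subword_decode(tok, -1L), "invalid_id")
})

test_that("one shared model encodes both sides of a pair", {
  tok <- small_tok()
  p <- small_pairs(200, seed = 13)[[1]]
  ids_src <- subword_encode(tok, p$sentence)
  ids_tgt <- subword_encode(tok, p$structured)
  expect_true(max(ids_src, ids_tgt) < tok$vocab_size)
  # action keywords present in the vocabulary as learned pieces
  expect_true(any(grepl("ADD", tok$pieces, fixed = TRUE)))
})

test_that("mean pieces per word decreases as the vocabulary grows", {
  pairs <- small_pairs(400, seed = 7)
  corpus <- c(vapply(pairs, `[[`, character(1), "sentence"),
              vapply(pairs, `[[`, character(1), "structured"))
  eval_lines <- corpus[1:150]
  ppw <- vapply(c(400, 700, 1200), function(v)
    pieces_per_word(train_subword(corpus, vocab_size = v), eval_lines),
    numeric(1))
  expect_true(all(diff(ppw) <= 1e-9))
})

test_that("training is deterministic and models survive save/load", {
  pairs <- small_pairs(200, seed = 13)
  corpus <- vapply(pairs, `[[`, character(1), "sentence")
  m1 <- train_subword(corpus, vocab_size = 450)
  m2 <- train_subword(corpus, vocab_size = 450)
  expect_identical(m1$pieces, m2$pieces)
  expect_identical(m1$logp, m2$logp)
  f <- withr::local_tempfile(fileext = ".tsv")
  save_subword(m1, f)
  m3 <- load_subword(f)
  s <- corpus[7]
  expect_identical(subword_encode(m3, s), subword_encode(m1, s))
  expect_identical(m3$split_digits, m1$split_digits)
})

test_that("split_digits=TRUE segments every digit separately", {
  pairs <- small_pairs(200, seed = 13)
  corpus <- vapply(pairs, `[[`, character(1), "sentence")
  tok <- train_subword(corpus, vocab_size = 400, split_digits = TRUE)
  ids <- subword_encode(tok, "374 mg")
  pieces <- tok$pieces[ids + 1]
  digit_pieces <- pieces[grepl("[0-9]", pieces)]
  expect_true(all(nchar(gsub("▁", "", digit_pieces)) == 1))
  expect_identical(subword_decode(tok, ids), "374 mg")
})
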