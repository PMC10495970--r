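test_that("baselines reproduce the analytic values for a 0.336/0.664 split", {
  labels <- c(rep(0, 664), rep(1, 336))
  rb <- random_baseline(labels)
  expect_equal(rb, 0.336^2 + 0.664^2)
  expect_equal(floor(rb * 1000) / 1000, 0.553)  # printed to three decimals
  expect_equal(majority_baseline(labels), 0.664)
})

test_that("baseline edge cases behave as the formulas dictate", {
  expect_equal(random_baseline(c(0, 1, 0, 1)), 0.5)
  expect_equal(majority_baseline(c(0, 1, 0, 1)), 0.5)
  expect_equal(random_baseline(rep(1, 9)), 1)
  expect_equal(majority_baseline(rep("x", 5)), 1)
  expect_chem_error(random_baseline(numeric(0)), "empty_labels")
  expect_chem_error(majority_baseline(numeric(0)), "empty_labels")
})

test_that("random baseline never exceeds the majority baseline", {
  set.seed(5)
  for (i in 1:1000) {
    k <- sample(2:4, 1)
    labels <- sample(seq_len(k), sample(3:50, 1), replace = TRUE)
    expect_lte(random_baseline(labels), majority_baseline(labels))
  }
})

test_that("classification metrics match a hand-counted confusion matrix", {
  m <- classification_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 0.5)
  expect_equal(m$f1, 2 / 3)
  expect_equal(unname(m$counts), c(1, 2, 0, 1))

  perfect <- classification_metrics(c(1, 0, 1), c(1, 0, 1))
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))

  inverted <- classification_metrics(c(1, 0), c(0, 1))
  expect_equal(inverted$accuracy, 0)
  expect_equal(inverted$precision, 0)
  expect_equal(inverted$recall, 0)

  none_pred <- classification_metrics(c(0, 0), c(0, 0))
  expect_true("precision" %in% none_pred$undefined)
  expect_chem_error(classification_metrics(c(1, 0), c(1)), "length_mismatch")
  expect_chem_error(classification_metrics(c(1, 2), c(1, 0)), "data")
})

test_that("corpus BLEU matches hand n-gram computations", {
  identity <- corpus_bleu(c("a b c d e", "f g h i"), c("a b c d e", "f g h i"))
  expect_equal(identity$bleu, 1)
  expect_equal(identity$brevity_penalty, 1)

  short <- corpus_bleu("a b c d e", "a b c d")
  expect_equal(short$precisions, rep(1, 4))
  expect_equal(short$brevity_penalty, exp(1 - 5 / 4))
  expect_equal(short$bleu, exp(1 - 5 / 4))

  expect_equal(corpus_bleu("a b c d", "w x y z")$bleu, 0)
  expect_chem_error(corpus_bleu(character(0), character(0)), "empty_corpus")
  expect_chem_error(corpus_bleu(c("a", "b"), "a"), "length_mismatch")
})

test_that("clipping caps repeated hypothesis n-grams at the reference count", {
  r <- corpus_bleu("the cat sat on the mat", "the the the the the the")
  expect_equal(r$precisions[1], 2 / 6)  # "the" appears twice in the reference
  expect_equal(r$bleu, 0)               # no higher-order matches
})

test_that("corpus BLEU equals the independent reference implementation", {
  set.seed(11)
  alphabet <- c(letters[1:8], "ADD", "STIR", "10", "mg")
  corpora <- lapply(1:200, function(i) {
    n <- sample(1:8, 1)
    refs <- vapply(seq_len(n), function(j)
      paste(sample(alphabet, sample(1:12, 1), replace = TRUE), collapse = " "),
      character(1))
    hyps <- vapply(seq_len(n), function(j) {
      if (runif(1) < 0.3) refs[j]
      else paste(sample(alphabet, sample(1:12, 1), replace = TRUE),
                 collapse = " ")
    }, character(1))
    list(refs = refs, hyps = hyps)
  })
  fin <- tempfile(fileext = ".json")
  jsonlite::write_json(corpora, fin, auto_unbox = FALSE)
  oracle <- system.file("oracle", "bleu_oracle.py", package = "chemactions")
  py <- if (Sys.which("python") != "") "python" else "python3"
  out <- system2(py, c(oracle, fin), stdout = TRUE)
  expected <- jsonlite::fromJSON(paste(out, collapse = ""))
  got <- vapply(corpora, function(co)
    corpus_bleu(co$refs, co$hyps)$bleu, numeric(1))
  expect_equal(got, expected, tolerance = 1e-6)
})

test_that("ROUGE-L matches hand LCS computations", {
  expect_equal(rouge_l("A B C D", "A B C D"), 1)
  expect_equal(rouge_l("A B C D", "A C D E"), 0.75)
  expect_equal(rouge_l("a b", "c d"), 0)
  expect_chem_error(rouge_l("a", c("a", "b")), "length_mismatch")
  expect_chem_error(rouge_l("", "a"), "empty_text")
})

test_that("the ROUGE-L dynamic program agrees with brute-force subsequence enumeration", {
  brute_lcs <- function(a, b) {
    subseqs <- function(x) {
      n <- length(x)
      out <- list(character(0))
      for (i in seq_len(n))
        out <- c(out, lapply(out, function(s) c(s, x[i])))
      out
    }
    is_subseq <- function(s, y) {
      if (!length(s)) return(TRUE)
      j <- 1
      for (v in y) {
        if (v == s[j]) { j <- j + 1; if (j > length(s)) return(TRUE) }
      }
      FALSE
    }
    best <- 0
    for (s in subseqs(a)) if (length(s) > best && is_subseq(s, b))
      best <- length(s)
    best
  }
  rouge_from_lcs <- function(a, b) {
    l <- brute_lcs(a, b)
    if (l == 0) return(0)
    p <- l / length(b); r <- l / length(a)
    2 * p * r / (p + r)
  }
  alpha <- c("x", "y", "z")
  set.seed(3)
  # exhaustive over short pairs, sampled up to length 8
  for (la in 1:3) for (lb in 1:3) {
    grids_a <- expand.grid(rep(list(alpha), la), stringsAsFactors = FALSE)
    grids_b <- expand.grid(rep(list(alpha), lb), stringsAsFactors = FALSE)
    for (i in seq_len(nrow(grids_a))) for (j in seq_len(nrow(grids_b))) {
      a <- unlist(grids_a[i, ], use.names = FALSE)
      b <- unlist(grids_b[j, ], use.names = FALSE)
      expect_equal(rouge_l(paste(a, collapse = " "), paste(b, collapse = " ")),
                   rouge_from_lcs(a, b))
    }
  }
  for (k in 1:300) {
    a <- sample(alpha, sample(4:8, 1), replace = TRUE)
    b <- sample(alpha, sample(4:8, 1), replace = TRUE)
    expect_equal(rouge_l(paste(a, collapse = " "), paste(b, collapse = " ")),
                 rouge_from_lcs(a, b))
  }
})

test_that("BLEU and ROUGE-L live in [0,1] and reach 1 only at identity", {
  pairs <- small_pairs(60, seed = 23)
  refs <- vapply(pairs, `[[`, character(1), "structured")
  hyps <- c(refs[-1], "ADD water.")
  b <- corpus_bleu(refs, hyps)$bleu
  r <- rouge_l(refs, hyps)
  expect_true(b >= 0 && b < 1)
  expect_true(r >= 0 && r < 1)
  expect_equal(corpus_bleu(refs, refs)$bleu, 1)
  expect_equal(rouge_l(refs, refs), 1)
})

test_that("exact match applies whitespace and trailing-period normalization", {
  expect_equal(exact_match_accuracy("ADD x.", "ADD  x"), 1)
  expect_equal(exact_match_accuracy(c("a.", "b."), c("a.", "c.")), 0.5)
  expect_equal(exact_match_accuracy(character(0), character(0)), NaN)
  expect_chem_error(exact_match_accuracy("a", c("a", "b")), "length_mismatch")
})
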