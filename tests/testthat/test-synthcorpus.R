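test_that("generation honours n, determinism and the pair-consistency contract", {
  cfg <- generator_config(n = 0, seed = 1)
  expect_length(generate_pairs(cfg), 0)

  cfg <- generator_config(n = 250, seed = 17)
  pairs <- generate_pairs(cfg)
  expect_length(pairs, 250)
  expect_identical(pairs, generate_pairs(cfg))

  for (p in pairs) {
    seq <- parse_structured(p$structured, "strict")  # must not error
    for (cl in seq$clauses) for (ch in cl$chemicals) {
      if (!ch$is_solution_ref)
        expect_true(grepl(ch$name, p$sentence, fixed = TRUE), info = p$sentence)
    }
  }
})

test_that("generator rejects degenerate configurations", {
  expect_chem_error(generator_config(action_weights =
    setNames(rep(0, 28), action_types()$name)), "config")
  lex <- default_lexicons(); lex$solvents <- character(0)
  expect_chem_error(generator_config(lexicons = lex), "config")
  expect_chem_error(generator_config(positive_fraction = 0), "config")
  w <- default_action_weights()[-1]
  expect_chem_error(generator_config(action_weights = w), "config")
})

test_that("empirical action frequencies follow the configured weights", {
  pairs <- memo("pairs_freq", function()
    generate_pairs(generator_config(n = 50000, seed = 4)))
  acts <- unlist(lapply(pairs, function(p)
    vapply(parse_structured(p$structured)$clauses, `[[`, character(1),
           "action")))
  w <- default_action_weights()
  expected_p <- w / sum(w)
  obs <- table(factor(acts, levels = names(w)))
  n <- sum(obs)
  # chi-square goodness of fit; rare actions are covered by the test size
  gof <- suppressWarnings(chisq.test(as.numeric(obs), p = expected_p))
  expect_gt(gof$p.value, 0.001)
  # tolerance check on well-populated actions
  big <- names(w)[expected_p * n >= 500]
  rel <- abs(as.numeric(obs[big]) / n - expected_p[big]) / expected_p[big]
  expect_true(all(rel < 0.10))
})

test_that("negative paragraphs all fail the admission rules, deterministically", {
  negs <- generate_negatives(100, seed = 3)
  expect_length(negs, 100)
  expect_true(all(!vapply(negs, function(r)
    admissible_procedure(r)$decision, logical(1))))
  expect_identical(negs, generate_negatives(100, seed = 3))
  expect_length(generate_negatives(0, seed = 3), 0)
})

test_that("classification sets hit the configured positive fraction", {
  cs <- memo("clfset_5000", function()
    generate_classification_set(5000, generator_config(seed = 31)))
  labs <- vapply(cs, function(r) r$label, numeric(1))
  expect_lt(abs(mean(labs) - 0.336), 0.02)
  # positives pass the rules; negatives fail them
  pos <- cs[labs == 1][1:50]
  expect_true(all(vapply(pos, function(r)
    admissible_procedure(r)$decision, logical(1))))
})

test_that("augmentation substitutes slots consistently on both sides", {
  pairs <- small_pairs()
  # pick a pair with augmentable slots
  p <- NULL
  for (cand in pairs) {
    cls <- vapply(cand$slots, `[[`, character(1), "class")
    if (any(cls %in% c("temperature", "duration", "solvent", "compound"))) {
      p <- cand; break
    }
  }
  vars <- augment_pair(p, 4, seed = 5)
  expect_length(vars, 4)
  ref_actions <- vapply(parse_structured(p$structured)$clauses, `[[`,
                        character(1), "action")
  for (v in vars) {
    expect_equal(v$origin, "augmented")
    expect_equal(v$parent_id, p$id)
    seq <- parse_structured(v$structured, "strict")
    expect_identical(vapply(seq$clauses, `[[`, character(1), "action"),
                     ref_actions)
    for (cl in seq$clauses) for (ch in cl$chemicals) {
      if (!ch$is_solution_ref)
        expect_true(grepl(ch$name, v$sentence, fixed = TRUE))
    }
    # at least one surface changed
    expect_false(identical(v$structured, p$structured))
  }
  expect_length(augment_pair(p, 0), 0)
  expect_chem_error(augment_pair(p, 5), "config")
})

test_that("temperature augmentation rewrites the full value+notation surface", {
  pairs <- small_pairs()
  p <- NULL
  for (cand in pairs) {
    cls <- vapply(cand$slots, `[[`, character(1), "class")
    if ("temperature" %in% cls) { p <- cand; break }
  }
  old <- p$slots[[which(vapply(p$slots, `[[`, character(1), "class") ==
                          "temperature")[1]]]$value
  found_change <- FALSE
  for (v in augment_pair(p, 4, seed = 11)) {
    slot <- v$slots[[which(vapply(v$slots, `[[`, character(1), "class") ==
                             "temperature")[1]]]
    if (slot$value != old) {
      found_change <- TRUE
      expect_true(grepl(slot$value, v$sentence, fixed = TRUE))
      expect_true(grepl(slot$value, v$structured, fixed = TRUE))
    }
  }
  expect_true(found_change)
})

test_that("the split rule reproduces the published subset sizes", {
  expect_equal(unname(split_sizes(20199)), c(16159, 2020, 2020))
  expect_equal(unname(split_sizes(3074038)), c(2459230, 307404, 307404))
  expect_equal(unname(split_sizes(10)), c(8, 1, 1))
})

test_that("split partitions the dataset for random sizes", {
  set.seed(1)
  for (n in c(3, 4, sample(5:1000, 20), sample(1001:100000, 5))) {
    x <- seq_len(n)
    sp <- split_dataset(x, seed = n)
    expect_equal(length(sp$train) + length(sp$validation) + length(sp$test), n)
    expect_equal(sort(c(sp$train, sp$validation, sp$test)), x)
    expect_length(intersect(sp$train, sp$test), 0)
    expect_length(intersect(sp$train, sp$validation), 0)
    expect_length(intersect(sp$validation, sp$test), 0)
  }
  expect_chem_error(split_dataset(1:2), "size")
})

test_that("pair corpora survive TSV round trips", {
  pairs <- small_pairs()[1:20]
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pairs_tsv(pairs, f)
  back <- read_pairs_tsv(f)
  expect_equal(vapply(back, `[[`, character(1), "sentence"),
               vapply(pairs, `[[`, character(1), "sentence"))
  expect_equal(vapply(back, `[[`, character(1), "structured"),
               vapply(pairs, `[[`, character(1), "structured"))
  fj <- withr::local_tempfile(fileext = ".jsonl")
  write_pairs_jsonl(pairs, fj)
  expect_length(readLines(fj, warn = FALSE), 20)
})
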