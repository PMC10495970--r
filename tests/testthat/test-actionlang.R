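test_that("the action inventory has exactly 28 members with uppercase keywords", {
  tab <- action_types()
  expect_equal(nrow(tab), 28)
  expect_equal(anyDuplicated(tab$name), 0)
  expect_identical(tab$keyword, toupper(tab$name))
  expect_true(all(c("Add", "MakeSolution", "CollectLayer", "Purify",
                    "InvalidAction", "FollowOtherProcedure", "Yield")
                  %in% tab$name))
})

test_that("worked structured examples parse in strict mode and round-trip byte-identically", {
  for (s in table1_structured) {
    seq <- parse_structured(s, mode = "strict")
    expect_identical(serialize_actions(seq), normalize_structured(s))
    expect_identical(serialize_actions(seq), s)  # already normal form
  }
})

test_that("parsed clauses expose typed slots", {
  seq <- parse_structured(table1_structured[1], "strict")
  expect_equal(length(seq$clauses), 4)
  ms <- seq$clauses[[1]]
  expect_equal(ms$action, "MakeSolution")
  expect_equal(ms$chemicals[[1]]$name,
               "3-cyano-4-((1-methylethyl)oxy)benzoic acid")
  expect_equal(ms$chemicals[[1]]$amount, "200 mg")
  expect_equal(ms$chemicals[[2]]$name, "tetrahydrofuran (THF)")
  expect_equal(ms$chemicals[[2]]$amount, "10 mL")
  expect_true(seq$clauses[[2]]$chemicals[[1]]$is_solution_ref)

  seq2 <- parse_structured("PARTITION with dichloromethane (10 mL) and water (10 mL).")
  expect_equal(length(seq2$clauses), 1)
  expect_equal(vapply(seq2$clauses[[1]]$chemicals, `[[`, character(1), "amount"),
               c("10 mL", "10 mL"))

  seq3 <- parse_structured("ADD Ethanol; ADD water; FILTER keep precipitate.")
  expect_equal(length(seq3$clauses), 3)
  expect_equal(seq3$clauses[[3]]$keep_phase, "precipitate")

  seq5 <- parse_structured(table1_structured[5])
  expect_equal(seq5$clauses[[3]]$purify_solvents,
               c("ethyl acetate", "petroleum ether"))
})

test_that("modifier clauses carry temperature and duration slots", {
  seq <- parse_structured("STIR at 25 °C for 2 h; REFLUX for 30 min; MICROWAVE at 120 C for 10 min.")
  expect_equal(seq$clauses[[1]]$temperature, "25 °C")
  expect_equal(seq$clauses[[1]]$duration, "2 h")
  expect_null(seq$clauses[[2]]$temperature)
  expect_equal(seq$clauses[[2]]$duration, "30 min")
  expect_equal(seq$clauses[[3]]$temperature, "120 C")
})

test_that("parse errors carry condition classes", {
  expect_chem_error(parse_structured(""), "empty_input")
  expect_chem_error(parse_structured("   .  "), "empty_input")
  expect_chem_error(parse_structured("FROB with water", "strict"),
                    "unknown_action")
  expect_chem_error(parse_structured("FILTER keep organic", "strict"),
                    "malformed_clause")
  expect_chem_error(parse_structured("CONCENTRATE the mixture", "strict"),
                    "malformed_clause")
})

test_that("lenient mode maps unknown keywords to InvalidAction with raw text kept", {
  seq <- parse_structured("FROB with water; ADD Ethanol.", "lenient")
  expect_equal(seq$clauses[[1]]$action, "InvalidAction")
  expect_equal(seq$clauses[[1]]$free_params, "FROB with water")
  expect_equal(seq$clauses[[2]]$action, "Add")
})

test_that("keyword case is normalized on input and output", {
  seq <- parse_structured("add Ethanol; filter keep precipitate.")
  expect_identical(serialize_actions(seq),
                   "ADD Ethanol; FILTER keep precipitate.")
})

test_that("clause count equals the number of ';'-separated non-empty segments", {
  pairs <- small_pairs()
  for (p in pairs[1:150]) {
    nsegs <- sum(nzchar(trimws(
      strsplit(sub("\\.$", "", p$structured), ";", fixed = TRUE)[[1]])))
    expect_equal(length(parse_structured(p$structured)$clauses), nsegs)
  }
})

test_that("round-trip holds on generated grammar-conforming strings", {
  pairs <- memo("pairs_roundtrip", function()
    generate_pairs(generator_config(n = 1000, seed = 99)))
  for (p in pairs) {
    s <- p$structured
    expect_identical(serialize_actions(parse_structured(s, "strict")),
                     normalize_structured(s))
  }
})

test_that("parsing is deterministic across runs", {
  s <- table1_structured[1]
  expect_identical(parse_structured(s), parse_structured(s))
})

test_that("validate reports violations by clause and rule", {
  good <- parse_structured(table1_structured[5])
  expect_length(validate_actions(good), 0)

  bad1 <- parse_structured("PURIFY: methanol.")
  bad1$clauses[[1]]$keep_phase <- "filtrate"
  v1 <- validate_actions(bad1)
  expect_length(v1, 1)
  expect_match(v1, "keep_phase only allowed")

  bad2 <- parse_structured("FILTER keep precipitate.")
  bad2$clauses[[1]]$keep_phase <- "organic"
  expect_match(validate_actions(bad2), "not allowed for Filter")

  expect_equal(validate_actions(action_sequence()), "sequence has no clauses")
  expect_chem_error(serialize_actions(action_sequence()), "invalid_sequence")
})

test_that("programmatically built MakeSolution serializes to grammar-conforming text", {
  cl <- action_clause("MakeSolution", chemicals = list(
    chemical_mention("A", amount = "1 mL"),
    chemical_mention("B", amount = "2 mg")))
  s <- serialize_actions(action_sequence(list(cl)))
  expect_identical(s, "MAKESOLUTION with A (1 mL) and B (2 mg).")
  reparsed <- parse_structured(s, "strict")
  expect_identical(serialize_actions(reparsed), s)
})

test_that("'and' inside parentheses does not split chemical items", {
  s <- "ADD mixture of acids (formic and acetic).."
  seq <- parse_structured("WASH with buffer (phosphate and citrate) and brine.")
  expect_equal(length(seq$clauses[[1]]$chemicals), 2)
  expect_equal(seq$clauses[[1]]$chemicals[[1]]$name,
               "buffer (phosphate and citrate)")
})
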