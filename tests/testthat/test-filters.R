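long_tail <- paste("The mixture was stirred for two hours and the product",
                   "was isolated by filtration after cooling.")

test_that("each admission rule can be violated in isolation", {
  # R1: too short
  r <- admissible_procedure("Too short to pass muster here.")
  expect_false(r$decision); expect_equal(r$violations, "R1")
  # R2: ends abruptly
  r <- admissible_procedure(paste("A mixture of the two reagents in toluene",
                                  "was stirred at room temperature for"))
  expect_false(r$decision); expect_equal(r$violations, "R2")
  # R3: references another procedure
  r <- admissible_procedure(paste("Following general procedure A, the",
                                  long_tail))
  expect_false(r$decision); expect_equal(r$violations, "R3")
  r <- admissible_procedure(paste("The product was prepared as described in",
                                  "the earlier patent, and", long_tail))
  expect_true("R3" %in% r$violations)
  # R4: bare compound reference
  r <- admissible_procedure(paste("Compound 7 was treated with acid, and",
                                  long_tail))
  expect_false(r$decision); expect_equal(r$violations, "R4")
  r <- admissible_procedure(paste("INTERMEDIATE 2 was dissolved in ether, and",
                                  long_tail))
  expect_equal(r$violations, "R4")
  # R5: euphemism without a proper name
  r <- admissible_procedure(paste("Evaporation gave the title compound as a",
                                  "white solid which was stored under argon",
                                  "until further use."))
  expect_false(r$decision); expect_equal(r$violations, "R5")
})

test_that("a complete well-formed procedure paragraph is accepted", {
  txt <- paste("To a solution of 3-cyano-4-((1-methylethyl)oxy)benzoic acid",
               "(200 mg) in tetrahydrofuran (THF) (10 mL) was added EDC",
               "(374 mg) and HOBt (299 mg). The mixture was stirred",
               "overnight to give the title compound",
               "1-benzyl-2-(chloromethyl)pyrrolidine as a white solid.")
  r <- admissible_procedure(txt)
  expect_true(r$decision)
  expect_length(r$violations, 0)
})

test_that("R5 is waived only when an IUPAC-like name shares the sentence", {
  # name in a different sentence than the euphemism: still rejected
  txt <- paste("The starting material was",
               "3-cyano-4-((1-methylethyl)oxy)benzoic acid in THF solution.",
               "Workup gave the title compound as a white solid after drying",
               "under high vacuum overnight.")
  r <- admissible_procedure(txt)
  expect_equal(r$violations, "R5")
})

test_that("systematic names starting with a locant do not trip the compound-reference rule", {
  txt <- paste("The title compound 1-benzyl-2-(chloromethyl)pyrrolidine was",
               "obtained after column chromatography of the residue in good",
               "overall yield from the pooled organic fractions.")
  r <- admissible_procedure(txt)
  expect_true(r$decision)
})

test_that("looks_iupac needs at least two surface features", {
  expect_true(looks_iupac("3-cyano-4-((1-methylethyl)oxy)benzoic acid"))
  expect_true(looks_iupac("1-benzyl-2-(chloromethyl)pyrrolidine"))
  expect_false(looks_iupac("white solid"))
  expect_false(looks_iupac("title compound"))
  expect_false(looks_iupac("water"))
  expect_true(looks_iupac("N-(4-chlorophenyl)-2-hydroxyacetamide"))
})

test_that("violations are monotone under appending violating text", {
  base <- paste("The two reagents were combined in dichloromethane and",
                "stirred at ambient temperature until complete conversion.")
  r0 <- admissible_procedure(base)
  expect_true(r0$decision)
  worse <- paste(base, "This was done following general procedure B with",
                 "Compound 4 as the starting material.")
  r1 <- admissible_procedure(worse)
  expect_true(all(c("R3", "R4") %in% r1$violations))
})

test_that("rule configuration is honoured", {
  cfg <- rule_config(min_words = 3)
  expect_true(admissible_procedure("Short but now long enough overall.",
                                   cfg)$decision)
  cfg2 <- rule_config(reference_phrases = "quoth the raven")
  r <- admissible_procedure(paste("Following general procedure A, the",
                                  long_tail), cfg2)
  expect_false("R3" %in% r$violations)
  expect_error(rule_config(min_words = 0))
})

test_that("decisions are deterministic", {
  txt <- paste("Compound 3 was treated with base, and", long_tail)
  expect_identical(admissible_procedure(txt), admissible_procedure(txt))
})
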