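# chemactions

Turns free-text organic synthesis procedures into structured action
sequences and a tabular reaction dataset.

Patent experimental sections describe syntheses as prose. Downstream
chemistry — reaction prediction, condition optimization, autonomous
labs — needs the same content as a normalized sequence of actions with
typed parameters. chemactions implements that conversion end to end for R
users: a formal 28-action procedure language with parser and serializer;
rule-based admission criteria that decide whether a paragraph is a
well-formed procedure; a synthetic paired-corpus generator with slot-based
augmentation; a unigram subword tokenizer with byte fallback; desk-scale
neural networks (GRU/LSTM/BiLSTM/transformer classifier, and
rnn/birnn/transformer sequence-to-sequence converter) trained with
class-importance weighting and patience-based early stopping; the
evaluation suite (random/majority baselines, accuracy/precision/recall/F1,
corpus BLEU with brevity penalty, ROUGE-L, exact match); and
reactant/product/SMILES extraction through a local name dictionary.

## The core model

Task 1 is binary classification: learn η : paragraph → {0, 1} where 1
marks a synthesis procedure. Admission rules R1–R5 (length ≥ 10 words, no
abrupt ending, no references to other procedures, no bare compound
references such as "Compound 1", product euphemisms only alongside a
proper name) define label quality; baselines are
Random = Σᵢ P(yᵢ)² and Majority = max P(yᵢ), which for the 0.336/0.664
class split equal 0.553 (truncated) and 0.664.

Task 2 is sequence-to-sequence translation from an English sentence
s = (s₁…sₙ) to a structured sentence t = (t₁…tₘ) in the action language,
e.g.

```
The solution was quenched with saturated aqueous NH4Cl and extracted with CH2Cl2.
→ QUENCH with saturated aqueous NH4Cl; EXTRACT with CH2Cl2.
```

Both tasks share one unigram subword vocabulary. Generation quality is
scored with corpus BLEU, BLEU = BP · exp(Σₙ log pₙ / 4) with
BP = e^(1−r/c) for c ≤ r (clipped n-gram precisions pₙ pooled over the
corpus), ROUGE-L (LCS F-score, β = 1), and exact-match accuracy.
Reactants are read from ADD/MAKESOLUTION clauses, products from YIELD, and
names resolve to SMILES via a two-column dictionary.

## Worked example

```r
library(chemactions)

## parse and round-trip a structured string
parse_structured("QUENCH with saturated aqueous NH4Cl; EXTRACT with CH2Cl2.")
#> <action_sequence> 2 clause(s)
#>   QUENCH with saturated aqueous NH4Cl; EXTRACT with CH2Cl2.

## generate a synthetic (sentence, structured) pair
generate_pairs(generator_config(n = 3, seed = 42))[[1]]
#> <corpus_pair pair_000001>
#>   sentence:   The pH was adjusted to 10 with 9-borabicyclo[3.3.1]nonane, then the
#>               mixture was stirred for overnight, then the solution was cooled to 70 deg C.
#>   structured: PH to pH 10 with 9-borabicyclo[3.3.1]nonane; STIR for overnight; SETTEMPERATURE 70 deg C.

## admission rules reject procedure references
admissible_procedure(
  "Following general procedure A, the mixture was stirred for two hours at reflux.")
#> $decision    FALSE
#> $violations  "R3"

## reactant extraction with solvent stoplist removal
seq <- parse_structured(paste(
  "MAKESOLUTION with 3-cyano-4-((1-methylethyl)oxy)benzoic acid (200 mg)",
  "and tetrahydrofuran (THF) (10 mL); ADD SLN; ADD EDC (374 mg); ADD HOBt (299 mg)."))
collect_reactants(seq)
#> [1] "3-cyano-4-((1-methylethyl)oxy)benzoic acid" "EDC" "HOBt"

## baselines and BLEU
labs <- c(rep(1, 336), rep(0, 664))
random_baseline(labs)    #> 0.553792  (printed to three decimals: 0.553)
majority_baseline(labs)  #> 0.664
corpus_bleu("a b c d e", "a b c d")$bleu  #> 0.7788008  (= e^(1 - 5/4))

## the whole pipeline, rule-based stages only
res <- run_pipeline(c(
  paste("A solution of 4-bromoaniline (5 g) in ethanol (40 mL) was prepared,",
        "then the mixture was stirred at 25 C for 2 h and then the reaction",
        "afforded ethyl 4-aminobenzoate (4 g)."),
  "Compound 7 was treated with acid as described in Example 3."))
res
#> <pipeline_result>
#>   input                2
#>   deduplicated         2
#>   classified_positive  1
#>   excluded_invalid     0
#>   quarantined          0
#>   records              1
res$records[[1]]$reactants  #> "4-bromoaniline"   (ethanol removed as solvent)
res$records[[1]]$product    #> "ethyl 4-aminobenzoate"
```

The first paragraph is admitted, split, translated and mined; the second
violates the compound-reference and procedure-reference rules and is
dropped. Training the neural components follows the same grain:
`train_subword()` → `train_classifier()` / `train_seq2seq()` →
`predict_label()` / `translate()`; `desk_classifier_config()` and
`desk_seq2seq_config()` hold single-CPU presets, and
`classifier_presets()` / `seq2seq_presets()` the published full-scale
hyper-parameter combinations.

A thin command-line front end wrapping these functions ships at
`inst/cli/chemactions.R`
(`Rscript inst/cli/chemactions.R generate --n 1000 --out pairs.tsv`, and
likewise `filter`, `tokenize`, `train-s2s`, `translate`, `evaluate`,
`extract`, `run`).

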