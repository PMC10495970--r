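---
title: "From synthesis paragraphs to structured actions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From synthesis paragraphs to structured actions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemactions)
```

## The problem

Experimental sections of organic-chemistry patents describe synthesis
procedures as free prose: *"To a solution of 3-cyano-4-((1-methylethyl)oxy)benzoic
acid (200 mg) in tetrahydrofuran (THF) (10 mL) was added EDC (374 mg) and
HOBt (299 mg)."* Machine consumption of such text — reaction prediction,
condition optimization, robotic execution — needs the same content as a
normalized sequence of *actions* with typed parameters:

```
MAKESOLUTION with 3-cyano-4-((1-methylethyl)oxy)benzoic acid (200 mg) and
tetrahydrofuran (THF) (10 mL); ADD SLN; ADD EDC (374 mg); ADD HOBt (299 mg).
```

chemactions implements the full path from raw paragraphs to a tabular
reaction dataset in two machine-learning stages plus deterministic
bookkeeping:

1. **Paragraph admission/classification.** Decide whether a paragraph is a
   well-formed synthesis procedure, either with five rule-based admission
   criteria or with a trained binary classifier.
2. **Sentence-to-structure conversion.** Translate each sentence into the
   structured action language with a sequence-to-sequence network (or, for
   synthetic text, an exact rule-based inverse).
3. **Extraction.** Parse the structured strings and read off reactants
   (ADD/MAKESOLUTION clauses), the product (YIELD clause), and SMILES via a
   local name dictionary.

## The structured action language

The language has exactly 28 action types (`action_types()`). A structured
string is a `";"`-separated list of clauses ending in a period. Each clause
begins with an uppercase action keyword followed by an action-specific
payload:

* single-item actions (`ADD`, `YIELD`): one chemical, optionally with a
  parenthesized, space-separated amount; the reserved token `SLN`
  back-references the solution formed by a preceding `MAKESOLUTION`;
* `with`-list actions (`MAKESOLUTION`, `PARTITION`, `QUENCH`, `EXTRACT`,
  `WASH`, `TRITURATE`, `RECRYSTALLIZE`, `DRYSOLUTION`): one or more items
  joined by `and`;
* phase-keeping actions: `FILTER keep precipitate|filtrate`,
  `COLLECTLAYER keep organic|aqueous`;
* `PURIFY:` followed by a `":"`-separated solvent list and an optional
  numeric ratio such as `1:1`;
* `SETTEMPERATURE <temperature>`, `PH <free text>`, and bare keywords for
  the remaining actions;
* any clause may end with canonical `at <temperature>` and `for <duration>`
  modifiers, in that order.

The complete EBNF ships in `inst/extdata/grammar.ebnf` and is normative for
`parse_structured()`/`serialize_actions()`. Published sources show the
format by example rather than as a grammar, so this EBNF is a covering
reconstruction; two decisions deserve mention. Keywords are matched
case-insensitively on input and always emitted uppercase, while chemical
names are preserved verbatim (nomenclature is case-significant). Items in a
`with`-list are split only on *top-level* `" and "` — `and` inside
parentheses stays inside a name, because amounts and trivial-name
abbreviations live in parentheses. An amount is recognized only when the
trailing parenthesis is space-separated and starts like a quantity, so
`tetrakis(triphenylphosphine)palladium(0)` parses as one name while
`EDC (374 mg)` splits into name and amount. Whether the `PURIFY` ratio is
its own slot is not observable from examples; it is modeled as optional
ratio text after the solvent list.

The round-trip contract is the module's central invariant: for every
grammar-conforming string, `serialize_actions(parse_structured(s))` equals
`normalize_structured(s)` (whitespace collapsed, keywords uppercased, one
trailing period), and parsing is deterministic.

```{r}
s <- "QUENCH with saturated aqueous NH4Cl; EXTRACT with CH2Cl2."
identical(serialize_actions(parse_structured(s)), s)
```

## Admission rules

`admissible_procedure()` applies five rules; a paragraph is admitted iff
none is violated:

* **R1** — at least 10 whitespace words (configurable; numbers count).
* **R2** — must not end abruptly. "Abruptly" is operationalized purely as
  missing terminal punctuation (`.` `!` `?`, optionally followed by a
  closing quote or bracket). A linguistic completeness check (e.g. a finite
  verb) was deliberately not attempted: it would trade determinism for
  marginal precision.
* **R3** — no references to other procedures ("following general procedure
  A", "as described in", ...). The phrase list is configurable because
  published sources give examples, not a closed set.
* **R4** — no bare compound references ("Compound 1", "INTERMEDIATE 2").
  A negative lookahead keeps systematic names such as
  "compound 1-benzyl-2-(chloromethyl)pyrrolidine" from matching.
* **R5** — product euphemisms ("title compound", "white solid", "yellow
  crystals", ...) are only allowed when a proper chemical name co-occurs
  *in the same sentence*. The same-sentence reading is the closest testable
  interpretation of "the proper compound name is also provided";
  paragraph-level co-occurrence would admit paragraphs whose product is
  never actually named near the euphemism.

The name test `looks_iupac()` is a surface heuristic: digit locants
(`1-`, `2,3-`), nested brackets, characteristic morphemes (`yl`, `oxy`,
`amino`, `benzo`, `pyridin`, `acid`, halogen prefixes, ...), and multiple
hyphens; at least two features must fire. It is intentionally cheap and
transparent — it gates a rule, it is not a nomenclature validator.

## The synthetic corpus generator

Because the original patent-derived corpora cannot be redistributed at desk
scale, all training and evaluation data here come from
`generate_pairs()`/`generate_negatives()`/`generate_classification_set()`.
Each sentence is composed from per-action templates; a template renders one
natural-language fragment *and* one structured clause from the same slot
values, so slot provenance is exact, every chemical name in the structured
side appears verbatim in the sentence, and every generated target parses in
strict mode. Fragments are chained with the connectives ", then ",
" and then ", ", after which " into a single sentence of up to
`max_clauses_per_sentence` clauses (default 3 — synthesis sentences rarely
carry more actions).

Defaults mirror the study conditions the package targets:

* action sampling weights proportional to the action frequencies observed
  in large patent corpora (`default_action_weights()`: Add dominates at
  ~28% of clauses; Sonicate and OtherLanguage are three orders rarer);
* a positive fraction of 0.336 for classification sets;
* seed lexicons shipped as plain-text files (≈120 compounds, 24 solvents,
  temperature notations, duration units, drying agents).

Augmentation (`augment_pair()`) produces up to four variants per pair by
substituting surfaces from the four substitution classes — temperatures,
durations, solvents, compound names — identically on both sides, never
touching the action-type sequence. The cap of four variants per instance is
part of the study conditions. The per-instance augmentation multiplicity in
the original large-scale datasets is not fully determined by their printed
totals, so `k` is an explicit argument rather than a constant.

The 80/10/10 splitter uses `val = round(0.1·N)`, `test = round(0.1·N)`,
`train = N − val − test`. This rounding rule is reverse-engineered from the
two published splits it must reproduce — (16,159, 2,020, 2,020) from
N = 20,199 and (2,459,230, 307,404, 307,404) from N = 3,074,038 — and is
pinned by tests.

What the generator does *not* emulate: real patent prose style (passive
free variation, OCR noise, cross-sentence anaphora beyond `SLN`,
enumerated compound references inside admissible paragraphs). Passing
desk-scale tests therefore demonstrates that the machinery — grammar,
tokenizer, networks, metrics, extraction — is correct and learnable, not
that the shipped desk presets would reach the published accuracy on real
patents.

## Subword tokenization

`train_subword()` learns a unigram-language-model segmentation shared by
source sentences and structured targets (one vocabulary, enabling tied
embeddings). Words are marked with the `▁` whitespace marker; pieces never
cross word boundaries. Training seeds candidates from frequent substrings,
runs EM on the segmentation lattice of the unique corpus words, prunes to
the requested vocabulary, and re-estimates. Three policy choices:

* **Case is preserved.** Action keywords are uppercase on the target side
  and chemical nomenclature is case-significant, so lowercasing would
  destroy information the models need.
* **Digits are never split** (default): cut points inside a digit run are
  forbidden and observed digit runs are mandatory pieces, so amounts like
  `10 mL` keep `10` intact. `split_digits = TRUE` inverts the policy for
  comparison.
* **Byte fallback**: all 256 raw-byte pieces are reserved, so any
  character — including symbols never seen in training — encodes and
  round-trips losslessly. No input is unrepresentable.
* **No normalization** (no NFKC); round-trip identity is the contract.

## Neural models

No deep-learning framework is involved: layers (embedding, GRU/LSTM cells,
bidirectional wrappers, layer normalization, multi-head attention,
feed-forward blocks) implement explicit forward and backward passes on base
R matrices, with the batched attention inner loop in compiled code
(`src/attention.cpp`). Every layer and every full architecture is verified
against central-difference numerical gradients in the test suite. Training
is bit-for-bit reproducible given the config seed, which is why the
importance-monotonicity and ensemble checks use seed sets rather than a
nondeterministic backend.

**Classifier** (`train_classifier()`): embedding → dropout → GRU / LSTM /
BiLSTM (final hidden state; both directions' final states concatenated for
BiLSTM) or transformer-encoder blocks with mean-pooling over non-pad
positions (the pooling choice is not dictated by the architecture; masked
mean-pooling is the conventional default) → ReLU feed-forward → single
logit. The loss is binary cross-entropy with the positive-class loss
multiplied by the *importance* factor (typical search range 0.5–3) to
counter the ~1:2 class imbalance. Early stopping monitors validation
accuracy with patience 7 by default and restores the best epoch's weights;
`stopped_epoch − best_epoch` equals the patience whenever a run stops
early.

**Seq2seq converter** (`train_seq2seq()`): three architectures.
The `rnn` variant is an LSTM encoder compressing the source into a
fixed-length context vector that initializes an LSTM decoder — deliberately
without attention, preserving the known degradation on long inputs that
motivates the transformer. `birnn` uses a BiLSTM encoder whose
concatenated final states are projected to the decoder size. `transformer`
is a pre-norm encoder-decoder with causal self-attention and
cross-attention, trained with teacher forcing and token-level
cross-entropy; no label smoothing and no length penalty (defaults chosen
in the absence of evidence either way). Decoding is greedy by default
(deterministic); beam search (default width 4) returns the highest-scoring
completed hypothesis under length-normalized log-probability.

Published optimal hyper-parameter combinations are available as presets
(`classifier_presets()`, `seq2seq_presets()`), including the full-scale
transformer (6 stacks, 8 heads, model size 512, feed-forward 2,048,
learning rate 0.005, batch 4,096). Those settings assume GPU-scale
resources; the shipped *desk presets* are the package's own sizing for
single-CPU work and are what the tests train:

* `desk_classifier_config()` — BiLSTM, vocabulary 2,000, embedding 8,
  hidden 16, feed-forward 8, importance 2, batch 128, paragraphs truncated
  at 64 pieces;
* `desk_seq2seq_config()` — transformer with 2 stacks, 4 heads, model
  dimension 64, feed-forward 256, Adam at 10⁻³, batch 64, length caps 80.
  Model dimension 64 (rather than 128) keeps a 16,000-pair training run
  around ten minutes on one CPU while still reaching corpus BLEU ≥ 0.94 on
  the held-out synthetic split in the pilot configuration.

Problem sizes used by the automated checks, chosen once as the package's
desk-scale study conditions: the seq2seq contract trains on a
20,000-pair corpus (16,000 train / 2,000 validation / 2,000 test, subword
model fitted on the text of 4,000 pairs, 5 epochs); the classifier
contract trains a 5-seed ensemble on 4,000-paragraph classification sets;
parameter-recovery scans use 1,000 generated pairs.

## Evaluation

All formulas are implemented from their definitions and cross-checked:

* the **random baseline** is the accuracy of a labeler drawing from the
  empirical class distribution, \(\sum_i P(y_i)^2\); the **majority
  baseline** is \(\max_i P(y_i)\). For a 0.336/0.664 binary split these
  give 0.5538 (printed truncated as 0.553) and 0.664;
* accuracy/precision/recall/F1 from the confusion counts with positive
  class 1; zero-denominator metrics return 0 and are flagged;
* **corpus BLEU**: modified (clipped) n-gram precisions up to order 4
  pooled over the corpus, uniform weights, brevity penalty
  \(e^{1-r/c}\) for \(c \le r\) with corpus-total token counts \(r, c\).
  Two policy decisions: no smoothing (a zero pooled precision zeroes the
  score — a `smoothing` flag exists for exploration but is off in all
  shipped checks), and corpus-level rather than sentence-level pooling
  (the brevity penalty is defined on corpus totals). A degenerate corpus
  with fewer tokens than the maximum order restricts the geometric mean to
  the orders that occur, so identity still scores 1. The implementation
  agrees with an independent Python reference implementation
  (`inst/oracle/bleu_oracle.py`) to 10⁻⁶ on randomized corpora;
* **ROUGE-L**: longest-common-subsequence F-score with β = 1 per pair,
  arithmetic-mean aggregated over the corpus (the per-pair formula is
  standard; the aggregation is a package decision). The LCS dynamic
  program is verified against exhaustive subsequence enumeration;
* **exact-match accuracy** after normalization (whitespace collapsed, one
  trailing period), matching how structured strings are compared
  everywhere else.

Tokenization for both text metrics is whitespace on normalized text — the
structured language is whitespace-friendly, and nothing finer is
warranted.

The reference baselines 0.553/0.664 follow from a 0.336/0.664 class
distribution, and that distribution — not any particular raw label count —
is what the generator's `positive_fraction` default encodes and what the
automated checks reproduce.

## Extraction and the pipeline

`collect_reactants()` reads Add/MakeSolution clauses in order, skips `SLN`,
deduplicates to the first occurrence, and removes stoplist solvents —
matching case-insensitively after stripping trailing parenthesized
qualifiers, so `tetrahydrofuran (THF)` matches stoplist entry
`tetrahydrofuran`. Whether MakeSolution's solvent is excluded by rule or
only via the stoplist cannot be determined from published descriptions;
the package uses the stoplist only, and the shipped stoplist covers the
full solvent lexicon. `collect_product()` takes the first YIELD clause
(extra YIELDs warn). `to_smiles()` resolves names through a local
two-column TSV dictionary — exact match first, then case-insensitive —
and never drops unresolved names; external name-translation services are
deliberately out of scope (no network dependency in tests), but the
dictionary interface is the plug-point for them.

`run_pipeline()` chains everything: dedupe (normalized-text hash, first
occurrence kept) → admission rules or trained classifier → rule-based
sentence splitting (terminal punctuation at parenthesis depth zero,
followed by whitespace and a capital or digit, guarded by an abbreviation
list; spans are 0-based half-open) → per-sentence translation → clause
lists joined with `"; "` into one paragraph-level structured string (the
recomposition is a package decision; sources imply but never state it) →
extraction. Paragraphs whose structured output fails even lenient parsing
are quarantined, never silently dropped; records containing InvalidAction
or FollowOtherProcedure are excluded by default (`exclude_invalid`),
following the practice of excluding content a converter cannot sensibly
translate.

The `rule_oracle` converter deserves emphasis: it inverts the generator's
templates with regular expressions and is the exact inverse of
`generate_pairs()` on generated text. Composed with the generator it is
the identity, which gives every downstream stage a converter-independent
test path — extraction and reporting can be validated with no trained
model in the loop.

## Numerical and degenerate-input choices

* Attention softmax subtracts row maxima; masked positions get −∞ before
  normalization. Pad queries never influence pooled representations or
  the loss.
* The unigram EM floors expected counts at 10⁻⁶ to keep log-probabilities
  finite; byte pieces carry a large fixed penalty so learned pieces always
  win when available.
* An unseen digit run (never observed in training) cannot be kept whole by
  any piece; segmentation then relaxes to per-character digits rather than
  failing.
* `round()` (banker's rounding) is used by the splitter; both published
  splits are insensitive to the half-even/half-up distinction.
* Ties in greedy decoding resolve to the lowest token id (`max.col` with
  deterministic tie-breaking via the first maximum).
* Empty inputs raise typed conditions (`chemactions_error_empty_input`,
  etc.) rather than returning sentinel values.

## Known limitations

* The grammar is a reconstruction: real converter output may use slot
  orders or keywords for rare actions (PH, Degas, Microwave) that differ
  from this EBNF; lenient parsing degrades such clauses to carrying their
  payload in `free_params` rather than typed slots.
* The admission rules are surface heuristics; R5 in particular inherits
  the precision of `looks_iupac()`.
* Desk presets are sized for CPUs; reproducing the published full-scale
  scores would require the full-scale presets, the original corpora and
  GPU training, all out of scope here.
* The recurrent seq2seq paths are faithful to the fixed-length-context
  design and therefore underperform the transformer on long sentences by
  construction.
* The name dictionary ships as a small demonstration set; serious use
  should point `read_name_dictionary()` at a real dictionary.
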