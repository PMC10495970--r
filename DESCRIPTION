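Package: chemactions
Title: Structured Action Extraction from Chemical Synthesis Procedures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for turning free-text organic synthesis procedures into
    structured action sequences and a tabular reaction dataset. Provides a
    formal grammar, parser and serializer for a 28-action procedure language;
    rule-based admission filters for deciding whether a patent paragraph is a
    well-formed synthesis procedure; a synthetic paired-corpus generator with
    slot-based data augmentation; a unigram-language-model subword tokenizer
    with byte fallback; desk-scale recurrent and transformer networks for
    paragraph classification and sentence-to-structure translation, trained
    with class-importance weighting and early stopping; corpus BLEU, ROUGE-L,
    exact-match and classification metrics; and reactant/product/SMILES
    extraction from parsed action sequences via a local name dictionary.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Config/testthat/edition: 3
RoxygenNote: 7.3.3
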