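# Evaluation formulas: baselines, classification metrics, corpus BLEU,
# ROUGE-L, exact-match accuracy.

#' Random and majority baselines for a label multiset
#'
#' \code{random_baseline} is the accuracy of a labeler that draws labels
#' from the empirical class distribution: the sum of squared class
#' probabilities.  \code{majority_baseline} is the accuracy of always
#' predicting the most frequent class: the maximum class probability.
#'
#' @param labels Non-empty vector of class labels.
#' @return A single number in (0, 1].
#' @export
#' @examples
#' random_baseline(c(rep(0, 664), rep(1, 336)))    # 0.553792
#' majority_baseline(c(rep(0, 664), rep(1, 336)))  # 0.664
random_baseline <- function(labels) {
  if (!length(labels)) stop_chemactions("empty_labels", "labels must be non-empty")
  p <- table(labels) / length(labels)
  sum(p^2)
}

#' @rdname random_baseline
#' @export
majority_baseline <- function(labels) {
  if (!length(labels)) stop_chemactions("empty_labels", "labels must be non-empty")
  p <- table(labels) / length(labels)
  max(p)
}

#' Binary classification metrics
#'
#' Accuracy, precision, recall and F1 from the confusion counts with the
#' positive class equal to 1.  Zero-denominator metrics are returned as 0
#' and flagged via the \code{undefined} attribute.
#'
#' @param y_true,y_pred Equal-length binary vectors.
#' @return Named list with \code{accuracy}, \code{precision}, \code{recall},
#'   \code{f1}, \code{counts} (tp/tn/fp/fn) and \code{undefined} (character
#'   vector of metrics with zero denominator).
#' @export
classification_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop_chemactions("length_mismatch", "y_true and y_pred differ in length")
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1)))
    stop_chemactions("data", "labels must be binary (0/1)")
  tp <- sum(y_true == 1 & y_pred == 1)
  tn <- sum(y_true == 0 & y_pred == 0)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  undefined <- character(0)
  div <- function(num, den, metric) {
    if (den == 0) { undefined <<- c(undefined, metric); return(0) }
    num / den
  }
  precision <- div(tp, tp + fp, "precision")
  recall <- div(tp, tp + fn, "recall")
  f1 <- div(2 * precision * recall, precision + recall, "f1")
  list(accuracy = (tp + tn) / (tp + tn + fp + fn),
       precision = precision, recall = recall, f1 = f1,
       counts = c(tp = tp, tn = tn, fp = fp, fn = fn),
       undefined = undefined)
}

ws_tokens <- function(x) {
  x <- squish(x)
  if (!nzchar(x)) return(character(0))
  strsplit(x, " ", fixed = TRUE)[[1]]
}

ngram_counts <- function(tokens, n) {
  len <- length(tokens) - n + 1
  if (len < 1) return(integer(0))
  grams <- vapply(seq_len(len), function(i)
    paste(tokens[i:(i + n - 1)], collapse = "\u0001"), character(1))
  table(grams)
}

#' Corpus-level BLEU with brevity penalty
#'
#' Modified (clipped) n-gram precisions up to order 4 pooled over the whole
#' corpus, combined as their geometric mean with uniform weights and
#' multiplied by the brevity penalty \eqn{BP = \min(1, e^{1 - r/c})}, where
#' \eqn{r} and \eqn{c} are the corpus-total reference and hypothesis token
#' counts.  No smoothing: if any pooled precision is zero the score is zero
#' (a \code{smoothing} flag adds +1 Laplace counts for exploratory use).
#'
#' @param references,hypotheses Equal-length character vectors, one
#'   reference per hypothesis; whitespace tokenization.
#' @param max_n Maximum n-gram order (default 4).
#' @param smoothing Logical, default \code{FALSE}.
#' @return A list of class \code{bleu_report}: \code{bleu},
#'   \code{precisions}, \code{brevity_penalty}, \code{ref_len},
#'   \code{hyp_len}.
#' @export
#' @examples
#' corpus_bleu("a b c d e", "a b c d")$bleu  # exp(1 - 5/4)
corpus_bleu <- function(references, hypotheses, max_n = 4, smoothing = FALSE) {
  if (length(references) != length(hypotheses))
    stop_chemactions("length_mismatch", "references and hypotheses differ in length")
  if (!length(references))
    stop_chemactions("empty_corpus", "empty corpus")
  ref_tok <- lapply(references, ws_tokens)
  hyp_tok <- lapply(hypotheses, ws_tokens)
  r <- sum(lengths(ref_tok)); c_ <- sum(lengths(hyp_tok))
  match_n <- numeric(max_n); total_n <- numeric(max_n)
  for (i in seq_along(ref_tok)) {
    for (n in seq_len(max_n)) {
      hyp_counts <- ngram_counts(hyp_tok[[i]], n)
      if (!length(hyp_counts)) next
      ref_counts <- ngram_counts(ref_tok[[i]], n)
      clipped <- pmin(hyp_counts,
                      ifelse(is.na(ref_counts[names(hyp_counts)]), 0,
                             ref_counts[names(hyp_counts)]))
      match_n[n] <- match_n[n] + sum(clipped)
      total_n[n] <- total_n[n] + sum(hyp_counts)
    }
  }
  if (smoothing) { match_n <- match_n + 1; total_n <- total_n + 1 }
  precisions <- ifelse(total_n > 0, match_n / total_n, 0)
  bp <- if (c_ > r) 1 else if (c_ == 0) 0 else exp(1 - r / c_)
  # degenerate corpora shorter than max_n tokens: use the orders that occur
  orders <- which(total_n > 0)
  bleu <- if (!length(orders) || any(precisions[orders] == 0)) 0 else
    bp * exp(sum(log(precisions[orders])) / length(orders))
  structure(list(bleu = bleu, precisions = precisions, brevity_penalty = bp,
                 ref_len = r, hyp_len = c_), class = "bleu_report")
}

lcs_length <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0) return(0L)
  prev <- integer(nb + 1)
  for (i in seq_len(na)) {
    cur <- integer(nb + 1)
    match_row <- c(0L, (a[i] == b))
    for (j in seq_len(nb)) {
      cur[j + 1] <- if (match_row[j + 1]) prev[j] + 1L else max(prev[j + 1], cur[j])
    }
    prev <- cur
  }
  prev[nb + 1]
}

#' ROUGE-L (longest common subsequence) F-score
#'
#' LCS computed by dynamic programming on whitespace tokens;
#' precision = LCS/|hypothesis|, recall = LCS/|reference|, combined with
#' beta = 1.  For vectors, the corpus score is the arithmetic mean of the
#' per-pair scores.
#'
#' @param reference,hypothesis Character vectors of equal length.
#' @return Numeric in [0, 1]: mean per-pair ROUGE-L.
#' @export
#' @examples
#' rouge_l("A B C D", "A C D E")  # 0.75
rouge_l <- function(reference, hypothesis) {
  if (length(reference) != length(hypothesis))
    stop_chemactions("length_mismatch", "reference and hypothesis differ in length")
  if (!length(reference)) stop_chemactions("empty_text", "empty input")
  scores <- vapply(seq_along(reference), function(i) {
    a <- ws_tokens(reference[i]); b <- ws_tokens(hypothesis[i])
    if (!length(a) || !length(b))
      stop_chemactions("empty_text", "cannot score an empty text")
    l <- lcs_length(a, b)
    if (l == 0) return(0)
    p <- l / length(b); r <- l / length(a)
    2 * p * r / (p + r)
  }, numeric(1))
  mean(scores)
}

#' Exact-match accuracy after normalization
#'
#' Fraction of hypothesis strings identical to their reference after
#' whitespace collapsing and ensuring a single trailing period.
#'
#' @param references,hypotheses Equal-length character vectors.
#' @return Numeric in [0, 1].
#' @export
exact_match_accuracy <- function(references, hypotheses) {
  if (length(references) != length(hypotheses))
    stop_chemactions("length_mismatch", "references and hypotheses differ in length")
  norm <- function(x) {
    x <- squish(x)
    ifelse(grepl("\\.$", x), x, paste0(x, "."))
  }
  mean(norm(references) == norm(hypotheses))
}
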