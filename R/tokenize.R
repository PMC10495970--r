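# Unigram-language-model subword tokenizer with byte fallback.
#
# Words are marked with a leading "▁" (the whitespace marker), pieces
# never cross word boundaries, and segmentation maximizes the unigram
# log-likelihood (Viterbi).  Training runs EM on a segmentation lattice over
# the unique words of the corpus, then prunes to the requested vocabulary.
# Single characters, raw-byte pieces <0x00>..<0xFF> and (when digits are not
# split) the digit runs observed in the corpus are mandatory pieces, which
# guarantees open-vocabulary coverage and keeps numbers unsplit.

WS_MARK <- "▁"
SPECIAL_PIECES <- c("<pad>", "<unk>", "<s>", "</s>")
BYTE_PIECES <- sprintf("<0x%02X>", 0:255)

# ---- text <-> marked words -------------------------------------------------

mark_words <- function(text) {
  if (!nzchar(text)) return(character(0))
  parts <- strsplit(text, " ", fixed = TRUE)[[1]]
  if (!length(parts)) parts <- ""
  paste0(WS_MARK, parts)
}

unmark_text <- function(joined) {
  out <- gsub(WS_MARK, " ", joined, fixed = TRUE)
  sub("^ ", "", out)
}

utf8_chars <- function(word) strsplit(word, "", fixed = TRUE)[[1]]

digit_run_ids <- function(chars) {
  is_digit <- grepl("[0-9]", chars)
  run <- integer(length(chars))
  cur <- 0L
  for (i in seq_along(chars)) {
    if (is_digit[i]) {
      if (i == 1 || !is_digit[i - 1]) cur <- cur + 1L
      run[i] <- cur
    }
  }
  run
}

# valid cut positions between chars i and i+1 (TRUE = may cut)
cut_allowed <- function(chars, split_digits) {
  n <- length(chars)
  if (n <= 1) return(logical(0))
  is_digit <- grepl("[0-9]", chars)
  inside_run <- is_digit[-n] & is_digit[-1]
  if (split_digits) rep(TRUE, n - 1) else !inside_run
}

# ---- model object ----------------------------------------------------------

new_subword_model <- function(pieces, logp, split_digits) {
  ord <- seq_along(pieces)
  id_of <- new.env(parent = emptyenv(), size = length(pieces) * 2L)
  for (i in ord) assign(pieces[i], i - 1L, envir = id_of)  # 0-based ids
  structure(list(
    pieces = pieces, logp = logp, vocab_size = length(pieces),
    split_digits = split_digits, id_of = id_of,
    max_piece_chars = max(nchar(pieces[!pieces %in% c(SPECIAL_PIECES, BYTE_PIECES)]),
                          1L),
    cache = new.env(parent = emptyenv())
  ), class = "subword_model")
}

#' @export
print.subword_model <- function(x, ...) {
  cat("<subword_model> ", x$vocab_size, " pieces, split_digits=",
      x$split_digits, "\n", sep = "")
  invisible(x)
}

piece_id <- function(model, piece) {
  get0(piece, envir = model$id_of, ifnotfound = NA_integer_)
}

char_byte_pieces <- function(ch) {
  sprintf("<0x%02X>", as.integer(charToRaw(ch)))
}

# ---- lattice helpers (shared by EM and Viterbi) ----------------------------

word_lattice <- function(chars, piece_logp_env, max_len, ok_cut) {
  # arcs[[j]] : matrix-free list of (i, piece, logp) ending at char j
  n <- length(chars)
  prefix <- c("", cumpaste(chars))
  arcs_i <- vector("list", n); arcs_lp <- vector("list", n)
  arcs_piece <- vector("list", n)
  for (j in seq_len(n)) {
    i_min <- max(1L, j - max_len + 1L)
    is <- i_min:j
    # respect digit-run cuts: arc (i..j) needs valid cuts at i-1|i and j|j+1
    valid <- vapply(is, function(i) {
      (i == 1 || ok_cut[i - 1]) && (j == n || ok_cut[j])
    }, logical(1))
    is <- is[valid]
    if (!length(is)) { arcs_i[[j]] <- integer(0); next }
    subs <- substring(paste(chars, collapse = ""), is, j)
    lps <- vapply(subs, function(s)
      get0(s, envir = piece_logp_env, ifnotfound = NA_real_), numeric(1),
      USE.NAMES = FALSE)
    keep <- !is.na(lps)
    arcs_i[[j]] <- is[keep]; arcs_lp[[j]] <- lps[keep]
    arcs_piece[[j]] <- subs[keep]
  }
  list(i = arcs_i, lp = arcs_lp, piece = arcs_piece, n = n)
}

cumpaste <- function(chars) {
  Reduce(function(a, b) paste0(a, b), chars, accumulate = TRUE)
}

logsumexp <- function(x) {
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

# ---- training --------------------------------------------------------------

#' Train a unigram subword model
#'
#' @param corpus Character vector of text lines (>= 1,000 characters in
#'   total).
#' @param vocab_size Target vocabulary size, including 4 special ids
#'   (pad/unk/bos/eos), 256 raw-byte pieces, all corpus characters and (when
#'   \code{split_digits = FALSE}) the observed digit runs.
#' @param split_digits When \code{FALSE} (default) digit runs are never cut
#'   by segmentation; when \code{TRUE} every digit becomes its own piece.
#' @param max_piece_len Maximum piece length in characters (default 10).
#' @param em_rounds EM rounds before and after pruning (default 2).
#' @return A \code{subword_model}.
#' @export
train_subword <- function(corpus, vocab_size, split_digits = FALSE,
                          max_piece_len = 10, em_rounds = 2) {
  total_chars <- sum(nchar(corpus))
  if (total_chars < 1000)
    stop_chemactions("corpus_too_small",
                     sprintf("corpus has %d characters; >= 1000 required",
                             total_chars))
  if (vocab_size < 100)
    stop_chemactions("config", "vocab_size must be >= 100")

  words <- unlist(lapply(corpus, mark_words), use.names = FALSE)
  wtab <- table(words)
  uwords <- names(wtab)
  wcount <- as.numeric(wtab)
  char_lists <- lapply(uwords, utf8_chars)
  cut_lists <- lapply(char_lists, cut_allowed, split_digits = split_digits)

  # mandatory pieces: every character; digit runs when digits are unsplit
  all_chars <- unique(unlist(char_lists, use.names = FALSE))
  digit_runs <- character(0)
  if (!split_digits) {
    digit_runs <- unique(unlist(lapply(char_lists, function(ch) {
      r <- digit_run_ids(ch)
      if (!any(r > 0)) return(character(0))
      vapply(split(seq_along(ch)[r > 0], r[r > 0]),
             function(idx) paste(ch[idx], collapse = ""), character(1))
    }), use.names = FALSE))
    digit_runs <- digit_runs[nchar(digit_runs) > 1]
  }
  mandatory <- unique(c(all_chars, digit_runs))
  n_reserved <- length(SPECIAL_PIECES) + length(BYTE_PIECES) + length(mandatory)
  if (vocab_size <= n_reserved)
    stop_chemactions("config",
                     sprintf("vocab_size %d cannot hold the %d reserved pieces",
                             vocab_size, n_reserved))

  # candidate substrings (frequency-weighted), respecting digit-run cuts
  cand <- new.env(parent = emptyenv(), size = 65536L)
  for (w in seq_along(uwords)) {
    ch <- char_lists[[w]]; n <- length(ch); cnt <- wcount[w]
    ok <- cut_lists[[w]]
    if (n < 2) next
    word_str <- uwords[w]
    for (i in 1:(n - 1)) {
      if (!(i == 1 || ok[i - 1])) next
      jmax <- min(n, i + max_piece_len - 1L)
      for (j in (i + 1):jmax) {
        if (!(j == n || ok[j])) next
        if (split_digits && any(grepl("[0-9]", ch[i:j]))) next
        s <- substr(word_str, i, j)
        assign(s, (get0(s, envir = cand, ifnotfound = 0) + cnt), envir = cand)
      }
    }
  }
  cand_pieces <- ls(cand)
  cand_freq <- vapply(cand_pieces, get, numeric(1), envir = cand)
  ord <- order(-cand_freq, cand_pieces)
  keep_n <- min(length(ord), (vocab_size - n_reserved) * 3L)
  cand_pieces <- cand_pieces[ord[seq_len(keep_n)]]
  cand_freq <- cand_freq[ord[seq_len(keep_n)]]
  cand_pieces <- setdiff(cand_pieces, mandatory)

  run_em <- function(pieces, init_counts, rounds) {
    counts <- init_counts
    for (r in seq_len(rounds)) {
      logp <- log(pmax(counts, 1e-6)) - log(sum(pmax(counts, 1e-6)))
      env <- new.env(parent = emptyenv(), size = length(pieces) * 2L)
      for (i in seq_along(pieces)) assign(pieces[i], logp[i], envir = env)
      newc <- stats::setNames(numeric(length(pieces)), pieces)
      for (w in seq_along(uwords)) {
        lat <- word_lattice(char_lists[[w]], env, max_piece_len, cut_lists[[w]])
        n <- lat$n
        alpha <- c(0, rep(-Inf, n))
        for (j in seq_len(n)) {
          if (!length(lat$i[[j]])) next
          alpha[j + 1] <- logsumexp(alpha[lat$i[[j]]] + lat$lp[[j]])
        }
        if (!is.finite(alpha[n + 1])) next
        beta <- c(rep(-Inf, n), 0)
        for (j in rev(seq_len(n))) {
          # arcs starting at j end at j..j+L-1; collect arcs with i == j
          acc <- -Inf
          for (j2 in j:min(n, j + max_piece_len - 1L)) {
            sel <- which(lat$i[[j2]] == j)
            if (length(sel))
              acc <- logsumexp(c(acc, lat$lp[[j2]][sel] + beta[j2 + 1]))
          }
          beta[j] <- acc
        }
        z <- alpha[n + 1]
        for (j in seq_len(n)) {
          if (!length(lat$i[[j]])) next
          post <- exp(alpha[lat$i[[j]]] + lat$lp[[j]] + beta[j + 1] - z)
          for (k in seq_along(post)) {
            p <- lat$piece[[j]][k]
            newc[p] <- newc[p] + post[k] * wcount[w]
          }
        }
      }
      counts <- newc
    }
    counts
  }

  pieces0 <- c(mandatory, cand_pieces)
  counts0 <- c(rep(1, length(mandatory)),
               cand_freq[match(cand_pieces, names(cand_freq))])
  names(counts0) <- pieces0
  counts1 <- run_em(pieces0, counts0, em_rounds)

  # prune: mandatory pieces stay; best candidates fill the remaining budget
  budget <- vocab_size - length(SPECIAL_PIECES) - length(BYTE_PIECES) -
    length(mandatory)
  cand_final_counts <- counts1[cand_pieces]
  ord2 <- order(-cand_final_counts, cand_pieces)
  kept <- cand_pieces[ord2[seq_len(min(budget, length(cand_pieces)))]]
  if (length(kept) < budget)
    stop_chemactions("vocab_too_large",
                     sprintf("requested vocab_size %d exceeds the %d attainable pieces",
                             vocab_size,
                             n_reserved + length(SPECIAL_PIECES) + length(BYTE_PIECES) +
                               length(cand_pieces)))

  pieces2 <- c(mandatory, kept)
  counts2 <- run_em(pieces2, counts1[pieces2], em_rounds)
  counts2 <- pmax(counts2, 1e-6)
  logp2 <- log(counts2) - log(sum(counts2))

  all_pieces <- c(SPECIAL_PIECES, BYTE_PIECES, pieces2)
  # byte pieces get a strong penalty so learned pieces are preferred
  all_logp <- c(rep(-1e9, length(SPECIAL_PIECES)),
                rep(min(logp2) - 20, length(BYTE_PIECES)),
                unname(logp2))
  new_subword_model(all_pieces, all_logp, split_digits)
}

# ---- encoding --------------------------------------------------------------

logp_env_of <- function(model) {
  env <- get0("logp_env", envir = model$cache)
  if (is.null(env)) {
    env <- new.env(parent = emptyenv(), size = model$vocab_size * 2L)
    core <- !(model$pieces %in% c(SPECIAL_PIECES, BYTE_PIECES))
    for (i in which(core)) assign(model$pieces[i], model$logp[i], envir = env)
    assign("logp_env", env, envir = model$cache)
  }
  env
}

viterbi_word <- function(model, word, relax_digit_runs = FALSE) {
  chars <- utf8_chars(word)
  n <- length(chars)
  env <- logp_env_of(model)
  ok <- if (relax_digit_runs) rep(TRUE, max(n - 1, 0))
        else cut_allowed(chars, model$split_digits)
  max_len <- model$max_piece_chars
  # per-character fallback cost (byte pieces)
  byte_lp <- model$logp[match("<0x41>", model$pieces)]
  best <- c(0, rep(-Inf, n))
  back_i <- integer(n); back_piece <- vector("list", n)
  word_str <- word
  for (j in seq_len(n)) {
    i_min <- max(1L, j - max_len + 1L)
    for (i in i_min:j) {
      if (!((i == 1 || ok[i - 1]) && (j == n || ok[j]))) next
      if (model$split_digits && j > i && any(grepl("[0-9]", chars[i:j]))) next
      s <- substr(word_str, i, j)
      lp <- get0(s, envir = env, ifnotfound = NA_real_)
      if (is.na(lp)) next
      cand <- best[i] + lp
      if (cand > best[j + 1]) {
        best[j + 1] <- cand; back_i[j] <- i; back_piece[[j]] <- s
      }
    }
    # byte fallback for the single character ending at j
    if (!is.finite(best[j + 1]) ||
        best[j] + byte_lp * 4 > best[j + 1]) {
      bp <- char_byte_pieces(chars[j])
      cand <- best[j] + byte_lp * length(bp)
      if (cand > best[j + 1] && (j == n || ok[j] || relax_digit_runs) &&
          (j == 1 || ok[j - 1] || relax_digit_runs) &&
          is.na(get0(chars[j], envir = env, ifnotfound = NA_real_))) {
        best[j + 1] <- cand; back_i[j] <- j; back_piece[[j]] <- bp
      }
    }
  }
  if (!is.finite(best[n + 1])) {
    if (!relax_digit_runs) return(viterbi_word(model, word, TRUE))
    stop_chemactions("config", sprintf("cannot segment word '%s'", word))
  }
  pieces <- list(); j <- n
  while (j >= 1) {
    pieces <- c(list(back_piece[[j]]), pieces)
    j <- back_i[j] - 1L
  }
  unlist(pieces, use.names = FALSE)
}

#' Encode text to subword ids
#'
#' Lossless on any input: characters outside the vocabulary are emitted as
#' raw-byte pieces.
#'
#' @param model A \code{subword_model}.
#' @param text A single string.
#' @return Integer vector of 0-based piece ids.
#' @export
subword_encode <- function(model, text) {
  stopifnot(inherits(model, "subword_model"))
  if (!nzchar(text)) return(integer(0))
  words <- mark_words(text)
  pieces <- unlist(lapply(words, function(w) {
    hit <- get0(w, envir = model$cache)
    if (is.null(hit)) {
      hit <- viterbi_word(model, w)
      assign(w, hit, envir = model$cache)
    }
    hit
  }), use.names = FALSE)
  ids <- vapply(pieces, function(p) piece_id(model, p), integer(1),
                USE.NAMES = FALSE)
  ids
}

#' Decode subword ids back to text
#'
#' @param model A \code{subword_model}.
#' @param ids Integer vector of 0-based piece ids.
#' @return The decoded string.
#' @export
subword_decode <- function(model, ids) {
  stopifnot(inherits(model, "subword_model"))
  if (!length(ids)) return("")
  if (any(ids < 0 | ids >= model$vocab_size))
    stop_chemactions("invalid_id",
                     sprintf("piece id out of range [0, %d)", model$vocab_size))
  pieces <- model$pieces[ids + 1L]
  pieces <- pieces[!pieces %in% SPECIAL_PIECES]
  out <- raw(0)
  for (p in pieces) {
    if (grepl("^<0x[0-9A-F]{2}>$", p)) {
      out <- c(out, as.raw(strtoi(substr(p, 4, 5), 16L)))
    } else {
      out <- c(out, charToRaw(p))
    }
  }
  txt <- rawToChar(out)
  Encoding(txt) <- "UTF-8"
  unmark_text(txt)
}

#' Special token ids of a subword model
#' @param model A \code{subword_model}.
#' @return Named integer vector: pad, unk, bos, eos.
#' @export
subword_specials <- function(model) {
  c(pad = 0L, unk = 1L, bos = 2L, eos = 3L)
}

#' Mean pieces per word over a corpus
#' @param model A \code{subword_model}.
#' @param corpus Character vector of lines.
#' @return Average number of pieces per whitespace word.
#' @export
pieces_per_word <- function(model, corpus) {
  n_words <- sum(vapply(corpus, function(s) length(mark_words(s)), integer(1)))
  n_pieces <- sum(vapply(corpus, function(s) length(subword_encode(model, s)),
                         integer(1)))
  n_pieces / n_words
}

# ---- model IO --------------------------------------------------------------

#' Save a subword model as a piece-list text file
#' @param model A \code{subword_model}.
#' @param path Output file (TSV: piece, logp; header lines carry metadata).
#' @export
save_subword <- function(model, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("#vocab_size\t%d", model$vocab_size), con)
  writeLines(sprintf("#split_digits\t%d", as.integer(model$split_digits)), con)
  writeLines(sprintf("%s\t%.17g", model$pieces, model$logp), con)
  invisible(path)
}

#' Load a subword model saved by \code{\link{save_subword}}
#' @param path Input file.
#' @return A \code{subword_model}.
#' @export
load_subword <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  split_digits <- as.logical(as.integer(
    sub("^#split_digits\t", "", meta[startsWith(meta, "#split_digits")])))
  parts <- strsplit(body, "\t", fixed = TRUE)
  pieces <- vapply(parts, `[[`, character(1), 1)
  logp <- as.numeric(vapply(parts, `[[`, character(1), 2))
  new_subword_model(pieces, logp, split_digits)
}
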