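# Sequence-to-sequence converter: free-text synthesis sentences to
# structured action strings.
#
# Three architectures: "rnn" (LSTM encoder compressing the source into a
# fixed-length context vector that initializes an LSTM decoder — no
# attention, with the known long-input limitation that entails), "birnn"
# (BiLSTM encoder, LSTM decoder, concatenated final states projected to the
# decoder size), and "transformer" (encoder-decoder with causal
# self-attention and cross-attention).  Source and target share one subword
# vocabulary, so a single embedding matrix is used for both sides.

#' Seq2seq configuration
#'
#' @param arch One of \code{"transformer"}, \code{"rnn"}, \code{"birnn"}.
#' @param vocab_size Shared source/target vocabulary size.
#' @param embedding_dim Embedding (and, for the transformer, model)
#'   dimension.
#' @param encoder_size,decoder_size Recurrent hidden sizes (rnn/birnn).
#' @param stacks Number of transformer encoder and decoder blocks.
#' @param heads Attention heads (must divide \code{embedding_dim}).
#' @param ff_size Transformer feed-forward size.
#' @param learning_rate Optimizer learning rate.
#' @param max_src_len,max_tgt_len Length caps in pieces (>= 1).
#' @param decoding \code{"greedy"} or \code{"beam"}.
#' @param beam_width Beam width (>= 1) when \code{decoding = "beam"}.
#' @param batch_size,optimizer,patience,max_epochs,seed Training controls,
#'   as in \code{\link{classifier_config}}.
#' @return An object of class \code{seq2seq_config}.
#' @export
seq2seq_config <- function(arch = c("transformer", "rnn", "birnn"),
                           vocab_size = 2000, embedding_dim = 64,
                           encoder_size = 64, decoder_size = 64,
                           stacks = 2, heads = 4, ff_size = 256,
                           learning_rate = 1e-3,
                           max_src_len = 80, max_tgt_len = 80,
                           decoding = c("greedy", "beam"), beam_width = 4,
                           batch_size = 64, optimizer = "adam",
                           patience = 7, max_epochs = 10, seed = 1) {
  arch <- match.arg(arch); decoding <- match.arg(decoding)
  if (max_src_len < 1 || max_tgt_len < 1)
    stop_chemactions("config", "length caps must be >= 1")
  if (beam_width < 1) stop_chemactions("config", "beam_width must be >= 1")
  if (arch == "transformer" && embedding_dim %% heads != 0)
    stop_chemactions("config", "heads must divide embedding_dim")
  if (patience < 1) stop_chemactions("config", "patience must be >= 1")
  structure(list(arch = arch, vocab_size = vocab_size,
                 embedding_dim = embedding_dim, encoder_size = encoder_size,
                 decoder_size = decoder_size, stacks = stacks, heads = heads,
                 ff_size = ff_size, learning_rate = learning_rate,
                 max_src_len = max_src_len, max_tgt_len = max_tgt_len,
                 decoding = decoding, beam_width = beam_width,
                 batch_size = batch_size, optimizer = optimizer,
                 patience = patience, max_epochs = max_epochs,
                 seed = as.integer(seed)),
            class = "seq2seq_config")
}

#' Published optimal seq2seq hyper-parameters
#'
#' Recurrent presets per vocabulary size (batch 64), plus the full-scale
#' transformer (6 stacks, 8 heads, model size 512, feed-forward 2,048,
#' learning rate 0.005, batch 4,096).
#'
#' @return data.frame, one row per preset.
#' @export
seq2seq_presets <- function() {
  rec <- function(arch, vocab, emb, enc, dec, opt)
    data.frame(arch = arch, vocab_size = vocab, embedding_dim = emb,
               encoder_size = enc, decoder_size = dec, optimizer = opt,
               stacks = NA, heads = NA, ff_size = NA, learning_rate = 1e-3,
               batch_size = 64, stringsAsFactors = FALSE)
  rbind(
    rec("rnn", 8000, 32, 256, 256, "adam"),
    rec("rnn", 16000, 64, 128, 128, "adamax"),
    rec("rnn", 32000, 64, 128, 128, "rmsprop"),
    rec("birnn", 8000, 64, 256, 128, "adamax"),
    rec("birnn", 16000, 64, 256, 128, "adam"),
    rec("birnn", 32000, 64, 128, 128, "adam"),
    data.frame(arch = "transformer", vocab_size = 16000, embedding_dim = 512,
               encoder_size = NA, decoder_size = NA, optimizer = "adam",
               stacks = 6, heads = 8, ff_size = 2048, learning_rate = 0.005,
               batch_size = 4096, stringsAsFactors = FALSE)
  )
}

#' Desk-scale seq2seq preset
#'
#' A 2-stack, 4-head transformer with model dimension 64, sized so that
#' training on ~20,000 synthetic pairs fits a single-CPU budget.
#' @param ... Overrides.
#' @return A \code{seq2seq_config}.
#' @export
desk_seq2seq_config <- function(...) {
  args <- list(arch = "transformer", vocab_size = 2000, embedding_dim = 64,
               stacks = 2, heads = 4, ff_size = 256, learning_rate = 1e-3,
               batch_size = 64, max_src_len = 80, max_tgt_len = 80,
               max_epochs = 8, patience = 3)
  do.call(seq2seq_config, utils::modifyList(args, list(...)))
}

# ---- parameters ------------------------------------------------------------

init_s2s_params <- function(cfg) {
  V <- cfg$vocab_size; d <- cfg$embedding_dim
  p <- list(E = glorot(V, d))
  if (cfg$arch == "transformer") {
    block <- function() list(
      g1 = rep(1, d), b1 = rep(0, d), mha = init_mha(d, cfg$heads),
      g2 = rep(1, d), b2 = rep(0, d),
      Wf1 = glorot(d, cfg$ff_size), bf1 = rep(0, cfg$ff_size),
      Wf2 = glorot(cfg$ff_size, d), bf2 = rep(0, d))
    dec_block <- function() list(
      g1 = rep(1, d), b1 = rep(0, d), mha = init_mha(d, cfg$heads),
      gx = rep(1, d), bx = rep(0, d), xatt = init_mha(d, cfg$heads),
      g2 = rep(1, d), b2 = rep(0, d),
      Wf1 = glorot(d, cfg$ff_size), bf1 = rep(0, cfg$ff_size),
      Wf2 = glorot(cfg$ff_size, d), bf2 = rep(0, d))
    p$enc <- lapply(seq_len(cfg$stacks), function(i) block())
    p$dec <- lapply(seq_len(cfg$stacks), function(i) dec_block())
    p$g_enc <- rep(1, d); p$b_enc <- rep(0, d)
    p$g_dec <- rep(1, d); p$b_dec <- rep(0, d)
    p$Wout <- glorot(d, V); p$bout <- rep(0, V)
  } else if (cfg$arch == "rnn") {
    p$enc <- init_lstm(d, cfg$encoder_size)
    p$dec <- init_lstm(d, cfg$decoder_size)
    p$Wh <- glorot(cfg$encoder_size, cfg$decoder_size); p$bh <- rep(0, cfg$decoder_size)
    p$Wc <- glorot(cfg$encoder_size, cfg$decoder_size); p$bc <- rep(0, cfg$decoder_size)
    p$Wout <- glorot(cfg$decoder_size, V); p$bout <- rep(0, V)
  } else {
    p$enc_f <- init_lstm(d, cfg$encoder_size)
    p$enc_b <- init_lstm(d, cfg$encoder_size)
    p$dec <- init_lstm(d, cfg$decoder_size)
    p$Wh <- glorot(2 * cfg$encoder_size, cfg$decoder_size); p$bh <- rep(0, cfg$decoder_size)
    p$Wc <- glorot(2 * cfg$encoder_size, cfg$decoder_size); p$bc <- rep(0, cfg$decoder_size)
    p$Wout <- glorot(cfg$decoder_size, V); p$bout <- rep(0, V)
  }
  p
}

# ---- transformer encoder/decoder blocks (shared fwd/bwd helpers) ----------

tf_block_fwd <- function(x, bl, B, T, heads, causal, key_mask) {
  ln1 <- ln_fwd(x, bl$g1, bl$b1)
  at <- mha_fwd(ln1$out, ln1$out, bl$mha, B, T, T, heads,
                causal = causal, key_mask = key_mask)
  x1 <- x + at$out
  ln2 <- ln_fwd(x1, bl$g2, bl$b2)
  f1 <- dense_fwd(ln2$out, bl$Wf1, bl$bf1, "relu")
  f2 <- dense_fwd(f1$out, bl$Wf2, bl$bf2, "linear")
  list(out = x1 + f2$out,
       cache = list(ln1 = ln1, at = at, ln2 = ln2, f1 = f1, f2 = f2))
}

tf_block_bwd <- function(bl, cc, dx) {
  gb <- list()
  d_f2 <- dense_bwd(cc$f2$cache, dx)
  gb$Wf2 <- d_f2$dW; gb$bf2 <- d_f2$db
  d_f1 <- dense_bwd(cc$f1$cache, d_f2$dx)
  gb$Wf1 <- d_f1$dW; gb$bf1 <- d_f1$db
  d_ln2 <- ln_bwd(cc$ln2$cache, d_f1$dx)
  gb$g2 <- d_ln2$dgamma; gb$b2 <- d_ln2$dbeta
  dx1 <- dx + d_ln2$dx
  d_at <- mha_bwd(cc$at$cache, bl$mha, dx1)
  gb$mha <- d_at$grads
  d_ln1 <- ln_bwd(cc$ln1$cache, d_at$dxq + d_at$dxkv)
  gb$g1 <- d_ln1$dgamma; gb$b1 <- d_ln1$dbeta
  list(dx = dx1 + d_ln1$dx, grads = gb[names(bl)])
}

embed_pe <- function(E, ids_flat, T, B, d) {
  x <- E[ids_flat + 1L, , drop = FALSE] * sqrt(d)
  pe <- sinusoidal_pe(T, d)
  x + pe[rep(seq_len(T), B), , drop = FALSE]
}

s2s_encode_fwd <- function(p, cfg, src, training = FALSE) {
  B <- nrow(src$ids); T <- ncol(src$ids)
  if (cfg$arch == "transformer") {
    d <- cfg$embedding_dim
    flat <- as.vector(t(src$ids))
    x <- embed_pe(p$E, flat, T, B, d)
    caches <- vector("list", length(p$enc))
    for (l in seq_along(p$enc)) {
      r <- tf_block_fwd(x, p$enc[[l]], B, T, cfg$heads, FALSE, src$mask)
      x <- r$out; caches[[l]] <- r$cache
    }
    lnf <- ln_fwd(x, p$g_enc, p$b_enc)
    list(enc_out = lnf$out, B = B, T = T, flat = flat,
         caches = caches, lnf = lnf)
  } else if (cfg$arch == "rnn") {
    X <- embed_fwd(p$E, src$ids)
    rn <- lstm_fwd(X, src$mask, p$enc, cfg$encoder_size)
    h0 <- dense_fwd(rn$h_final, p$Wh, p$bh, "tanh")
    c0 <- dense_fwd(rn$c_final, p$Wc, p$bc, "tanh")
    list(h0 = h0$out, c0 = c0$out, B = B, T = T, rn = rn,
         h0c = h0, c0c = c0)
  } else {
    X <- embed_fwd(p$E, src$ids)
    rnf <- lstm_fwd(X, src$mask, p$enc_f, cfg$encoder_size)
    rnb <- lstm_fwd(rev(X), src$mask[, rev(seq_len(T)), drop = FALSE],
                    p$enc_b, cfg$encoder_size)
    hcat <- cbind(rnf$h_final, rnb$h_final)
    ccat <- cbind(rnf$c_final, rnb$c_final)
    h0 <- dense_fwd(hcat, p$Wh, p$bh, "tanh")
    c0 <- dense_fwd(ccat, p$Wc, p$bc, "tanh")
    list(h0 = h0$out, c0 = c0$out, B = B, T = T, rnf = rnf, rnb = rnb,
         h0c = h0, c0c = c0)
  }
}

# decoder forward with teacher forcing; tgt_in ids B x Tt (bos-prefixed)
# logits_rows: optional row subset (into the (B*Tt)-row layout) for which
# output logits are needed; incremental decoding only projects the last
# position of each prefix, which dominates decode cost otherwise
s2s_decode_fwd <- function(p, cfg, enc, tgt_ids_in, tgt_mask, src_mask,
                           logits_rows = NULL) {
  B <- nrow(tgt_ids_in); Tt <- ncol(tgt_ids_in)
  if (cfg$arch == "transformer") {
    d <- cfg$embedding_dim
    flat <- as.vector(t(tgt_ids_in))
    x <- embed_pe(p$E, flat, Tt, B, d)
    caches <- vector("list", length(p$dec))
    for (l in seq_along(p$dec)) {
      bl <- p$dec[[l]]
      ln1 <- ln_fwd(x, bl$g1, bl$b1)
      at <- mha_fwd(ln1$out, ln1$out, bl$mha, B, Tt, Tt, cfg$heads,
                    causal = TRUE, key_mask = tgt_mask)
      x1 <- x + at$out
      lnx <- ln_fwd(x1, bl$gx, bl$bx)
      xat <- mha_fwd(lnx$out, enc$enc_out, bl$xatt, B, Tt, enc$T, cfg$heads,
                     causal = FALSE, key_mask = src_mask)
      x2 <- x1 + xat$out
      ln2 <- ln_fwd(x2, bl$g2, bl$b2)
      f1 <- dense_fwd(ln2$out, bl$Wf1, bl$bf1, "relu")
      f2 <- dense_fwd(f1$out, bl$Wf2, bl$bf2, "linear")
      x <- x2 + f2$out
      caches[[l]] <- list(ln1 = ln1, at = at, lnx = lnx, xat = xat,
                          ln2 = ln2, f1 = f1, f2 = f2)
    }
    lnf <- ln_fwd(x, p$g_dec, p$b_dec)
    h_out <- if (is.null(logits_rows)) lnf$out else
      lnf$out[logits_rows, , drop = FALSE]
    logits <- addbias(h_out %*% p$Wout, p$bout)
    list(logits = logits, flat = flat, caches = caches, lnf = lnf,
         B = B, Tt = Tt)
  } else {
    X <- embed_fwd(p$E, tgt_ids_in)
    rn <- lstm_fwd_h0(X, tgt_mask, p$dec, cfg$decoder_size, enc$h0, enc$c0)
    H <- do.call(rbind, lapply(seq_len(B), function(b)
      do.call(rbind, lapply(rn$H, function(h) h[b, , drop = FALSE]))))
    if (!is.null(logits_rows)) H <- H[logits_rows, , drop = FALSE]
    logits <- addbias(H %*% p$Wout, p$bout)
    list(logits = logits, rn = rn, B = B, Tt = Tt)
  }
}

# LSTM with a provided initial state (used by the decoder)
lstm_fwd_h0 <- function(X_list, mask, p, d_h, h0, c0) {
  T <- length(X_list); B <- nrow(X_list[[1]])
  h <- h0; c_ <- c0
  caches <- vector("list", T); H <- vector("list", T)
  for (t in seq_len(T)) {
    z <- X_list[[t]] %*% p$Wx + h %*% p$Wh
    z <- addbias(z, p$b)
    i <- sigmoid_(z[, 1:d_h, drop = FALSE])
    f <- sigmoid_(z[, d_h + 1:d_h, drop = FALSE])
    o <- sigmoid_(z[, 2 * d_h + 1:d_h, drop = FALSE])
    g <- tanh(z[, 3 * d_h + 1:d_h, drop = FALSE])
    c_new <- f * c_ + i * g
    tc <- tanh(c_new)
    h_new <- o * tc
    m <- mask[, t]
    caches[[t]] <- list(x = X_list[[t]], h_prev = h, c_prev = c_, i = i, f = f,
                        o = o, g = g, c_new = c_new, tc = tc, m = m)
    h <- h_new * m + h * (1 - m)
    c_ <- c_new * m + c_ * (1 - m)
    H[[t]] <- h
  }
  list(H = H, h_final = h, c_final = c_, caches = caches)
}

s2s_backward <- function(p, cfg, enc, dec, dlogits, src, tgt_mask) {
  g <- zeros_like(p)
  B <- dec$B; Tt <- dec$Tt
  if (cfg$arch == "transformer") {
    g$Wout <- crossprod(dec$lnf$out, dlogits)
    g$bout <- colSums(dlogits)
    dx <- dlogits %*% t(p$Wout)
    bk <- ln_bwd(dec$lnf$cache, dx)
    g$g_dec <- bk$dgamma; g$b_dec <- bk$dbeta
    dx <- bk$dx
    d_enc_out <- matrix(0, enc$B * enc$T, cfg$embedding_dim)
    for (l in rev(seq_along(p$dec))) {
      bl <- p$dec[[l]]; cc <- dec$caches[[l]]
      gb <- list()
      d_f2 <- dense_bwd(cc$f2$cache, dx)
      gb$Wf2 <- d_f2$dW; gb$bf2 <- d_f2$db
      d_f1 <- dense_bwd(cc$f1$cache, d_f2$dx)
      gb$Wf1 <- d_f1$dW; gb$bf1 <- d_f1$db
      d_ln2 <- ln_bwd(cc$ln2$cache, d_f1$dx)
      gb$g2 <- d_ln2$dgamma; gb$b2 <- d_ln2$dbeta
      dx2 <- dx + d_ln2$dx
      d_xat <- mha_bwd(cc$xat$cache, bl$xatt, dx2)
      gb$xatt <- d_xat$grads
      d_enc_out <- d_enc_out + d_xat$dxkv
      d_lnx <- ln_bwd(cc$lnx$cache, d_xat$dxq)
      gb$gx <- d_lnx$dgamma; gb$bx <- d_lnx$dbeta
      dx1 <- dx2 + d_lnx$dx
      d_at <- mha_bwd(cc$at$cache, bl$mha, dx1)
      gb$mha <- d_at$grads
      d_ln1 <- ln_bwd(cc$ln1$cache, d_at$dxq + d_at$dxkv)
      gb$g1 <- d_ln1$dgamma; gb$b1 <- d_ln1$dbeta
      dx <- dx1 + d_ln1$dx
      g$dec[[l]] <- gb[names(bl)]  # keep the parameter field order
    }
    dx <- dx * sqrt(cfg$embedding_dim)
    gE <- rowsum(dx, group = dec$flat)
    rows <- as.integer(rownames(gE)) + 1L
    g$E[rows, ] <- g$E[rows, ] + gE
    # encoder backward
    bk <- ln_bwd(enc$lnf$cache, d_enc_out)
    g$g_enc <- bk$dgamma; g$b_enc <- bk$dbeta
    dxe <- bk$dx
    for (l in rev(seq_along(p$enc))) {
      r <- tf_block_bwd(p$enc[[l]], enc$caches[[l]], dxe)
      g$enc[[l]] <- r$grads; dxe <- r$dx
    }
    dxe <- dxe * sqrt(cfg$embedding_dim)
    gE <- rowsum(dxe, group = enc$flat)
    rows <- as.integer(rownames(gE)) + 1L
    g$E[rows, ] <- g$E[rows, ] + gE
    return(g)
  }
  # recurrent paths
  d_h <- cfg$decoder_size
  H <- dec$rn$H
  g$Wout <- matrix(0, d_h, cfg$vocab_size)
  dH <- vector("list", Tt)
  for (t in seq_len(Tt)) {
    rows <- (seq_len(B) - 1) * Tt + t
    drows <- dlogits[rows, , drop = FALSE]
    g$Wout <- g$Wout + crossprod(H[[t]], drows)
    dH[[t]] <- drows %*% t(p$Wout)
  }
  g$bout <- colSums(dlogits)
  bk <- lstm_bwd(dec$rn$caches, p$dec, d_h, dH)
  g$dec <- bk$grads
  dX <- bk$dX
  tgt_ids_in <- attr(dec, "tgt_ids_in")
  g$E <- embed_bwd(p$E, tgt_ids_in, dX)
  dh0 <- bk$dh0; dc0 <- bk$dc0
  dh <- dense_bwd(enc$h0c$cache, dh0)
  dc <- dense_bwd(enc$c0c$cache, dc0)
  g$Wh <- dh$dW; g$bh <- dh$db; g$Wc <- dc$dW; g$bc <- dc$db
  Ts <- enc$T
  dH_zero <- vector("list", Ts)
  if (cfg$arch == "rnn") {
    bke <- lstm_bwd(enc$rn$caches, p$enc, cfg$encoder_size, dH_zero,
                    dh_final = dh$dx, dc_final = dc$dx)
    g$enc <- bke$grads
    g$E <- g$E + embed_bwd(p$E, src$ids, bke$dX)
  } else {
    es <- cfg$encoder_size
    bkef <- lstm_bwd(enc$rnf$caches, p$enc_f, es, dH_zero,
                     dh_final = dh$dx[, 1:es, drop = FALSE],
                     dc_final = dc$dx[, 1:es, drop = FALSE])
    bkeb <- lstm_bwd(enc$rnb$caches, p$enc_b, es, dH_zero,
                     dh_final = dh$dx[, es + 1:es, drop = FALSE],
                     dc_final = dc$dx[, es + 1:es, drop = FALSE])
    g$enc_f <- bkef$grads; g$enc_b <- bkeb$grads
    dXe <- mapply(function(a, b) a + b, bkef$dX, rev(bkeb$dX), SIMPLIFY = FALSE)
    g$E <- g$E + embed_bwd(p$E, src$ids, dXe)
  }
  g
}

# ---- batch assembly --------------------------------------------------------

pairs_to_batches <- function(tok, pairs, cfg) {
  bos <- 2L; eos <- 3L
  src <- lapply(pairs, function(p) {
    ids <- subword_encode(tok, p$sentence)
    if (length(ids) > cfg$max_src_len) ids <- ids[seq_len(cfg$max_src_len)]
    ids
  })
  tgt <- lapply(pairs, function(p) {
    ids <- subword_encode(tok, p$structured)
    if (length(ids) > cfg$max_tgt_len - 1) ids <- ids[seq_len(cfg$max_tgt_len - 1)]
    ids
  })
  list(src = src, tgt = tgt)
}

pad_batch <- function(seqs) {
  B <- length(seqs); T <- max(1L, max(lengths(seqs)))
  ids <- matrix(0L, B, T); mask <- matrix(0, B, T)
  for (b in seq_len(B)) {
    l <- length(seqs[[b]])
    if (l) { ids[b, seq_len(l)] <- seqs[[b]]; mask[b, seq_len(l)] <- 1 }
  }
  list(ids = ids, mask = mask)
}

# teacher-forcing views: input = bos + tgt; output = tgt + eos
tf_views <- function(tgt_seqs) {
  bos <- 2L; eos <- 3L
  tin <- lapply(tgt_seqs, function(x) c(bos, x))
  tout <- lapply(tgt_seqs, function(x) c(x, eos))
  list(tin = pad_batch(tin), tout = pad_batch(tout))
}

s2s_step <- function(params, cfg, tok, src_seqs, tgt_seqs, training = TRUE) {
  src <- pad_batch(src_seqs)
  v <- tf_views(tgt_seqs)
  enc <- s2s_encode_fwd(params, cfg, src, training)
  dec <- s2s_decode_fwd(params, cfg, enc, v$tin$ids, v$tin$mask, src$mask)
  attr(dec, "tgt_ids_in") <- v$tin$ids
  B <- nrow(v$tin$ids); Tt <- ncol(v$tin$ids)
  targets <- as.vector(t(v$tout$ids))
  weights <- as.vector(t(v$tout$mask))
  ls <- softmax_ce(dec$logits, targets, weights)
  pred <- max.col(dec$logits) - 1L
  tok_acc <- sum((pred == targets) * weights) / sum(weights)
  list(enc = enc, dec = dec, src = src, loss = ls, tok_acc = tok_acc,
       tgt_mask = v$tin$mask)
}

#' Train a sequence-to-sequence converter
#'
#' Token-level cross-entropy with teacher forcing over the shared
#' vocabulary; early stopping on validation token accuracy with the
#' configured patience; best-epoch weights restored.  Reproducible given
#' \code{cfg$seed}.
#'
#' @param pairs,val_pairs Lists of \code{\link{corpus_pair}} (targets must
#'   parse in strict mode).
#' @param tok Shared \code{subword_model}.
#' @param cfg A \code{\link{seq2seq_config}}.
#' @param check_targets Validate that all training targets parse in strict
#'   mode before training (default TRUE; disable for speed on trusted
#'   corpora).
#' @param verbose Print per-epoch metrics.
#' @return A \code{trained_model}.
#' @export
train_seq2seq <- function(pairs, val_pairs, tok, cfg = desk_seq2seq_config(),
                          check_targets = TRUE, verbose = FALSE) {
  if (!length(pairs) || !length(val_pairs))
    stop_chemactions("data", "pairs and val_pairs must be non-empty")
  if (tok$vocab_size != cfg$vocab_size)
    stop_chemactions("tokenizer_mismatch",
                     sprintf("tokenizer vocab %d != config vocab %d",
                             tok$vocab_size, cfg$vocab_size))
  if (check_targets) {
    for (p in pairs[seq_len(min(length(pairs), 500))])
      parse_structured(p$structured, "strict")
  }
  tb <- pairs_to_batches(tok, pairs, cfg)
  vb <- pairs_to_batches(tok, val_pairs, cfg)
  n <- length(pairs)

  with_seed(cfg$seed, {
    params <- init_s2s_params(cfg)
    opt <- make_optimizer(cfg$optimizer, cfg$learning_rate)
    es <- early_stopper(cfg$patience)
    history <- NULL
    lens <- lengths(tb$src) + lengths(tb$tgt)
    for (epoch in seq_len(cfg$max_epochs)) {
      # length-bucketed batches (random jitter + shuffled batch order) keep
      # padding small so each batch stays on the fast attention path
      perm <- order(lens + stats::runif(n, 0, 4))
      starts <- seq(1, n, by = cfg$batch_size)
      batch_list <- lapply(starts, function(s)
        perm[s:min(s + cfg$batch_size - 1, n)])
      batch_list <- batch_list[sample.int(length(batch_list))]
      ep_loss <- 0; nb <- 0
      for (bidx in batch_list) {
        st <- s2s_step(params, cfg, tok, tb$src[bidx], tb$tgt[bidx])
        grads <- s2s_backward(params, cfg, st$enc, st$dec, st$loss$dlogits,
                              st$src, st$tgt_mask)
        params <- opt$update(params, grads)
        ep_loss <- ep_loss + st$loss$loss; nb <- nb + 1
      }
      # validation token accuracy, batched
      va_acc <- 0; va_n <- 0
      for (s in seq(1, length(vb$src), by = cfg$batch_size)) {
        bidx <- s:min(s + cfg$batch_size - 1, length(vb$src))
        st <- s2s_step(params, cfg, tok, vb$src[bidx], vb$tgt[bidx],
                       training = FALSE)
        w <- sum(lengths(vb$tgt[bidx])) + length(bidx)
        va_acc <- va_acc + st$tok_acc * w; va_n <- va_n + w
      }
      va_acc <- va_acc / va_n
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = ep_loss / nb,
                                           val_token_accuracy = va_acc))
      if (verbose)
        message(sprintf("epoch %d  loss %.4f  val_tok_acc %.4f",
                        epoch, ep_loss / nb, va_acc))
      if (es$note(epoch, va_acc, params)) break
    }
    structure(list(kind = "seq2seq", params = es$env$best_params,
                   config = cfg, history = history,
                   stopped_epoch = nrow(history),
                   best_epoch = es$env$best_epoch,
                   best_val_token_accuracy = es$env$best,
                   tok_hash = tok_fingerprint(tok)),
              class = "trained_model")
  })
}

# ---- decoding --------------------------------------------------------------

# one decoder forward over given prefixes; returns last-position logits
dec_step_logits <- function(p, cfg, enc, prefix_ids, src_mask) {
  B <- nrow(prefix_ids); Tt <- ncol(prefix_ids)
  mask <- matrix(1, B, Tt)
  rows <- (seq_len(B) - 1) * Tt + Tt
  dec <- s2s_decode_fwd(p, cfg, enc, prefix_ids, mask, src_mask,
                        logits_rows = rows)
  dec$logits
}

#' Translate sentences into the structured format
#'
#' Greedy decoding is deterministic; beam search returns the
#' highest-scoring completed hypothesis.  Output stops at the end-of-
#' sequence token or \code{max_tgt_len}.
#'
#' @param model A seq2seq \code{trained_model}.
#' @param tok The shared \code{subword_model}.
#' @param sentences Character vector of source sentences (non-empty).
#' @param decoding \code{"greedy"} or \code{"beam"} (default: model
#'   config).
#' @param beam_width Beam width when beam decoding.
#' @return Character vector of structured strings.
#' @export
translate <- function(model, tok, sentences, decoding = NULL,
                      beam_width = NULL) {
  stopifnot(inherits(model, "trained_model"), model$kind == "seq2seq")
  if (!identical(model$tok_hash, tok_fingerprint(tok)))
    stop_chemactions("tokenizer_mismatch",
                     "model was trained with a different tokenizer")
  if (!length(sentences) || any(!nzchar(trimws(sentences))))
    stop_chemactions("empty_input", "sentences must be non-empty")
  cfg <- model$config
  decoding <- decoding %||% cfg$decoding
  beam_width <- beam_width %||% cfg$beam_width
  if (decoding == "greedy") {
    out <- character(length(sentences))
    bs <- cfg$batch_size
    for (s in seq(1, length(sentences), by = bs)) {
      bidx <- s:min(s + bs - 1, length(sentences))
      out[bidx] <- greedy_decode_batch(model, tok, sentences[bidx])
    }
    out
  } else {
    vapply(sentences, function(s) beam_decode_one(model, tok, s, beam_width),
           character(1), USE.NAMES = FALSE)
  }
}

greedy_decode_batch <- function(model, tok, sentences) {
  cfg <- model$config; p <- model$params
  bos <- 2L; eos <- 3L
  src_seqs <- lapply(sentences, function(s) {
    ids <- subword_encode(tok, s)
    if (length(ids) > cfg$max_src_len) ids <- ids[seq_len(cfg$max_src_len)]
    ids
  })
  src <- pad_batch(src_seqs)
  enc <- s2s_encode_fwd(p, cfg, src, FALSE)
  B <- length(sentences)
  prefix <- matrix(bos, B, 1)
  outs <- vector("list", B)
  active <- seq_len(B)          # original indices of still-decoding rows
  src_mask <- src$mask
  for (step in seq_len(cfg$max_tgt_len)) {
    logits <- dec_step_logits(p, cfg, enc, prefix, src_mask)
    nxt <- max.col(logits) - 1L
    finished <- nxt == eos
    still <- which(!finished)
    for (k in still)
      outs[[active[k]]] <- c(outs[[active[k]]], nxt[k])
    if (!length(still)) break
    if (length(still) < length(active)) {
      # shrink the batch to the unfinished sequences
      active <- active[still]
      prefix <- prefix[still, , drop = FALSE]
      nxt <- nxt[still]
      src_mask <- src_mask[still, , drop = FALSE]
      if (!is.null(enc$enc_out)) {
        T_enc <- enc$T
        rows <- as.vector(vapply(still, function(b)
          ((b - 1) * T_enc + 1):(b * T_enc), integer(T_enc)))
        enc$enc_out <- enc$enc_out[rows, , drop = FALSE]
      } else {
        enc$h0 <- enc$h0[still, , drop = FALSE]
        enc$c0 <- enc$c0[still, , drop = FALSE]
      }
      enc$B <- length(still)
    }
    prefix <- cbind(prefix, nxt)
  }
  vapply(outs, function(ids)
    subword_decode(tok, if (is.null(ids)) integer(0) else ids), character(1))
}

beam_decode_one <- function(model, tok, sentence, beam_width) {
  cfg <- model$config; p <- model$params
  bos <- 2L; eos <- 3L
  ids <- subword_encode(tok, sentence)
  if (length(ids) > cfg$max_src_len) ids <- ids[seq_len(cfg$max_src_len)]
  src <- pad_batch(list(ids))
  enc <- s2s_encode_fwd(p, cfg, src, FALSE)
  beams <- list(list(seq = bos, lp = 0, done = FALSE))
  completed <- list()
  for (step in seq_len(cfg$max_tgt_len)) {
    cand <- list()
    for (bm in beams) {
      if (bm$done) { completed <- c(completed, list(bm)); next }
      prefix <- matrix(bm$seq, 1)
      logits <- dec_step_logits(p, cfg, enc, prefix, src$mask)
      lp <- logits[1, ] - logsumexp(logits[1, ])
      top <- order(lp, decreasing = TRUE)[seq_len(beam_width)]
      for (k in top) {
        tokid <- k - 1L
        cand <- c(cand, list(list(seq = c(bm$seq, tokid),
                                  lp = bm$lp + lp[k],
                                  done = tokid == eos)))
      }
    }
    if (!length(cand)) break
    ord <- order(vapply(cand, `[[`, numeric(1), "lp"), decreasing = TRUE)
    beams <- cand[ord[seq_len(min(beam_width, length(ord)))]]
    if (all(vapply(beams, `[[`, logical(1), "done"))) {
      completed <- c(completed, beams); break
    }
  }
  completed <- c(completed, beams[!vapply(beams, `[[`, logical(1), "done")])
  scores <- vapply(completed, function(b) b$lp / max(1, length(b$seq) - 1),
                   numeric(1))
  best <- completed[[which.max(scores)]]
  out <- best$seq[-1]
  out <- out[out != eos]
  subword_decode(tok, out)
}
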