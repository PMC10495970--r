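# Paragraph classifier: configs, presets, training with class-importance
# weighting and early stopping, and prediction.
#
# Architectures follow the common recipe for this task: embedding layer,
# dropout, a GRU/LSTM/BiLSTM layer (or transformer encoder blocks), a ReLU
# feed-forward layer and a single-logit output trained with binary
# cross-entropy, where the positive (procedure) class loss is multiplied by
# an importance factor to counter class imbalance.

#' Classifier configuration
#'
#' @param arch One of \code{"gru"}, \code{"lstm"}, \code{"bilstm"},
#'   \code{"transformer_encoder"}.
#' @param vocab_size Tokenizer vocabulary size the model expects.
#' @param embedding_dim Embedding dimension.
#' @param recurrent_size Hidden size of the recurrent layer.
#' @param ff_size Feed-forward layer size.
#' @param dropout Dropout rate in [0, 1) applied after the embedding.
#' @param importance Positive-class loss weight (> 0; typical range
#'   0.5-3).
#' @param optimizer One of adam, nadam, sgd, adamax, rmsprop.
#' @param batch_size Minibatch size.
#' @param patience Early-stopping patience in epochs (default 7).
#' @param heads,attention_layers Transformer-encoder geometry (heads must
#'   divide \code{embedding_dim}).
#' @param max_len Maximum paragraph length in pieces (longer inputs are
#'   truncated).
#' @param max_epochs Hard cap on training epochs.
#' @param learning_rate Optimizer learning rate.
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @return An object of class \code{classifier_config}.
#' @export
classifier_config <- function(arch = c("bilstm", "gru", "lstm", "transformer_encoder"),
                              vocab_size = 2000, embedding_dim = 8,
                              recurrent_size = 16, ff_size = 8,
                              dropout = 0.2, importance = 2,
                              optimizer = "rmsprop", batch_size = 64,
                              patience = 7, heads = 2, attention_layers = 1,
                              max_len = 64, max_epochs = 30,
                              learning_rate = 1e-3, seed = 1) {
  arch <- match.arg(arch)
  if (dropout < 0 || dropout >= 1)
    stop_chemactions("config", "dropout must lie in [0, 1)")
  if (importance <= 0) stop_chemactions("config", "importance must be > 0")
  if (patience < 1) stop_chemactions("config", "patience must be >= 1")
  if (arch == "transformer_encoder" && embedding_dim %% heads != 0)
    stop_chemactions("config", "heads must divide embedding_dim")
  structure(list(arch = arch, vocab_size = vocab_size,
                 embedding_dim = embedding_dim,
                 recurrent_size = recurrent_size, ff_size = ff_size,
                 dropout = dropout, importance = importance,
                 optimizer = optimizer, batch_size = batch_size,
                 patience = patience, heads = heads,
                 attention_layers = attention_layers, max_len = max_len,
                 max_epochs = max_epochs, learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "classifier_config")
}

#' Published optimal classifier hyper-parameters
#'
#' The per-vocabulary optimal settings for the GRU/LSTM/BiLSTM and
#' transformer-encoder classifiers (full-scale presets; ReLU feed-forward
#' activation and batch size 64 for the recurrent models).
#'
#' @return data.frame, one row per (arch, vocab_size) combination.
#' @export
classifier_presets <- function() {
  rec <- function(arch, vocab, emb, drop, layer, ff, imp, opt)
    data.frame(arch = arch, vocab_size = vocab, embedding_dim = emb,
               dropout = drop, recurrent_size = layer, ff_size = ff,
               importance = imp, optimizer = opt, batch_size = 64,
               heads = NA, attention_layers = NA, stringsAsFactors = FALSE)
  tra <- function(vocab, emb, batch, heads, layers, imp, opt)
    data.frame(arch = "transformer_encoder", vocab_size = vocab,
               embedding_dim = emb, dropout = 0, recurrent_size = NA,
               ff_size = emb, importance = imp, optimizer = opt,
               batch_size = batch, heads = heads, attention_layers = layers,
               stringsAsFactors = FALSE)
  rbind(
    rec("gru", 2500, 8, 0.199, 32, 8, 1.282, "rmsprop"),
    rec("gru", 5000, 8, 0.367, 4, 32, 1.016, "rmsprop"),
    rec("gru", 10000, 8, 0.681, 64, 256, 1.228, "rmsprop"),
    rec("gru", 16000, 8, 0.677, 8, 8, 1.046, "nadam"),
    rec("gru", 32000, 8, 0.649, 4, 256, 1.042, "nadam"),
    rec("gru", 64000, 8, 0.593, 4, 64, 1.195, "adamax"),
    rec("lstm", 2500, 8, 0.340, 8, 256, 2.423, "nadam"),
    rec("lstm", 5000, 8, 0.650, 16, 16, 1.268, "nadam"),
    rec("lstm", 10000, 8, 0.594, 16, 64, 1.598, "adam"),
    rec("lstm", 16000, 8, 0.189, 64, 8, 1.055, "adamax"),
    rec("lstm", 32000, 8, 0.643, 64, 32, 2.187, "adam"),
    rec("lstm", 64000, 8, 0.207, 64, 8, 2.173, "adam"),
    rec("bilstm", 2500, 6, 0.646, 8, 256, 1.519, "adamax"),
    rec("bilstm", 5000, 8, 0.678, 16, 8, 1.622, "rmsprop"),
    rec("bilstm", 10000, 8, 0.405, 8, 8, 1.860, "adam"),
    rec("bilstm", 16000, 8, 0.639, 16, 8, 2.493, "rmsprop"),
    rec("bilstm", 32000, 8, 0.279, 16, 16, 1.039, "adamax"),
    rec("bilstm", 64000, 8, 0.430, 16, 16, 1.870, "rmsprop"),
    tra(2500, 16, 32, 2, 1, 1.245, "rmsprop"),
    tra(5000, 8, 128, 4, 2, 1.928, "rmsprop"),
    tra(10000, 8, 64, 8, 4, 1.594, "adam"),
    tra(16000, 8, 32, 2, 2, 1.117, "adamax"),
    tra(32000, 8, 64, 8, 4, 2.226, "rmsprop"),
    tra(64000, 8, 64, 4, 4, 1.764, "rmsprop")
  )
}

#' Build a classifier_config from a published preset
#'
#' @param arch Architecture name.
#' @param vocab_size Vocabulary size of the preset row.
#' @param ... Overrides passed to \code{\link{classifier_config}}.
#' @return A \code{classifier_config}.
#' @export
preset_classifier_config <- function(arch, vocab_size, ...) {
  tab <- classifier_presets()
  row <- tab[tab$arch == arch & tab$vocab_size == vocab_size, ]
  if (nrow(row) != 1)
    stop_chemactions("config", "no preset for this arch/vocab_size")
  args <- list(arch = row$arch, vocab_size = row$vocab_size,
               embedding_dim = row$embedding_dim, dropout = row$dropout,
               importance = row$importance, optimizer = row$optimizer,
               batch_size = row$batch_size)
  if (!is.na(row$recurrent_size)) args$recurrent_size <- row$recurrent_size
  if (!is.na(row$ff_size)) args$ff_size <- row$ff_size
  if (!is.na(row$heads)) { args$heads <- row$heads
                           args$attention_layers <- row$attention_layers }
  do.call(classifier_config, utils::modifyList(args, list(...)))
}

#' Desk-scale classifier preset
#'
#' A BiLSTM sized to train on a few thousand synthetic paragraphs on one
#' CPU in seconds per epoch.
#' @param ... Overrides.
#' @return A \code{classifier_config}.
#' @export
desk_classifier_config <- function(...) {
  args <- list(arch = "bilstm", vocab_size = 2000, embedding_dim = 8,
               recurrent_size = 16, ff_size = 8, dropout = 0.2,
               importance = 2, optimizer = "rmsprop", batch_size = 128,
               max_len = 64, max_epochs = 12, patience = 7)
  do.call(classifier_config, utils::modifyList(args, list(...)))
}

# ---- tokenized batches -----------------------------------------------------

texts_to_ids <- function(tok, texts, max_len) {
  seqs <- lapply(texts, function(s) {
    ids <- subword_encode(tok, s)
    if (length(ids) > max_len) ids <- ids[seq_len(max_len)]
    ids
  })
  lens <- pmax(lengths(seqs), 1L)
  T <- max(lens)
  B <- length(seqs)
  ids <- matrix(0L, B, T)
  mask <- matrix(0, B, T)
  for (b in seq_len(B)) {
    l <- length(seqs[[b]])
    if (l > 0) { ids[b, seq_len(l)] <- seqs[[b]]; mask[b, seq_len(l)] <- 1 }
  }
  list(ids = ids, mask = mask)
}

tok_fingerprint <- function(tok) {
  paste0(tok$vocab_size, ":",
         paste(utils::head(tok$pieces, 40), collapse = ""))
}

# ---- classifier forward/backward ------------------------------------------

init_classifier_params <- function(cfg) {
  V <- cfg$vocab_size; d <- cfg$embedding_dim
  h <- cfg$recurrent_size
  p <- list(E = glorot(V, d))
  if (cfg$arch == "gru") {
    p$rnn <- init_gru(d, h); rep_dim <- h
  } else if (cfg$arch == "lstm") {
    p$rnn <- init_lstm(d, h); rep_dim <- h
  } else if (cfg$arch == "bilstm") {
    p$rnn_f <- init_lstm(d, h); p$rnn_b <- init_lstm(d, h); rep_dim <- 2 * h
  } else {
    p$blocks <- lapply(seq_len(cfg$attention_layers), function(i)
      list(g1 = rep(1, d), b1 = rep(0, d), mha = init_mha(d, cfg$heads),
           g2 = rep(1, d), b2 = rep(0, d),
           Wf1 = glorot(d, cfg$ff_size), bf1 = rep(0, cfg$ff_size),
           Wf2 = glorot(cfg$ff_size, d), bf2 = rep(0, d)))
    p$gf <- rep(1, d); p$bf <- rep(0, d)
    rep_dim <- d
  }
  p$W1 <- glorot(rep_dim, cfg$ff_size); p$b1 <- rep(0, cfg$ff_size)
  p$W2 <- glorot(cfg$ff_size, 1); p$b2 <- 0
  p
}

clf_forward <- function(p, cfg, ids, mask, training = FALSE) {
  B <- nrow(ids); T <- ncol(ids)
  caches <- list(ids = ids, mask = mask, B = B, T = T)
  if (cfg$arch %in% c("gru", "lstm", "bilstm")) {
    X <- embed_fwd(p$E, ids)
    drops <- vector("list", T)
    for (t in seq_len(T)) {
      dr <- dropout_fwd(X[[t]], cfg$dropout, training)
      X[[t]] <- dr$out; drops[t] <- list(dr$cache)
    }
    caches$drops <- drops
    if (cfg$arch == "gru") {
      rn <- gru_fwd(X, mask, p$rnn, cfg$recurrent_size)
      rep_ <- rn$h_final; caches$rn <- rn
    } else if (cfg$arch == "lstm") {
      rn <- lstm_fwd(X, mask, p$rnn, cfg$recurrent_size)
      rep_ <- rn$h_final; caches$rn <- rn
    } else {
      rnf <- lstm_fwd(X, mask, p$rnn_f, cfg$recurrent_size)
      rnb <- lstm_fwd(rev(X), mask[, rev(seq_len(T)), drop = FALSE],
                      p$rnn_b, cfg$recurrent_size)
      rep_ <- cbind(rnf$h_final, rnb$h_final)
      caches$rnf <- rnf; caches$rnb <- rnb
    }
  } else {
    d <- cfg$embedding_dim
    flat_ids <- as.vector(t(ids))
    x <- p$E[flat_ids + 1L, , drop = FALSE] * sqrt(d)
    pe <- sinusoidal_pe(T, d)
    x <- x + pe[rep(seq_len(T), B), ]
    caches$flat_ids <- flat_ids
    caches$blocks <- vector("list", length(p$blocks))
    for (l in seq_along(p$blocks)) {
      bl <- p$blocks[[l]]
      ln1 <- ln_fwd(x, bl$g1, bl$b1)
      at <- mha_fwd(ln1$out, ln1$out, bl$mha, B, T, T, cfg$heads,
                    causal = FALSE, key_mask = mask)
      x1 <- x + at$out
      ln2 <- ln_fwd(x1, bl$g2, bl$b2)
      f1 <- dense_fwd(ln2$out, bl$Wf1, bl$bf1, "relu")
      f2 <- dense_fwd(f1$out, bl$Wf2, bl$bf2, "linear")
      x <- x1 + f2$out
      caches$blocks[[l]] <- list(ln1 = ln1, at = at, ln2 = ln2,
                                 f1 = f1, f2 = f2)
    }
    lnf <- ln_fwd(x, p$gf, p$bf)
    caches$lnf <- lnf
    # masked mean-pool over non-pad positions
    w <- as.vector(t(mask))
    nb <- rowSums(mask)
    pooled <- rowsum((lnf$out) * w, group = rep(seq_len(B), each = T)) / nb
    caches$pool_w <- w; caches$pool_nb <- nb
    rep_ <- pooled
  }
  caches$rep <- rep_
  f1 <- dense_fwd(rep_, p$W1, p$b1, "relu")
  f2 <- dense_fwd(f1$out, p$W2, p$b2, "linear")
  caches$h1 <- f1; caches$h2 <- f2
  list(logits = as.numeric(f2$out), caches = caches)
}

clf_backward <- function(p, cfg, caches, dlogits) {
  g <- zeros_like(p)
  B <- caches$B; T <- caches$T
  d2 <- dense_bwd(caches$h2$cache, matrix(dlogits, ncol = 1))
  g$W2 <- d2$dW; g$b2 <- d2$db
  d1 <- dense_bwd(caches$h1$cache, d2$dx)
  g$W1 <- d1$dW; g$b1 <- d1$db
  drep <- d1$dx
  if (cfg$arch %in% c("gru", "lstm", "bilstm")) {
    h <- cfg$recurrent_size
    dH_zero <- vector("list", T)
    if (cfg$arch == "gru") {
      bk <- gru_bwd(caches$rn$caches, p$rnn, h, dH_zero, dh_final = drep)
      g$rnn <- bk$grads; dX <- bk$dX
    } else if (cfg$arch == "lstm") {
      bk <- lstm_bwd(caches$rn$caches, p$rnn, h, dH_zero, dh_final = drep)
      g$rnn <- bk$grads; dX <- bk$dX
    } else {
      bkf <- lstm_bwd(caches$rnf$caches, p$rnn_f, h, dH_zero,
                      dh_final = drep[, 1:h, drop = FALSE])
      bkb <- lstm_bwd(caches$rnb$caches, p$rnn_b, h, dH_zero,
                      dh_final = drep[, h + 1:h, drop = FALSE])
      g$rnn_f <- bkf$grads; g$rnn_b <- bkb$grads
      dX <- mapply(function(a, b) a + b, bkf$dX, rev(bkb$dX), SIMPLIFY = FALSE)
    }
    for (t in seq_len(T)) dX[[t]] <- dropout_bwd(caches$drops[[t]], dX[[t]])
    g$E <- embed_bwd(p$E, caches$ids, dX)
  } else {
    # un-pool
    dx <- (drep / caches$pool_nb)[rep(seq_len(B), each = T), , drop = FALSE] *
      caches$pool_w
    bkf <- ln_bwd(caches$lnf$cache, dx)
    g$gf <- bkf$dgamma; g$bf <- bkf$dbeta
    dx <- bkf$dx
    for (l in rev(seq_along(p$blocks))) {
      bl <- p$blocks[[l]]; cc <- caches$blocks[[l]]
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
      dx <- dx1 + d_ln1$dx
      g$blocks[[l]] <- gb[names(bl)]  # keep the parameter field order
    }
    dx <- dx * sqrt(cfg$embedding_dim)
    gE <- rowsum(dx, group = caches$flat_ids)
    rows <- as.integer(rownames(gE)) + 1L
    g$E[rows, ] <- g$E[rows, ] + gE
  }
  g
}

# ---- early stopping --------------------------------------------------------

early_stopper <- function(patience) {
  env <- new.env(parent = emptyenv())
  env$best <- -Inf; env$best_epoch <- 0L; env$best_params <- NULL
  note <- function(epoch, metric, params) {
    if (metric > env$best) {
      env$best <- metric; env$best_epoch <- epoch
      env$best_params <- params
    }
    (epoch - env$best_epoch) >= patience
  }
  list(note = note, env = env)
}

# ---- training --------------------------------------------------------------

labels_of <- function(records) {
  vapply(records, function(r)
    if (inherits(r, "paragraph_record")) r$label else r$label, numeric(1))
}

texts_of <- function(records) {
  vapply(records, function(r) r$text, character(1))
}

#' Train a paragraph classifier
#'
#' Binary cross-entropy with a positive-class importance weight; early
#' stopping on validation accuracy with the configured patience; the
#' best-epoch weights are restored.  Fully reproducible given
#' \code{cfg$seed}.
#'
#' @param train,val Lists of \code{\link{paragraph_record}} with binary
#'   labels (both classes must be present in \code{train}).
#' @param tok A \code{subword_model} (its vocabulary size must match
#'   \code{cfg$vocab_size}).
#' @param cfg A \code{\link{classifier_config}}.
#' @param verbose Print per-epoch metrics.
#' @return An object of class \code{trained_model} with fields
#'   \code{params}, \code{config}, \code{history}, \code{stopped_epoch},
#'   \code{best_epoch}.
#' @export
train_classifier <- function(train, val, tok, cfg = desk_classifier_config(),
                             verbose = FALSE) {
  if (!length(train) || !length(val))
    stop_chemactions("data", "train and validation splits must be non-empty")
  y_tr <- labels_of(train); y_va <- labels_of(val)
  if (any(is.na(y_tr)) || !all(y_tr %in% c(0, 1)) || !all(y_va %in% c(0, 1)))
    stop_chemactions("data", "labels must be binary (0/1)")
  if (length(unique(y_tr)) < 2)
    stop_chemactions("data", "training set contains a single class")
  if (tok$vocab_size != cfg$vocab_size)
    stop_chemactions("tokenizer_mismatch",
                     sprintf("tokenizer vocab %d != config vocab %d",
                             tok$vocab_size, cfg$vocab_size))
  tr_texts <- texts_of(train); va_texts <- texts_of(val)
  va_batch <- texts_to_ids(tok, va_texts, cfg$max_len)

  with_seed(cfg$seed, {
    params <- init_classifier_params(cfg)
    opt <- make_optimizer(cfg$optimizer, cfg$learning_rate)
    es <- early_stopper(cfg$patience)
    history <- NULL
    n <- length(train)
    stopped <- cfg$max_epochs
    for (epoch in seq_len(cfg$max_epochs)) {
      idx <- sample.int(n)
      ep_loss <- 0; n_batches <- 0
      for (s in seq(1, n, by = cfg$batch_size)) {
        bidx <- idx[s:min(s + cfg$batch_size - 1, n)]
        bt <- texts_to_ids(tok, tr_texts[bidx], cfg$max_len)
        fw <- clf_forward(params, cfg, bt$ids, bt$mask, training = TRUE)
        ls <- bce_loss(fw$logits, y_tr[bidx], cfg$importance)
        grads <- clf_backward(params, cfg, fw$caches, ls$dlogits)
        params <- opt$update(params, grads)
        ep_loss <- ep_loss + ls$loss; n_batches <- n_batches + 1
      }
      va_fw <- clf_forward(params, cfg, va_batch$ids, va_batch$mask)
      va_prob <- sigmoid_(va_fw$logits)
      va_acc <- mean((va_prob >= 0.5) == y_va)
      history <- rbind(history,
                       data.frame(epoch = epoch,
                                  train_loss = ep_loss / n_batches,
                                  val_accuracy = va_acc))
      if (verbose)
        message(sprintf("epoch %d  loss %.4f  val_acc %.4f",
                        epoch, ep_loss / n_batches, va_acc))
      if (es$note(epoch, va_acc, params)) { stopped <- epoch; break }
    }
    structure(list(kind = "classifier", params = es$env$best_params,
                   config = cfg, history = history,
                   stopped_epoch = nrow(history),
                   best_epoch = es$env$best_epoch,
                   best_val_accuracy = es$env$best,
                   tok_hash = tok_fingerprint(tok)),
              class = "trained_model")
  })
}

#' @export
print.trained_model <- function(x, ...) {
  cat("<trained_model:", x$kind, "> arch=", x$config$arch,
      " epochs=", x$stopped_epoch, " best_epoch=", x$best_epoch, "\n", sep = "")
  invisible(x)
}

#' Predict the procedure probability of paragraphs
#'
#' @param model A classifier \code{trained_model}.
#' @param tok The \code{subword_model} used in training.
#' @param text Character vector of paragraphs.
#' @param threshold Decision threshold; label 1 iff probability >=
#'   threshold.
#' @return data.frame with \code{probability} and \code{label}.
#' @export
predict_label <- function(model, tok, text, threshold = 0.5) {
  stopifnot(inherits(model, "trained_model"), model$kind == "classifier")
  if (!identical(model$tok_hash, tok_fingerprint(tok)))
    stop_chemactions("tokenizer_mismatch",
                     "model was trained with a different tokenizer")
  bt <- texts_to_ids(tok, text, model$config$max_len)
  fw <- clf_forward(model$params, model$config, bt$ids, bt$mask)
  prob <- sigmoid_(fw$logits)
  data.frame(probability = prob, label = as.integer(prob >= threshold))
}

# ---- checkpoint IO ---------------------------------------------------------

#' Save a trained model checkpoint
#'
#' Writes a directory with \code{config.json} (config, history, epochs) and
#' \code{weights.json} (all parameters, full precision, text format).
#'
#' @param model A \code{trained_model}.
#' @param dir Checkpoint directory (created if missing).
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(kind = model$kind, config = unclass(model$config),
               config_class = class(model$config),
               history = model$history,
               stopped_epoch = model$stopped_epoch,
               best_epoch = model$best_epoch,
               tok_hash = model$tok_hash)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              dataframe = "columns"),
             file.path(dir, "config.json"))
  writeLines(jsonlite::serializeJSON(model$params, digits = NA),
             file.path(dir, "weights.json"))
  invisible(dir)
}

#' Load a checkpoint saved by \code{\link{save_model}}
#' @param dir Checkpoint directory.
#' @return A \code{trained_model}.
#' @export
load_model <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "config.json"),
                             simplifyDataFrame = TRUE)
  params <- jsonlite::unserializeJSON(
    paste(readLines(file.path(dir, "weights.json"), warn = FALSE),
          collapse = ""))
  cfg <- meta$config
  class(cfg) <- meta$config_class
  structure(list(kind = meta$kind, params = params, config = cfg,
                 history = meta$history, stopped_epoch = meta$stopped_epoch,
                 best_epoch = meta$best_epoch, tok_hash = meta$tok_hash),
            class = "trained_model")
}
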