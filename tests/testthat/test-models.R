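# Desk-scale training fixtures: tiny corpora and few epochs; anything
# larger lives in the acceptance tests.

clf_data <- function(n = 240, seed = 61, positive_fraction = 0.336) {
  memo(sprintf("clfdata_%d_%d_%s", n, seed, positive_fraction), function() {
    cs <- generate_classification_set(
      n, generator_config(seed = seed, positive_fraction = positive_fraction))
    split_dataset(cs, seed = seed)
  })
}

tiny_clf_cfg <- function(arch, ...) {
  args <- list(arch = arch, vocab_size = 600, embedding_dim = 8,
               recurrent_size = 8, ff_size = 8, dropout = 0,
               importance = 2, optimizer = "adam", batch_size = 64,
               max_len = 32, max_epochs = 2, patience = 7, heads = 2,
               attention_layers = 1, seed = 5)
  do.call(classifier_config, utils::modifyList(args, list(...)))
}

overfit_pairs <- function() {
  memo("overfit_pairs", function()
    generate_pairs(generator_config(n = 32, seed = 5,
                                    max_clauses_per_sentence = 2)))
}

overfit_tok <- function() {
  memo("overfit_tok", function() {
    pairs <- overfit_pairs()
    corpus <- c(vapply(pairs, `[[`, character(1), "sentence"),
                vapply(pairs, `[[`, character(1), "structured"))
    train_subword(c(corpus, corpus), vocab_size = 400)
  })
}

overfit_model <- function() {
  memo("overfit_model", function() {
    cfg <- seq2seq_config(arch = "transformer", vocab_size = 400,
                          embedding_dim = 48, stacks = 2, heads = 4,
                          ff_size = 96, batch_size = 8, max_epochs = 150,
                          patience = 150, learning_rate = 2e-3, seed = 9)
    train_seq2seq(overfit_pairs(), overfit_pairs(), overfit_tok(), cfg)
  })
}

clf_tiny_trained <- function() {
  memo("clf_tiny_trained", function() {
    sp <- clf_data()
    train_classifier(sp$train, sp$validation, small_tok(600),
                     tiny_clf_cfg("bilstm", max_epochs = 6))
  })
}

test_that("one epoch of training reduces the loss for every classifier architecture", {
  sp <- clf_data()
  tok <- small_tok(600)
  for (arch in c("gru", "lstm", "bilstm", "transformer_encoder")) {
    m <- train_classifier(sp$train, sp$validation, tok, tiny_clf_cfg(arch))
    expect_lt(m$history$train_loss[2], m$history$train_loss[1])
  }
})

test_that("one epoch of training reduces the loss for every seq2seq architecture", {
  pairs <- small_pairs(160, seed = 3)
  tok <- small_tok(600)
  for (arch in c("transformer", "rnn", "birnn")) {
    cfg <- seq2seq_config(arch = arch, vocab_size = 600, embedding_dim = 16,
                          encoder_size = 16, decoder_size = 16, stacks = 1,
                          heads = 2, ff_size = 32, batch_size = 32,
                          max_epochs = 2, patience = 7, seed = 5)
    m <- train_seq2seq(pairs[1:128], pairs[129:160], tok, cfg)
    expect_lt(m$history$train_loss[2], m$history$train_loss[1])
  }
})

test_that("degenerate training inputs raise data errors", {
  sp <- clf_data()
  tok <- small_tok(600)
  cfg <- tiny_clf_cfg("gru")
  expect_chem_error(train_classifier(list(), sp$validation, tok, cfg), "data")
  single <- Filter(function(r) r$label == 1, sp$train)
  expect_chem_error(train_classifier(single, sp$validation, tok, cfg), "data")
  expect_chem_error(train_seq2seq(list(), small_pairs(10, 1), tok,
                                  seq2seq_config(vocab_size = 600)), "data")
  # tokenizer/config vocabulary mismatch
  expect_chem_error(train_classifier(sp$train, sp$validation, tok,
                                     tiny_clf_cfg("gru", vocab_size = 999)),
                    "tokenizer_mismatch")
})

test_that("early stopping halts patience epochs after the best epoch and restores it", {
  sp <- clf_data()
  tok <- small_tok(600)
  cfg <- tiny_clf_cfg("bilstm", max_epochs = 25, patience = 3,
                      recurrent_size = 12)
  m <- train_classifier(sp$train, sp$validation, tok, cfg)
  expect_equal(nrow(m$history), m$stopped_epoch)
  if (m$stopped_epoch < cfg$max_epochs) {
    expect_equal(m$stopped_epoch - m$best_epoch, cfg$patience)
  }
  expect_equal(m$best_val_accuracy, max(m$history$val_accuracy))
  expect_equal(m$history$val_accuracy[m$best_epoch], m$best_val_accuracy)
})

test_that("seeded training is reproducible", {
  sp <- clf_data()
  tok <- small_tok(600)
  cfg <- tiny_clf_cfg("gru", max_epochs = 2)
  m1 <- train_classifier(sp$train, sp$validation, tok, cfg)
  m2 <- train_classifier(sp$train, sp$validation, tok, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
})

test_that("predictions are probabilities and respect the threshold", {
  sp <- clf_data()
  tok <- small_tok(600)
  m <- clf_tiny_trained()
  texts <- texts_of(sp$test[seq_len(min(30, length(sp$test)))])
  pr <- predict_label(m, tok, texts)
  expect_true(all(pr$probability >= 0 & pr$probability <= 1))
  expect_identical(pr$label, as.integer(pr$probability >= 0.5))
  pr1 <- predict_label(m, tok, texts, threshold = 1.0)
  expect_true(all(pr1$label[pr1$probability < 1] == 0))
  # a different tokenizer is refused
  tok2 <- small_tok(700)
  expect_chem_error(predict_label(m, tok2, texts), "tokenizer_mismatch")
})

test_that("class-1 recall responds monotonically to the importance factor", {
  tok <- small_tok(600)
  importances <- c(0.5, 1, 2, 3)
  seeds <- 1:5
  mean_recall <- vapply(importances, function(imp) {
    recalls <- vapply(seeds, function(sd) {
      cs <- generate_classification_set(
        220, generator_config(seed = 900 + sd, positive_fraction = 0.2))
      sp <- split_dataset(cs, seed = sd)
      cfg <- tiny_clf_cfg("gru", importance = imp, max_epochs = 2, seed = sd)
      m <- train_classifier(sp$train, sp$validation, tok, cfg)
      y <- labels_of(sp$test)
      pred <- predict_label(m, tok, texts_of(sp$test))$label
      if (!any(y == 1)) return(NA_real_)
      sum(pred == 1 & y == 1) / sum(y == 1)
    }, numeric(1))
    mean(recalls, na.rm = TRUE)
  }, numeric(1))
  expect_gte(mean_recall[4], mean_recall[1] - 0.01)
  expect_gte(suppressWarnings(cor(importances, mean_recall,
                                  method = "spearman")), 0)
})

test_that("a small transformer memorizes a 32-pair batch and decodes it exactly", {
  pairs <- overfit_pairs()
  tok <- overfit_tok()
  m <- overfit_model()
  ref <- vapply(pairs, `[[`, character(1), "structured")
  hyp <- translate(m, tok, vapply(pairs, `[[`, character(1), "sentence"))
  expect_gte(exact_match_accuracy(ref, hyp), 0.95)
})

test_that("greedy decoding is deterministic and beam returns a completed hypothesis", {
  pairs <- overfit_pairs()
  tok <- overfit_tok()
  m <- overfit_model()
  s <- pairs[[1]]$sentence
  g1 <- translate(m, tok, s)
  g2 <- translate(m, tok, s)
  expect_identical(g1, g2)
  b <- translate(m, tok, s, decoding = "beam", beam_width = 3)
  expect_true(nzchar(b))
  expect_chem_error(translate(m, tok, ""), "empty_input")
})

test_that("published presets load and validate", {
  tab <- classifier_presets()
  expect_equal(nrow(tab), 24)
  cfg <- preset_classifier_config("bilstm", 16000)
  expect_equal(cfg$embedding_dim, 8)
  expect_equal(cfg$dropout, 0.639)
  expect_equal(cfg$recurrent_size, 16)
  expect_equal(cfg$ff_size, 8)
  expect_equal(cfg$importance, 2.493)
  expect_equal(cfg$optimizer, "rmsprop")
  expect_equal(cfg$batch_size, 64)
  expect_equal(cfg$patience, 7)
  # every preset row passes config validation
  for (i in seq_len(nrow(tab)))
    expect_s3_class(preset_classifier_config(tab$arch[i], tab$vocab_size[i]),
                    "classifier_config")
  s2s <- seq2seq_presets()
  expect_equal(nrow(s2s), 7)
  expect_equal(s2s$stacks[s2s$arch == "transformer"], 6)
  expect_equal(s2s$learning_rate[s2s$arch == "transformer"], 0.005)
  expect_s3_class(desk_seq2seq_config(), "seq2seq_config")
  expect_s3_class(desk_classifier_config(), "classifier_config")
})

test_that("invalid configurations are rejected", {
  expect_chem_error(classifier_config(dropout = 1), "config")
  expect_chem_error(classifier_config(importance = 0), "config")
  expect_chem_error(classifier_config(patience = 0), "config")
  expect_chem_error(classifier_config(arch = "transformer_encoder",
                                      embedding_dim = 9, heads = 2), "config")
  expect_chem_error(seq2seq_config(beam_width = 0), "config")
  expect_chem_error(seq2seq_config(max_src_len = 0), "config")
  expect_chem_error(seq2seq_config(arch = "transformer", embedding_dim = 30,
                                   heads = 4), "config")
})

test_that("checkpoints survive a save/load round trip", {
  sp <- clf_data()
  tok <- small_tok(600)
  m <- clf_tiny_trained()
  dir <- withr::local_tempdir()
  save_model(m, dir)
  m2 <- load_model(dir)
  texts <- texts_of(sp$test[1:10])
  expect_equal(predict_label(m2, tok, texts)$probability,
               predict_label(m, tok, texts)$probability)
})
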