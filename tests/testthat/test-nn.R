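# Low-level layer checks: the compiled attention kernel against the pure-R
# reference path, and analytic gradients against central differences.

test_that("compiled attention equals the pure-R reference path", {
  set.seed(5)
  B <- 4; Tq <- 5; Tk <- 6; d <- 8; nh <- 2
  xq <- matrix(rnorm(B * Tq * d), B * Tq, d)
  xkv <- matrix(rnorm(B * Tk * d), B * Tk, d)
  km <- matrix(rbinom(B * Tk, 1, 0.8), B, Tk); km[, 1] <- 1
  p <- chemactions:::init_mha(d, nh)
  for (causal in c(FALSE, TRUE)) {
    f1 <- chemactions:::mha_fwd(xq, xkv, p, B, Tq, Tk, nh, causal, km)
    withr::local_options(chemactions.mha_loop = TRUE)
    f2 <- chemactions:::mha_fwd(xq, xkv, p, B, Tq, Tk, nh, causal, km)
    withr::local_options(chemactions.mha_loop = NULL)
    expect_lt(max(abs(f1$out - f2$out)), 1e-12)
    dout <- matrix(rnorm(B * Tq * d), B * Tq, d)
    b1 <- chemactions:::mha_bwd(f1$cache, p, dout)
    b2 <- chemactions:::mha_bwd(f2$cache, p, dout)
    expect_lt(max(abs(b1$dxq - b2$dxq)), 1e-12)
    expect_lt(max(abs(b1$dxkv - b2$dxkv)), 1e-12)
    expect_lt(max(abs(unlist(b1$grads) - unlist(b2$grads))), 1e-12)
  }
})

test_that("analytic gradients match central differences end to end", {
  set.seed(7)
  flatten <- function(tr) unlist(tr, use.names = FALSE)
  unflatten_into <- function(tr, v) {
    i <- 0
    walk <- function(x) {
      if (is.list(x)) return(lapply(x, walk))
      n <- length(x); out <- v[(i + 1):(i + n)]; i <<- i + n
      if (is.matrix(x)) out <- matrix(out, nrow(x), ncol(x))
      out
    }
    walk(tr)
  }
  rel_err <- function(a, b) max(abs(a - b)) / max(1e-8, max(abs(a) + abs(b)))
  check_grad <- function(p, loss_of, analytic, n_coords = 40, eps = 1e-5) {
    v <- flatten(p); gv <- flatten(analytic)
    co <- sort(sample(length(v), min(n_coords, length(v))))
    num <- vapply(co, function(k) {
      v1 <- v; v1[k] <- v1[k] + eps
      v2 <- v; v2[k] <- v2[k] - eps
      (loss_of(unflatten_into(p, v1)) - loss_of(unflatten_into(p, v2))) /
        (2 * eps)
    }, numeric(1))
    rel_err(num, gv[co])
  }

  ids <- matrix(sample(0:49, 3 * 6, TRUE), 3, 6)
  mask <- matrix(c(1, 1, 1, 1, 1, 1,
                   1, 1, 1, 1, 0, 0,
                   1, 1, 0, 0, 0, 0), 3, 6, byrow = TRUE)
  y <- c(1, 0, 1)
  for (arch in c("gru", "bilstm", "transformer_encoder")) {
    cfg <- classifier_config(arch = arch, vocab_size = 50, embedding_dim = 8,
                             recurrent_size = 5, ff_size = 4, dropout = 0,
                             importance = 1.7, heads = 2,
                             attention_layers = 2)
    set.seed(3)
    p <- chemactions:::init_classifier_params(cfg)
    loss_of <- function(pp) {
      fw <- chemactions:::clf_forward(pp, cfg, ids, mask)
      chemactions:::bce_loss(fw$logits, y, cfg$importance)$loss
    }
    fw <- chemactions:::clf_forward(p, cfg, ids, mask)
    bl <- chemactions:::bce_loss(fw$logits, y, cfg$importance)
    g <- chemactions:::clf_backward(p, cfg, fw$caches, bl$dlogits)
    expect_lt(check_grad(p, loss_of, g), 1e-5)
  }

  srcs <- list(c(5L, 6L, 7L, 8L), c(9L, 10L), c(11L, 12L, 13L))
  tgts <- list(c(20L, 21L, 22L), c(23L, 24L), c(25L))
  for (arch in c("transformer", "rnn", "birnn")) {
    cfg <- seq2seq_config(arch = arch, vocab_size = 40, embedding_dim = 8,
                          encoder_size = 6, decoder_size = 5, stacks = 2,
                          heads = 2, ff_size = 12)
    set.seed(4)
    p <- chemactions:::init_s2s_params(cfg)
    loss_of <- function(pp) {
      st <- chemactions:::s2s_step(pp, cfg, NULL, srcs, tgts,
                                   training = FALSE)
      st$loss$loss
    }
    st <- chemactions:::s2s_step(p, cfg, NULL, srcs, tgts, training = FALSE)
    g <- chemactions:::s2s_backward(p, cfg, st$enc, st$dec, st$loss$dlogits,
                                    st$src, st$tgt_mask)
    expect_lt(check_grad(p, loss_of, g), 1e-5)
  }
})

test_that("the five optimizers all reduce a quadratic objective", {
  set.seed(1)
  target <- matrix(rnorm(12), 3, 4)
  for (opt_name in c("adam", "nadam", "sgd", "adamax", "rmsprop")) {
    params <- list(W = matrix(0, 3, 4))
    opt <- chemactions:::make_optimizer(opt_name, lr = 0.05)
    loss0 <- sum((params$W - target)^2)
    for (i in 1:50)
      params <- opt$update(params, list(W = 2 * (params$W - target)))
    expect_lt(sum((params$W - target)^2), loss0 / 2)
  }
})
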