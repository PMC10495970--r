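# Minimal neural-network layer library: dense, embedding, LSTM/GRU,
# layer normalization, multi-head attention, losses, and the optimizers
# used by the training loops.  All layers implement explicit forward and
# backward passes on base-R matrices (BLAS does the heavy lifting), which
# keeps training bit-for-bit reproducible given a seed.

# ---- parameter trees -------------------------------------------------------

tree_map <- function(f, a) {
  if (is.list(a)) return(lapply(a, function(x) tree_map(f, x)))
  f(a)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a)); names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    return(out)
  }
  f(a, b)
}

zeros_like <- function(a) tree_map(function(x) x * 0, a)

add_trees <- function(a, b) tree_map2(`+`, a, b)

glorot <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

# ---- optimizers ------------------------------------------------------------

#' Create an optimizer
#'
#' @param name One of \code{"adam"}, \code{"nadam"}, \code{"sgd"},
#'   \code{"adamax"}, \code{"rmsprop"}.
#' @param lr Learning rate.
#' @return An object with an \code{update(params, grads)} closure; state is
#'   kept internally.
#' @keywords internal
make_optimizer <- function(name = c("adam", "nadam", "sgd", "adamax", "rmsprop"),
                           lr = 1e-3) {
  name <- match.arg(name)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; rho <- 0.9
  env <- new.env(parent = emptyenv())
  env$m <- NULL; env$v <- NULL; env$t <- 0L
  update <- function(params, grads) {
    env$t <- env$t + 1L
    t <- env$t
    if (is.null(env$m)) { env$m <- zeros_like(params); env$v <- zeros_like(params) }
    if (name == "sgd") {
      return(tree_map2(function(p, g) p - lr * g, params, grads))
    }
    if (name == "rmsprop") {
      env$v <- tree_map2(function(v, g) rho * v + (1 - rho) * g^2, env$v, grads)
      return(tree_map2(function(p, gv) p - lr * gv[[1]] / (sqrt(gv[[2]]) + eps),
                       params, tree_map2(function(g, v) list(g, v), grads, env$v)))
    }
    env$m <- tree_map2(function(m, g) b1 * m + (1 - b1) * g, env$m, grads)
    if (name == "adamax") {
      env$v <- tree_map2(function(v, g) pmax(b2 * v, abs(g)), env$v, grads)
      step <- lr / (1 - b1^t)
      return(tree_map2(function(p, mv) p - step * mv[[1]] / (mv[[2]] + eps),
                       params, tree_map2(function(m, v) list(m, v), env$m, env$v)))
    }
    env$v <- tree_map2(function(v, g) b2 * v + (1 - b2) * g^2, env$v, grads)
    mhat_scale <- 1 / (1 - b1^t)
    vhat_scale <- 1 / (1 - b2^t)
    if (name == "adam") {
      return(tree_map2(function(p, mvg)
        p - lr * (mvg[[1]] * mhat_scale) / (sqrt(mvg[[2]] * vhat_scale) + eps),
        params,
        tree_map2(function(m, v) list(m, v), env$m, env$v)))
    }
    # nadam: Nesterov momentum folded into the Adam step.
    # zip with matrix-leaved trees first: tree_map2 recurses on its first
    # argument, so the first argument must never have list leaves
    mv <- tree_map2(function(m, v) list(m, v), env$m, env$v)
    gmv <- tree_map2(function(g, mv1) list(g, mv1[[1]], mv1[[2]]), grads, mv)
    tree_map2(function(p, x) {
      g <- x[[1]]; m <- x[[2]]; v <- x[[3]]
      m_bar <- b1 * m * mhat_scale + (1 - b1) * g * mhat_scale
      p - lr * m_bar / (sqrt(v * vhat_scale) + eps)
    }, params, gmv)
  }
  list(name = name, lr = lr, update = update)
}

# ---- basic layers ----------------------------------------------------------

# column-wise bias add / scale without sweep()'s aperm overhead
addbias <- function(x, b) x + rep(b, each = nrow(x))
colscale <- function(x, s) x * rep(s, each = nrow(x))

dense_fwd <- function(x, W, b, act = c("linear", "relu", "tanh", "sigmoid")) {
  act <- match.arg(act)
  z <- x %*% W
  z <- addbias(z, b)
  a <- switch(act, linear = z, relu = pmax(z, 0), tanh = tanh(z),
              sigmoid = 1 / (1 + exp(-z)))
  list(out = a, cache = list(x = x, W = W, z = z, a = a, act = act))
}

dense_bwd <- function(cache, da) {
  dz <- switch(cache$act,
               linear = da,
               relu = da * (cache$z > 0),
               tanh = da * (1 - cache$a^2),
               sigmoid = da * cache$a * (1 - cache$a))
  list(dx = dz %*% t(cache$W),
       dW = crossprod(cache$x, dz),
       db = colSums(dz))
}

embed_fwd <- function(E, ids) {
  # ids: integer matrix B x T of 0-based piece ids; row id+1 of E
  B <- nrow(ids); T <- ncol(ids); d <- ncol(E)
  lapply(seq_len(T), function(t) E[ids[, t] + 1L, , drop = FALSE])
}

embed_bwd <- function(E, ids, dX_list) {
  dE <- matrix(0, nrow(E), ncol(E))
  for (t in seq_along(dX_list)) {
    g <- rowsum(dX_list[[t]], group = ids[, t])
    rows <- as.integer(rownames(g)) + 1L
    dE[rows, ] <- dE[rows, ] + g
  }
  dE
}

dropout_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(out = x, cache = NULL))
  mask <- matrix(stats::rbinom(length(x), 1, 1 - rate), nrow(x)) / (1 - rate)
  list(out = x * mask, cache = mask)
}

dropout_bwd <- function(cache, dout) {
  if (is.null(cache)) dout else dout * cache
}

# ---- recurrent cells -------------------------------------------------------

init_lstm <- function(d_in, d_h) {
  list(Wx = glorot(d_in, 4 * d_h), Wh = glorot(d_h, 4 * d_h),
       b = rep(0, 4 * d_h))
}

sigmoid_ <- function(x) 1 / (1 + exp(-x))

# X_list: list over time of B x d_in; mask: B x T (1 = real token)
lstm_fwd <- function(X_list, mask, p, d_h) {
  T <- length(X_list); B <- nrow(X_list[[1]])
  h <- matrix(0, B, d_h); c_ <- matrix(0, B, d_h)
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
    h_next <- h_new * m + h * (1 - m)
    c_next <- c_new * m + c_ * (1 - m)
    caches[[t]] <- list(x = X_list[[t]], h_prev = h, c_prev = c_, i = i, f = f,
                        o = o, g = g, c_new = c_new, tc = tc, m = m)
    h <- h_next; c_ <- c_next
    H[[t]] <- h
  }
  list(H = H, h_final = h, c_final = c_, caches = caches)
}

lstm_bwd <- function(caches, p, d_h, dH, dh_final = NULL, dc_final = NULL) {
  T <- length(caches); B <- nrow(caches[[1]]$x)
  dWx <- p$Wx * 0; dWh <- p$Wh * 0; db <- p$b * 0
  dX <- vector("list", T)
  dh <- if (is.null(dh_final)) matrix(0, B, d_h) else dh_final
  dc <- if (is.null(dc_final)) matrix(0, B, d_h) else dc_final
  for (t in rev(seq_len(T))) {
    cc <- caches[[t]]
    if (!is.null(dH[[t]])) dh <- dh + dH[[t]]
    m <- cc$m
    dh_new <- dh * m; dh_prev_skip <- dh * (1 - m)
    dc_new <- dc * m; dc_prev_skip <- dc * (1 - m)
    do_ <- dh_new * cc$tc
    dtc <- dh_new * cc$o
    dc_new <- dc_new + dtc * (1 - cc$tc^2)
    df <- dc_new * cc$c_prev
    di <- dc_new * cc$g
    dg <- dc_new * cc$i
    dc_prev <- dc_new * cc$f + dc_prev_skip
    dz <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                do_ * cc$o * (1 - cc$o),
                dg * (1 - cc$g^2))
    dWx <- dWx + crossprod(cc$x, dz)
    dWh <- dWh + crossprod(cc$h_prev, dz)
    db <- db + colSums(dz)
    dX[[t]] <- dz %*% t(p$Wx)
    dh <- dz %*% t(p$Wh) + dh_prev_skip
    dc <- dc_prev
  }
  list(dX = dX, grads = list(Wx = dWx, Wh = dWh, b = db),
       dh0 = dh, dc0 = dc)
}

init_gru <- function(d_in, d_h) {
  list(Wx = glorot(d_in, 3 * d_h), Wh = glorot(d_h, 3 * d_h),
       b = rep(0, 3 * d_h))
}

gru_fwd <- function(X_list, mask, p, d_h) {
  T <- length(X_list); B <- nrow(X_list[[1]])
  h <- matrix(0, B, d_h)
  caches <- vector("list", T); H <- vector("list", T)
  for (t in seq_len(T)) {
    zx <- X_list[[t]] %*% p$Wx
    zh <- h %*% p$Wh
    r <- sigmoid_(sweep(zx[, 1:d_h, drop = FALSE] + zh[, 1:d_h, drop = FALSE],
                        2, p$b[1:d_h], `+`))
    u <- sigmoid_(sweep(zx[, d_h + 1:d_h, drop = FALSE] +
                          zh[, d_h + 1:d_h, drop = FALSE],
                        2, p$b[d_h + 1:d_h], `+`))
    n <- tanh(sweep(zx[, 2 * d_h + 1:d_h, drop = FALSE] +
                      r * zh[, 2 * d_h + 1:d_h, drop = FALSE],
                    2, p$b[2 * d_h + 1:d_h], `+`))
    h_new <- (1 - u) * n + u * h
    m <- mask[, t]
    h_next <- h_new * m + h * (1 - m)
    caches[[t]] <- list(x = X_list[[t]], h_prev = h, r = r, u = u, n = n,
                        zh = zh, m = m)
    h <- h_next
    H[[t]] <- h
  }
  list(H = H, h_final = h, caches = caches)
}

gru_bwd <- function(caches, p, d_h, dH, dh_final = NULL) {
  T <- length(caches); B <- nrow(caches[[1]]$x)
  dWx <- p$Wx * 0; dWh <- p$Wh * 0; db <- p$b * 0
  dX <- vector("list", T)
  dh <- if (is.null(dh_final)) matrix(0, B, d_h) else dh_final
  for (t in rev(seq_len(T))) {
    cc <- caches[[t]]
    if (!is.null(dH[[t]])) dh <- dh + dH[[t]]
    m <- cc$m
    dh_new <- dh * m; dh_prev_skip <- dh * (1 - m)
    du <- dh_new * (cc$h_prev - cc$n)
    dn <- dh_new * (1 - cc$u)
    dh_prev <- dh_new * cc$u + dh_prev_skip
    dzn <- dn * (1 - cc$n^2)
    dr <- dzn * cc$zh[, 2 * d_h + 1:d_h, drop = FALSE]
    dzr <- dr * cc$r * (1 - cc$r)
    dzu <- du * cc$u * (1 - cc$u)
    dz <- cbind(dzr, dzu, dzn)
    dWx <- dWx + crossprod(cc$x, dz)
    db <- db + colSums(dz)
    # dzh columns: r,u gates direct; candidate gated by r
    dzh <- cbind(dzr, dzu, dzn * cc$r)
    dWh <- dWh + crossprod(cc$h_prev, dzh)
    dX[[t]] <- dz %*% t(p$Wx)
    dh <- dzh %*% t(p$Wh) + dh_prev
  }
  list(dX = dX, grads = list(Wx = dWx, Wh = dWh, b = db), dh0 = dh)
}

# ---- layer normalization ---------------------------------------------------

ln_fwd <- function(x, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * istd
  out <- addbias(colscale(xhat, gamma), beta)
  list(out = out, cache = list(xhat = xhat, istd = istd, gamma = gamma))
}

ln_bwd <- function(cache, dout) {
  xhat <- cache$xhat; istd <- cache$istd; gamma <- cache$gamma
  d <- ncol(xhat)
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- colscale(dout, gamma)
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * istd
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- multi-head attention --------------------------------------------------

init_mha <- function(d, n_heads) {
  list(Wq = glorot(d, d), Wk = glorot(d, d), Wv = glorot(d, d),
       Wo = glorot(d, d),
       bq = rep(0, d), bk = rep(0, d), bv = rep(0, d), bo = rep(0, d))
}

# xq: (B*Tq) x d query input; xkv: (B*Tk) x d key/value input (row-major by
# sequence: rows 1..Tq are sequence 1).  key_mask: B x Tk (1 = attend).
#
# The batched per-sequence/per-head computation runs in the compiled
# kernel (src/attention.cpp); a pure-R reference loop with identical
# results is kept for testing (options(chemactions.mha_loop = TRUE)).
# Attention weights are cached as a (B*Tq) x (H*Tk) matrix whose column
# block h holds head h (column (h-1)*Tk + j = key position j).
mha_fwd <- function(xq, xkv, p, B, Tq, Tk, n_heads, causal = FALSE,
                    key_mask = NULL) {
  d <- ncol(xq); dk <- d / n_heads
  Q <- addbias(xq %*% p$Wq, p$bq)
  K <- addbias(xkv %*% p$Wk, p$bk)
  V <- addbias(xkv %*% p$Wv, p$bv)
  scale <- 1 / sqrt(dk)
  if (!isTRUE(getOption("chemactions.mha_loop"))) {
    r <- attn_fwd_cpp(Q, K, V, B, Tq, Tk, n_heads, causal, key_mask)
    out <- addbias(r$ctx %*% p$Wo, p$bo)
    return(list(out = out,
                cache = list(xq = xq, xkv = xkv, Q = Q, K = K, V = V,
                             ctx = r$ctx, A = r$A, B = B, Tq = Tq, Tk = Tk,
                             compiled = TRUE, n_heads = n_heads,
                             scale = scale)))
  }
  ctx <- matrix(0, B * Tq, d)
  A_store <- vector("list", B * n_heads)
  for (b in seq_len(B)) {
    qr <- ((b - 1) * Tq + 1):(b * Tq)
    kr <- ((b - 1) * Tk + 1):(b * Tk)
    keep <- if (is.null(key_mask)) rep(TRUE, Tk) else key_mask[b, ] > 0
    for (h in seq_len(n_heads)) {
      hc <- ((h - 1) * dk + 1):(h * dk)
      Sb <- (Q[qr, hc, drop = FALSE] %*% t(K[kr, hc, drop = FALSE])) * scale
      if (causal) Sb[upper.tri(Sb)] <- -Inf
      if (!all(keep)) Sb[, !keep] <- -Inf
      Sb <- Sb - apply(Sb, 1, max)
      E <- exp(Sb)
      Ab <- E / rowSums(E)
      ctx[qr, hc] <- Ab %*% V[kr, hc, drop = FALSE]
      A_store[[(b - 1) * n_heads + h]] <- Ab
    }
  }
  out <- addbias(ctx %*% p$Wo, p$bo)
  list(out = out,
       cache = list(xq = xq, xkv = xkv, Q = Q, K = K, V = V, ctx = ctx,
                    A = A_store, B = B, Tq = Tq, Tk = Tk, compiled = FALSE,
                    n_heads = n_heads, scale = scale))
}

mha_bwd <- function(cache, p, dout) {
  B <- cache$B; Tq <- cache$Tq; Tk <- cache$Tk
  n_heads <- cache$n_heads; d <- ncol(cache$xq); dk <- d / n_heads
  dWo <- crossprod(cache$ctx, dout)
  dbo <- colSums(dout)
  dctx <- dout %*% t(p$Wo)
  if (isTRUE(cache$compiled)) {
    r <- attn_bwd_cpp(cache$Q, cache$K, cache$V, cache$A, dctx,
                      B, Tq, Tk, n_heads)
    dQ <- r$dQ; dK <- r$dK; dV <- r$dV
  } else {
    dQ <- matrix(0, B * Tq, d); dK <- matrix(0, B * Tk, d)
    dV <- matrix(0, B * Tk, d)
    for (b in seq_len(B)) {
      qr <- ((b - 1) * Tq + 1):(b * Tq)
      kr <- ((b - 1) * Tk + 1):(b * Tk)
      for (h in seq_len(n_heads)) {
        hc <- ((h - 1) * dk + 1):(h * dk)
        A <- cache$A[[(b - 1) * n_heads + h]]
        dA <- dctx[qr, hc, drop = FALSE] %*% t(cache$V[kr, hc, drop = FALSE])
        dV[kr, hc] <- dV[kr, hc] + t(A) %*% dctx[qr, hc, drop = FALSE]
        dS <- A * (dA - rowSums(dA * A))
        dQ[qr, hc] <- dS %*% cache$K[kr, hc, drop = FALSE] * cache$scale
        dK[kr, hc] <- dK[kr, hc] +
          t(dS) %*% cache$Q[qr, hc, drop = FALSE] * cache$scale
      }
    }
  }
  list(dxq = dQ %*% t(p$Wq),
       dxkv = dK %*% t(p$Wk) + dV %*% t(p$Wv),
       grads = list(Wq = crossprod(cache$xq, dQ),
                    Wk = crossprod(cache$xkv, dK),
                    Wv = crossprod(cache$xkv, dV),
                    Wo = dWo,
                    bq = colSums(dQ), bk = colSums(dK), bv = colSums(dV),
                    bo = dbo))
}

# ---- positional encoding ---------------------------------------------------

sinusoidal_pe <- function(T, d) {
  pos <- matrix(0, T, d)
  for (i in seq_len(ceiling(d / 2))) {
    freq <- 1 / (10000^((2 * (i - 1)) / d))
    pos[, 2 * i - 1] <- sin((seq_len(T) - 1) * freq)
    if (2 * i <= d) pos[, 2 * i] <- cos((seq_len(T) - 1) * freq)
  }
  pos
}

# ---- losses ----------------------------------------------------------------

# weighted binary cross-entropy on logits; importance multiplies the loss of
# positive examples
bce_loss <- function(logits, y, importance = 1) {
  w <- ifelse(y == 1, importance, 1)
  # stable softplus
  sp <- ifelse(logits > 30, logits, log1p(exp(pmin(logits, 30))))
  loss <- sum(w * (sp - y * logits)) / length(y)
  dlogits <- w * (sigmoid_(logits) - y) / length(y)
  list(loss = loss, dlogits = dlogits)
}

# softmax cross-entropy over rows of logits; targets 0-based ids;
# weight 0 drops a row (padding) - such rows are skipped entirely
softmax_ce <- function(logits, targets, weights) {
  act <- which(weights > 0)
  w <- weights[act]
  n <- sum(w)
  sub <- logits[act, , drop = FALSE]
  mx <- sub[cbind(seq_along(act), max.col(sub, ties.method = "first"))]
  ex <- exp(sub - mx)
  probs <- ex / rowSums(ex)
  idx <- cbind(seq_along(act), targets[act] + 1L)
  loss <- sum(-log(pmax(probs[idx], 1e-12)) * w) / n
  d <- probs
  d[idx] <- d[idx] - 1
  d <- d * (w / n)
  dlogits <- matrix(0, nrow(logits), ncol(logits))
  dlogits[act, ] <- d
  list(loss = loss, dlogits = dlogits)
}
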