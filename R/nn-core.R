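# Minimal neural-network core: forward/backward passes written as explicit
# matrix algebra, an Adam optimizer over nested parameter lists, and a
# cosine-annealed learning-rate schedule. Parameter trees are plain nested
# lists whose leaves are numeric arrays; linear maps are list(W, b),
# layer norms list(g, b). Weight decay applies only to leaves named "W"
# (normalization parameters, biases and the CLS token are excluded).

nnLinearInit <- function(d_in, d_out, scale = NULL) {
  if (is.null(scale)) scale <- sqrt(2 / (d_in + d_out))
  list(W = matrix(rnorm(d_in * d_out, sd = scale), d_in, d_out),
       b = numeric(d_out))
}

nnLinearFwd <- function(x, p) sweep(x %*% p$W, 2, p$b, "+")

nnLinearBwd <- function(dy, x, p) {
  list(grad = list(W = crossprod(x, dy), b = colSums(dy)),
       dx = dy %*% t(p$W))
}

nnLayerNormInit <- function(d) list(g = rep(1, d), b = numeric(d))

nnLayerNormFwd <- function(x, p, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(y = sweep(xhat, 2, p$g, "*") + rep(p$b, each = nrow(x)),
       xhat = xhat, inv = inv)
}

nnLayerNormBwd <- function(dy, cache, p) {
  xhat <- cache$xhat; inv <- cache$inv
  D <- ncol(xhat)
  dxhat <- sweep(dy, 2, p$g, "*")
  dx <- (inv / D) * (D * dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
  list(grad = list(g = colSums(dy * xhat), b = colSums(dy)), dx = dx)
}

nnSoftmaxRows <- function(x) {
  m <- apply(x, 1, max)
  e <- exp(x - m)
  e / rowSums(e)
}

# dL/dx for y = softmaxRows(x): P * (dP - rowSums(dP * P))
nnSoftmaxRowsBwd <- function(dP, P) P * (dP - rowSums(dP * P))

nnDropout <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, mask = NULL))
  mask <- matrix(rbinom(length(x), 1, 1 - rate), nrow(x), ncol(x)) / (1 - rate)
  list(y = x * mask, mask = mask)
}

# ---- multi-head self-attention with key padding mask --------------------
# x: T x C token matrix (row 1 is the CLS token); mask: T logicals,
# TRUE = valid key. Masked positions receive -Inf scores as keys, so they
# contribute exactly zero to every output row.

nnAttnInit <- function(C) {
  list(q = nnLinearInit(C, C), k = nnLinearInit(C, C),
       v = nnLinearInit(C, C), o = nnLinearInit(C, C))
}

nnAttnFwd <- function(x, mask, p, n_heads) {
  Tn <- nrow(x); C <- ncol(x); dh <- C %/% n_heads
  Q <- nnLinearFwd(x, p$q); K <- nnLinearFwd(x, p$k); V <- nnLinearFwd(x, p$v)
  heads <- vector("list", n_heads)
  O <- matrix(0, Tn, C)
  for (h in seq_len(n_heads)) {
    ix <- ((h - 1) * dh + 1):(h * dh)
    sc <- Q[, ix, drop = FALSE] %*% t(K[, ix, drop = FALSE]) / sqrt(dh)
    sc[, !mask] <- -Inf
    A <- nnSoftmaxRows(sc)
    O[, ix] <- A %*% V[, ix, drop = FALSE]
    heads[[h]] <- A
  }
  y <- nnLinearFwd(O, p$o)
  list(y = y, Q = Q, K = K, V = V, O = O, A = heads, x = x, mask = mask)
}

nnAttnBwd <- function(dy, cache, p, n_heads) {
  x <- cache$x; mask <- cache$mask
  C <- ncol(x); dh <- C %/% n_heads
  bo <- nnLinearBwd(dy, cache$O, p$o)
  dO <- bo$dx
  dQ <- matrix(0, nrow(x), C); dK <- dQ; dV <- dQ
  for (h in seq_len(n_heads)) {
    ix <- ((h - 1) * dh + 1):(h * dh)
    A <- cache$A[[h]]
    dOh <- dO[, ix, drop = FALSE]
    dV[, ix] <- t(A) %*% dOh
    dA <- dOh %*% t(cache$V[, ix, drop = FALSE])
    dSc <- nnSoftmaxRowsBwd(dA, A) / sqrt(dh)   # zero at masked keys (A = 0)
    dQ[, ix] <- dSc %*% cache$K[, ix, drop = FALSE]
    dK[, ix] <- t(dSc) %*% cache$Q[, ix, drop = FALSE]
  }
  bq <- nnLinearBwd(dQ, x, p$q)
  bk <- nnLinearBwd(dK, x, p$k)
  bv <- nnLinearBwd(dV, x, p$v)
  list(grad = list(q = bq$grad, k = bk$grad, v = bv$grad, o = bo$grad),
       dx = bq$dx + bk$dx + bv$dx)
}

# ---- transformer encoder layer (post-LN, as in the standard encoder) ----

nnTransformerLayerInit <- function(C, mlp_ratio = 4.0) {
  dff <- round(C * mlp_ratio)
  list(attn = nnAttnInit(C), ln1 = nnLayerNormInit(C),
       ffn1 = nnLinearInit(C, dff), ffn2 = nnLinearInit(dff, C),
       ln2 = nnLayerNormInit(C))
}

nnTransformerLayerFwd <- function(x, mask, p, n_heads, dropout = 0,
                                  training = FALSE) {
  at <- nnAttnFwd(x, mask, p$attn, n_heads)
  dp1 <- nnDropout(at$y, dropout, training)
  l1 <- nnLayerNormFwd(x + dp1$y, p$ln1)
  h <- nnLinearFwd(l1$y, p$ffn1)
  hr <- pmax(h, 0)
  dp2 <- nnDropout(hr, dropout, training)
  f <- nnLinearFwd(dp2$y, p$ffn2)
  dp3 <- nnDropout(f, dropout, training)
  l2 <- nnLayerNormFwd(l1$y + dp3$y, p$ln2)
  list(y = l2$y, at = at, dp1 = dp1, l1 = l1, h = h, hr = hr, dp2 = dp2,
       dp3 = dp3, l2 = l2)
}

nnTransformerLayerBwd <- function(dy, cache, p, n_heads) {
  b2 <- nnLayerNormBwd(dy, cache$l2, p$ln2)
  df <- b2$dx
  if (!is.null(cache$dp3$mask)) df <- df * cache$dp3$mask
  bf2 <- nnLinearBwd(df, cache$dp2$y, p$ffn2)
  dhr <- bf2$dx
  if (!is.null(cache$dp2$mask)) dhr <- dhr * cache$dp2$mask
  dh <- dhr * (cache$h > 0)
  bf1 <- nnLinearBwd(dh, cache$l1$y, p$ffn1)
  dl1 <- b2$dx + bf1$dx
  b1 <- nnLayerNormBwd(dl1, cache$l1, p$ln1)
  da <- b1$dx
  if (!is.null(cache$dp1$mask)) da <- da * cache$dp1$mask
  bat <- nnAttnBwd(da, cache$at, p$attn, n_heads)
  list(grad = list(attn = bat$grad, ln1 = b1$grad, ffn1 = bf1$grad,
                   ffn2 = bf2$grad, ln2 = b2$grad),
       dx = b1$dx + bat$dx)
}

# ---- parameter-tree utilities ------------------------------------------

treeMap <- function(f, ...) {
  trees <- list(...)
  t1 <- trees[[1]]
  if (is.list(t1)) {
    out <- vector("list", length(t1))
    names(out) <- names(t1)
    for (i in seq_along(t1))
      out[[i]] <- do.call(treeMap, c(list(f), lapply(trees, `[[`, i)))
    out
  } else do.call(f, trees)
}

treeZero <- function(tree) treeMap(function(x) x * 0, tree)

treeSum <- function(a, b) treeMap(`+`, a, b)

treeScale <- function(tree, s) treeMap(function(x) x * s, tree)

adamInit <- function(params) {
  list(m = treeZero(params), v = treeZero(params), t = 0L)
}

# One Adam step with L2 weight decay on leaves named "W" only.
adamStep <- function(params, grads, state, lr, weight_decay = 0,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v, path) {
    if (weight_decay > 0 && identical(path, "W")) g <- g + weight_decay * p
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  # recursion carries the leaf name so the decay rule can see it
  rec <- function(p, g, m, v, nm) {
    if (is.list(p)) {
      for (k in names(p)) {
        r <- rec(p[[k]], g[[k]], m[[k]], v[[k]], k)
        p[[k]] <- r$p; m[[k]] <- r$m; v[[k]] <- r$v
      }
      list(p = p, m = m, v = v)
    } else {
      r <- upd(p, g, m, v, nm)
      list(p = r$p, m = r$m, v = r$v)
    }
  }
  out <- rec(params, grads, state$m, state$v, "")
  list(params = out$p, state = list(m = out$m, v = out$v, t = t))
}

#' Cosine-annealed learning rate
#'
#' @param epoch 1-based epoch index.
#' @param epochs total number of epochs.
#' @param lr_init,lr_final initial and final learning rates.
#' @return the learning rate for `epoch`.
#' @export
cosineLR <- function(epoch, epochs, lr_init = 3e-3, lr_final = 1e-6) {
  if (epochs <= 1) return(lr_init)
  frac <- (epoch - 1) / (epochs - 1)
  lr_final + 0.5 * (lr_init - lr_final) * (1 + cos(pi * frac))
}
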