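# Differentiable layer primitives for the segmentation network.
#
# Feature maps are ((H*W*B) x C) matrices (pixel r + c*H + b*H*W in 0-based
# terms), token stacks are ((T*B) x K) matrices, item-major. Every *_fwd
# returns the output plus the cache its *_bwd needs; backward functions
# return the input gradient and parameter gradients named like the
# parameters, so gradient trees mirror parameter trees exactly.

addrow <- function(x, b) x + matrix(b, nrow(x), length(b), byrow = TRUE)

rowmat <- function(v, n, k) matrix(v, n, k, byrow = TRUE)

# ---- batch normalization (per channel over batch x space) ---------------
# column loops avoid large byrow-recycled temporaries on big feature maps

bn_fwd <- function(x, g, be, st, training, momentum = 0.1, eps = 1e-5) {
  if (training) {
    mo <- col_moments(x)
    mu <- mo$mu; v <- mo$var
    invstd <- 1 / sqrt(v + eps)
    xhat <- scale_cols(x, invstd, -mu * invstd)
    st$rm <- (1 - momentum) * st$rm + momentum * mu
    st$rv <- (1 - momentum) * st$rv + momentum * v
    list(y = scale_cols(xhat, g, be),
         cache = list(xhat = xhat, invstd = invstd), st = st)
  } else {
    invstd <- 1 / sqrt(st$rv + eps)
    list(y = scale_cols(x, g * invstd, be - st$rm * invstd * g),
         cache = NULL, st = st)
  }
}

bn_bwd <- function(dy, cache, g) {
  bn_bwd_core(dy, cache$xhat, g, cache$invstd)
}

# ---- layer normalization (per token over embedding dims) ----------------

ln_fwd <- function(x, g, b, eps = 1e-5) {
  K <- ncol(x); n <- nrow(x)
  mu <- rowMeans(x)
  xc <- x - mu
  invstd <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * invstd
  list(y = xhat * rowmat(g, n, K) + rowmat(b, n, K),
       cache = list(xhat = xhat, invstd = invstd))
}

ln_bwd <- function(dy, cache, g) {
  n <- nrow(dy); K <- ncol(dy)
  xhat <- cache$xhat
  dxhat <- dy * rowmat(g, n, K)
  dx <- cache$invstd *
    (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

# ---- pointwise nonlinearities -------------------------------------------

gelu_fwd <- function(x) {
  Phi <- pnorm(x)
  list(y = x * Phi, cache = list(x = x, Phi = Phi))
}

gelu_bwd <- function(dy, cache)
  dy * (cache$Phi + cache$x * dnorm(cache$x))

# ---- multi-head self-attention ------------------------------------------

attn_fwd <- function(x, p, T, B, nh) {
  K <- ncol(x); dh <- K %/% nh; sc <- 1 / sqrt(dh)
  y <- matrix(0, nrow(x), K)
  caches <- vector("list", B)
  for (b in seq_len(B)) {
    rows <- ((b - 1) * T + 1):(b * T)
    Xb <- x[rows, , drop = FALSE]
    Q <- addrow(Xb %*% p$Wq, p$bq)
    Km <- addrow(Xb %*% p$Wk, p$bk)
    V <- addrow(Xb %*% p$Wv, p$bv)
    O <- matrix(0, T, K)
    A <- vector("list", nh)
    for (h in seq_len(nh)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      S <- sc * (Q[, cols, drop = FALSE] %*% t(Km[, cols, drop = FALSE]))
      S <- S - S[cbind(seq_len(T), max.col(S, ties.method = "first"))]
      E <- exp(S)
      A[[h]] <- E / rowSums(E)
      O[, cols] <- A[[h]] %*% V[, cols, drop = FALSE]
    }
    y[rows, ] <- addrow(O %*% p$Wo, p$bo)
    caches[[b]] <- list(Xb = Xb, Q = Q, Km = Km, V = V, A = A, O = O)
  }
  list(y = y, cache = caches)
}

attn_bwd <- function(dy, cache, p, T, B, nh) {
  K <- ncol(dy); dh <- K %/% nh; sc <- 1 / sqrt(dh)
  dx <- matrix(0, nrow(dy), K)
  g <- list(Wq = 0 * p$Wq, bq = 0 * p$bq, Wk = 0 * p$Wk, bk = 0 * p$bk,
            Wv = 0 * p$Wv, bv = 0 * p$bv, Wo = 0 * p$Wo, bo = 0 * p$bo)
  for (b in seq_len(B)) {
    rows <- ((b - 1) * T + 1):(b * T)
    cb <- cache[[b]]
    dyb <- dy[rows, , drop = FALSE]
    dO <- dyb %*% t(p$Wo)
    g$Wo <- g$Wo + crossprod(cb$O, dyb)
    g$bo <- g$bo + colSums(dyb)
    dQ <- matrix(0, T, K); dK <- matrix(0, T, K); dV <- matrix(0, T, K)
    for (h in seq_len(nh)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      Ah <- cb$A[[h]]
      dOh <- dO[, cols, drop = FALSE]
      Vh <- cb$V[, cols, drop = FALSE]
      dA <- dOh %*% t(Vh)
      dV[, cols] <- crossprod(Ah, dOh)
      dS <- Ah * (dA - rowSums(dA * Ah))
      dQ[, cols] <- sc * (dS %*% cb$Km[, cols, drop = FALSE])
      dK[, cols] <- sc * (crossprod(dS, cb$Q[, cols, drop = FALSE]))
    }
    g$Wq <- g$Wq + crossprod(cb$Xb, dQ); g$bq <- g$bq + colSums(dQ)
    g$Wk <- g$Wk + crossprod(cb$Xb, dK); g$bk <- g$bk + colSums(dK)
    g$Wv <- g$Wv + crossprod(cb$Xb, dV); g$bv <- g$bv + colSums(dV)
    dx[rows, ] <- dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
  }
  list(dx = dx, grads = g)
}

# ---- transformer encoder block (pre-norm) -------------------------------

block_fwd <- function(x, p, T, B, nh) {
  l1 <- ln_fwd(x, p$ln1g, p$ln1b)
  at <- attn_fwd(l1$y, p, T, B, nh)
  h <- x + at$y
  l2 <- ln_fwd(h, p$ln2g, p$ln2b)
  m1 <- addrow(l2$y %*% p$W1, p$b1)
  ge <- gelu_fwd(m1)
  y <- h + addrow(ge$y %*% p$W2, p$b2)
  list(y = y, cache = list(l1 = l1, at = at, l2 = l2, ge = ge, h = h))
}

block_bwd <- function(dy, cache, p, T, B, nh) {
  ge <- cache$ge
  dge <- dy %*% t(p$W2)
  dm1 <- gelu_bwd(dge, ge$cache)
  dl2y <- dm1 %*% t(p$W1)
  l2b <- ln_bwd(dl2y, cache$l2$cache, p$ln2g)
  dh <- dy + l2b$dx
  ab <- attn_bwd(dh, cache$at$cache, p, T, B, nh)
  l1b <- ln_bwd(ab$dx, cache$l1$cache, p$ln1g)
  dx <- dh + l1b$dx
  g <- ab$grads
  g$ln1g <- l1b$dg; g$ln1b <- l1b$db
  g$ln2g <- l2b$dg; g$ln2b <- l2b$db
  g$W1 <- crossprod(cache$l2$y, dm1); g$b1 <- colSums(dm1)
  g$W2 <- crossprod(ge$y, dy); g$b2 <- colSums(dy)
  list(dx = dx, grads = g)
}

# ---- convolutional blocks (decoder) -------------------------------------

# 3x3 conv + batch norm + ReLU. The ReLU mask is recovered from the
# cached output (y > 0) instead of storing a separate logical map.
cbr_fwd <- function(x, p, st, H, W, B, training) {
  y1 <- conv3_fwd(x, p$W, p$b, H, W, B)
  bn <- bn_fwd(y1, p$g, p$be, st, training)
  y <- pmax(bn$y, 0)
  list(y = y, cache = list(x = x, bn = bn$cache, y = y), st = bn$st)
}

cbr_bwd <- function(dy, cache, p, H, W, B) {
  dyr <- dy * (cache$y > 0)
  bb <- bn_bwd(dyr, cache$bn, p$g)
  cv <- conv3_bwd(cache$x, bb$dx, p$W, H, W, B)
  list(dx = cv$dX,
       grads = list(W = as.numeric(cv$dW), b = as.numeric(cv$db),
                    g = bb$dg, be = bb$dbe))
}

# 2x2 stride-2 deconvolution (upsampling).
dcv_fwd <- function(x, p, H, W, B) {
  list(y = deconv2_fwd(x, p$W, p$b, H, W, B), cache = list(x = x))
}

dcv_bwd <- function(dy, cache, p, H, W, B) {
  g <- deconv2_bwd(cache$x, dy, p$W, H, W, B)
  list(dx = g$dX, grads = list(W = as.numeric(g$dW), b = as.numeric(g$db)))
}

# ---- Adam optimizer ------------------------------------------------------

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(theta, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad * grad
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}
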