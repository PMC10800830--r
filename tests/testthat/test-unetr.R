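# Network architecture contracts, the Focal Tversky loss, and gradient
# correctness of the hand-built backward pass.

test_that("token counts follow (image_size / P)^2", {
  expect_equal(token_count(256, 16), 256)
  expect_equal(token_count(256, 256), 1)
  expect_equal(token_count(64, 16), 16)
  expect_error(token_count(250, 16), "divisible")
})

test_that("configuration invariants are enforced", {
  expect_error(unetr_config(image_size = 100), "multiple")
  expect_error(unetr_config(embed_dim_K = 30, n_heads = 4), "divisible")
  expect_error(unetr_config(n_transformer_layers = 2), "at least 4")
  expect_error(unetr_config(skip_layer_indices = c(1, 2, 3, 20)), "skip")
  # default skips scale 3/6/9/12 proportionally
  expect_equal(unetr_config()$skip_layer_indices, c(3L, 6L, 9L, 12L))
  expect_equal(unetr_config(embed_dim_K = 32, n_transformer_layers = 4,
                            n_heads = 4)$skip_layer_indices, 1:4)
})

test_that("a tiny network stays under 2M parameters and runs fast", {
  net <- build_unetr(unetr_config(image_size = 64, embed_dim_K = 32,
                                  n_transformer_layers = 4, n_heads = 4,
                                  mlp_hidden_dim = 64,
                                  decoder_base_channels = 4), seed = 1)
  expect_lt(n_parameters(net), 2e6)
  x <- matrix(runif(64 * 64 * 3), 64 * 64, 3)
  t0 <- proc.time()[3]
  out <- ringseg:::unetr_forward(net, x, 1, training = FALSE,
                                 keep_cache = FALSE)
  expect_lt(proc.time()[3] - t0, 1)
  expect_equal(dim(out$logits), c(64 * 64, 1))
  # deterministic in evaluation mode
  out2 <- ringseg:::unetr_forward(net, x, 1, training = FALSE,
                                  keep_cache = FALSE)
  expect_identical(out$logits, out2$logits)
})

test_that("positional embedding length equals the token count", {
  cfg <- tiny_net_config(64)
  net <- build_unetr(cfg, seed = 2)
  expect_equal(nrow(net$params$embed$pos), token_count(64, 16))
})

test_that("checkpoints round-trip weights, statistics and config", {
  net <- build_unetr(tiny_net_config(32), seed = 3)
  f <- file.path(withr::local_tempdir(), "ck.rds")
  save_checkpoint(net, f)
  back <- load_checkpoint(f)
  expect_identical(back$params, net$params)
  expect_identical(back$bn, net$bn)
  expect_equal(unclass(back$cfg), unclass(net$cfg))
  expect_error(load_checkpoint("no/such.rds"), "not found")
})

test_that("focal Tversky loss reproduces its closed forms", {
  y <- c(1, 0, 1, 0, 0)
  expect_lte(focal_tversky_loss(y, y), 1e-9)        # perfect prediction
  expect_gte(focal_tversky_loss(y, rep(0, 5)), 1 - 1e-6)  # total miss
  expect_equal(focal_tversky_loss(c(1, 0), c(0.5, 0.5)), 0.5^0.75,
               tolerance = 1e-9)
  expect_error(focal_tversky_loss(c(1, 0), c(0.5)), "differ")
  expect_error(focal_tversky_loss(c(1, 0), c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the loss is monotone in each prediction and bounded", {
  set.seed(4)
  y <- rbinom(40, 1, 0.3)
  yh <- runif(40)
  L <- focal_tversky_loss(y, yh)
  expect_gte(L, 0); expect_lte(L, 1)
  for (i in c(which(y == 1)[1:3], which(y == 0)[1:3])) {
    up <- yh; up[i] <- min(1, up[i] + 0.1)
    if (y[i] == 1) expect_lte(focal_tversky_loss(y, up), L + 1e-12)
    else expect_gte(focal_tversky_loss(y, up), L - 1e-12)
  }
  # permutation symmetry
  p <- sample(40)
  expect_equal(focal_tversky_loss(y[p], yh[p]), L)
})

test_that("the analytic loss gradient matches finite differences", {
  set.seed(5)
  y <- rbinom(30, 1, 0.3)
  yh <- runif(30, 0.05, 0.95)
  g <- ringseg:::focal_tversky_grad(y, yh)
  eps <- 1e-7
  for (i in sample(30, 8)) {
    up <- yh; up[i] <- up[i] + eps
    dn <- yh; dn[i] <- dn[i] - eps
    num <- (focal_tversky_loss(y, up) - focal_tversky_loss(y, dn)) / (2 * eps)
    expect_equal(g[i], num, tolerance = 1e-5)
  }
})

test_that("convolution kernels match a double-precision reference", {
  set.seed(6)
  H <- 5; W <- 7; B <- 2; Cin <- 3; Cout <- 2; N <- H * W
  X <- matrix(rnorm(N * B * Cin), N * B, Cin)
  Wk <- rnorm(9 * Cin * Cout); bias <- rnorm(Cout)
  getX <- function(b, r, c, ci)
    if (r >= 1 && r <= H && c >= 1 && c <= W)
      X[(b - 1) * N + r + (c - 1) * H, ci] else 0
  ref <- matrix(0, N * B, Cout)
  for (b in 1:B) for (r in 1:H) for (cl in 1:W) for (co in 1:Cout) {
    v <- bias[co]
    for (dc in -1:1) for (dr in -1:1) for (ci in 1:Cin) {
      k <- (dr + 1) + 3 * (dc + 1)
      v <- v + getX(b, r + dr, cl + dc, ci) *
        Wk[1 + k + 9 * (ci - 1) + 9 * Cin * (co - 1)]
    }
    ref[(b - 1) * N + r + (cl - 1) * H, co] <- v
  }
  Y <- ringseg:::conv3_fwd(X, Wk, bias, H, W, B)
  expect_equal(Y, ref, tolerance = 1e-5, ignore_attr = TRUE)
  # backward against finite differences of the kernel's own forward
  dY <- matrix(rnorm(N * B * Cout), N * B, Cout)
  g <- ringseg:::conv3_bwd(X, dY, Wk, H, W, B)
  f <- function(Xv, Wv) sum(ringseg:::conv3_fwd(matrix(Xv, N * B, Cin),
                                                Wv, bias, H, W, B) * dY)
  eps <- 1e-3
  for (t in 1:10) {
    i <- sample(length(X), 1)
    X2 <- X; X2[i] <- X2[i] + eps
    X3 <- X; X3[i] <- X3[i] - eps
    expect_equal(g$dX[i], (f(X2, Wk) - f(X3, Wk)) / (2 * eps),
                 tolerance = 1e-2)
    j <- sample(length(Wk), 1)
    W2 <- Wk; W2[j] <- W2[j] + eps
    W3 <- Wk; W3[j] <- W3[j] - eps
    expect_equal(g$dW[j], (f(X, W2) - f(X, W3)) / (2 * eps),
                 tolerance = 1e-2)
  }
  expect_equal(as.numeric(g$db), colSums(dY), tolerance = 1e-5)
})

test_that("deconvolution kernels match a double-precision reference", {
  set.seed(7)
  H <- 4; W <- 5; B <- 2; Cin <- 3; Cout <- 2; N <- H * W
  X <- matrix(rnorm(N * B * Cin), N * B, Cin)
  Wk <- rnorm(4 * Cin * Cout); bias <- rnorm(Cout)
  Y <- ringseg:::deconv2_fwd(X, Wk, bias, H, W, B)
  expect_equal(dim(Y), c(4 * N * B, Cout))
  ref <- matrix(0, 4 * N * B, Cout)
  for (b in 1:B) for (r in 1:H) for (cl in 1:W) for (co in 1:Cout)
    for (dr in 0:1) for (dc in 0:1) {
      d <- dr + 2 * dc
      v <- 0
      for (ci in 1:Cin)
        v <- v + X[(b - 1) * N + r + (cl - 1) * H, ci] *
          Wk[1 + d + 4 * (ci - 1) + 4 * Cin * (co - 1)]
      ref[(b - 1) * 4 * N + (2 * (r - 1) + dr + 1) +
            (2 * (cl - 1) + dc) * 2 * H, co] <- v + bias[co]
    }
  expect_equal(Y, ref, tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("the whole-network gradient matches finite differences", {
  cfg <- unetr_config(image_size = 32, embed_dim_K = 8,
                      n_transformer_layers = 4, n_heads = 2,
                      mlp_hidden_dim = 16, decoder_base_channels = 2)
  net <- build_unetr(cfg, seed = 5)
  B <- 2; S <- 32
  set.seed(8)
  x <- matrix(runif(S * S * B * 3), S * S * B, 3)
  y <- rbinom(S * S * B, 1, 0.1)
  fw <- ringseg:::unetr_forward(net, x, B, training = TRUE)
  probs <- 1 / (1 + exp(-fw$logits))
  dlog <- matrix(ringseg:::focal_tversky_grad(y, probs) *
                   as.numeric(probs) * (1 - as.numeric(probs)), ncol = 1)
  grads <- ringseg:::unetr_backward(net, fw$cache, dlog)
  gv <- unlist(grads); tv <- unlist(net$params)
  expect_identical(names(gv), names(tv))
  lossat <- function(theta) {
    net2 <- net
    net2$params <- utils::relist(theta, net$params)
    f <- ringseg:::unetr_forward(net2, x, B, training = TRUE)
    focal_tversky_loss(y, 1 / (1 + exp(-f$logits)))
  }
  # directional derivatives along random directions aggregate over all
  # parameters, which keeps the finite-difference signal well above the
  # single-precision noise of the convolution kernels
  eps <- 1e-3
  set.seed(9)
  for (rep in 1:4) {
    u <- rnorm(length(tv))
    u <- u / sqrt(sum(u * u))
    num <- (lossat(tv + eps * u) - lossat(tv - eps * u)) / (2 * eps)
    ana <- sum(gv * u)
    expect_equal(num, ana, tolerance = 0.02)
  }
})

test_that("one small Adam step decreases the loss on a single pair", {
  cfg <- tiny_net_config(32)
  net <- build_unetr(cfg, seed = 10)
  set.seed(11)
  patch <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  m <- matrix(0L, 32, 32); m[15:17, ] <- 1L
  pair <- patch_pair(patch, m)
  fit <- train_model(list(pair), train_config(epochs = 2, batch_size = 1,
                                              learning_rate = 1e-3,
                                              seed = 12), net_cfg = cfg)
  expect_lt(fit$loss_history[2], fit$loss_history[1])
})
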