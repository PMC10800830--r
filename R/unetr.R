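# 2-D UNETR: vision-transformer encoder over 16x16 image patches with a
# convolutional decoder fed by skip connections from four encoder depths.
#
# The encoder embeds non-overlapping P x P patches linearly, adds a learned
# positional embedding, and applies pre-norm transformer blocks (multi-head
# self-attention + 2-layer GELU MLP). Hidden states at the four skip depths
# are reshaped to spatial grids and merged into a UNET-style decoder built
# from 2x2 deconvolutions and 3x3 conv + batch-norm + ReLU blocks; a final
# 1x1 convolution produces one logit per pixel. This is the 2-D analogue of
# the volumetric UNETR design, with all sizes configurable so that a tiny
# instance trains on one CPU.

#' Number of transformer tokens for an image
#'
#' An `image_size` x `image_size` input cut into non-overlapping
#' `patch_resolution_P` x `patch_resolution_P` patches yields
#' `(image_size / P)^2` tokens; 256/16 gives the canonical 256 tokens.
#'
#' @param image_size square input side in pixels.
#' @param patch_resolution_P transformer patch side in pixels.
#' @return integer token count.
#' @export
#' @examples
#' token_count(256, 16)  # 256
token_count <- function(image_size, patch_resolution_P) {
  stop_if_not(is_count(image_size) && is_count(patch_resolution_P),
              "sizes must be positive integers")
  stop_if_not(image_size %% patch_resolution_P == 0,
              "image_size %d not divisible by patch resolution %d",
              image_size, patch_resolution_P)
  as.integer((image_size / patch_resolution_P)^2)
}

default_skips <- function(L) {
  s <- unique(round(L * c(3, 6, 9, 12) / 12))
  s[s < 1] <- 1
  unique(s)
}

#' UNETR configuration
#'
#' Defaults follow the canonical instantiation (image 256, P = 16, K = 768,
#' 12 layers, 12 heads, skips at layers 3/6/9/12, decoder base width 64).
#' The decoder geometry fixes `patch_resolution_P = 16` (four 2x upsampling
#' stages); skip depths scale proportionally for shallower encoders.
#'
#' @param image_size square input side; must be divisible by 16.
#' @param patch_resolution_P transformer patch side (16).
#' @param embed_dim_K token embedding width; divisible by `n_heads`.
#' @param n_transformer_layers encoder depth (>= 4 so that four distinct
#'   skip depths exist).
#' @param n_heads attention heads.
#' @param mlp_hidden_dim hidden width of the per-token MLP (default `4 * K`).
#' @param skip_layer_indices four increasing encoder depths feeding the
#'   decoder; default scales 3/6/9/12 to the chosen depth.
#' @param decoder_base_channels decoder width at full resolution; stage
#'   widths are `8x, 4x, 2x, 1x` this value from coarse to fine.
#' @param out_channels number of output logit channels (1).
#' @return A validated `unetr_config` list.
#' @export
unetr_config <- function(image_size = 256, patch_resolution_P = 16,
                         embed_dim_K = 768, n_transformer_layers = 12,
                         n_heads = 12, mlp_hidden_dim = 4 * embed_dim_K,
                         skip_layer_indices = NULL,
                         decoder_base_channels = 64, out_channels = 1) {
  stop_if_not(patch_resolution_P == 16,
              "the decoder geometry requires patch_resolution_P = 16")
  stop_if_not(is_count(image_size) && image_size %% patch_resolution_P == 0,
              "image_size must be a positive multiple of %d",
              patch_resolution_P)
  stop_if_not(is_count(n_transformer_layers) && n_transformer_layers >= 4,
              "need at least 4 transformer layers (four skip depths)")
  stop_if_not(is_count(embed_dim_K) && is_count(n_heads) &&
                embed_dim_K %% n_heads == 0,
              "embed_dim_K must be divisible by n_heads")
  if (is.null(skip_layer_indices))
    skip_layer_indices <- default_skips(n_transformer_layers)
  stop_if_not(length(skip_layer_indices) == 4 &&
                !is.unsorted(skip_layer_indices, strictly = TRUE) &&
                max(skip_layer_indices) <= n_transformer_layers &&
                min(skip_layer_indices) >= 1,
              "skip_layer_indices must be 4 increasing depths within 1..%d",
              n_transformer_layers)
  stop_if_not(out_channels == 1, "only single-logit output is supported")
  structure(list(image_size = as.integer(image_size),
                 patch_resolution_P = as.integer(patch_resolution_P),
                 embed_dim_K = as.integer(embed_dim_K),
                 n_transformer_layers = as.integer(n_transformer_layers),
                 n_heads = as.integer(n_heads),
                 mlp_hidden_dim = as.integer(mlp_hidden_dim),
                 skip_layer_indices = as.integer(skip_layer_indices),
                 decoder_base_channels = as.integer(decoder_base_channels),
                 out_channels = 1L),
            class = "unetr_config")
}

# parameter initializers ---------------------------------------------------

init_lin <- function(nin, nout, sd = 0.02)
  matrix(rnorm(nin * nout, 0, sd), nin, nout)

init_conv3 <- function(cin, cout) {
  p <- list(W = rnorm(9 * cin * cout, 0, sqrt(2 / (9 * cin))),
            b = numeric(cout), g = rep(1, cout), be = numeric(cout))
  p
}

init_dcv <- function(cin, cout)
  list(W = rnorm(4 * cin * cout, 0, sqrt(2 / (4 * cin))), b = numeric(cout))

bn_state0 <- function(cout) list(rm = numeric(cout), rv = rep(1, cout))

#' Build a UNETR segmentation network
#'
#' Initializes all weights (seeded, reproducible) and the batch-norm
#' running statistics.
#'
#' @param cfg a [unetr_config()].
#' @param seed RNG seed for weight initialization.
#' @return An object of class `unetr_net` with elements `cfg`, `params`,
#'   `bn` (running statistics).
#' @export
build_unetr <- function(cfg = unetr_config(), seed = 1) {
  stopifnot(inherits(cfg, "unetr_config"))
  with_seed(seed, build_unetr_impl(cfg))
}

build_unetr_impl <- function(cfg) {
  K <- cfg$embed_dim_K; P <- cfg$patch_resolution_P
  Tn <- token_count(cfg$image_size, P)
  M <- cfg$mlp_hidden_dim; B0 <- cfg$decoder_base_channels
  blocks <- lapply(seq_len(cfg$n_transformer_layers), function(l) list(
    ln1g = rep(1, K), ln1b = numeric(K),
    Wq = init_lin(K, K), bq = numeric(K),
    Wk = init_lin(K, K), bk = numeric(K),
    Wv = init_lin(K, K), bv = numeric(K),
    Wo = init_lin(K, K), bo = numeric(K),
    ln2g = rep(1, K), ln2b = numeric(K),
    W1 = init_lin(K, M), b1 = numeric(M),
    W2 = init_lin(M, K), b2 = numeric(K)))
  params <- list(
    embed = list(We = init_lin(P * P * 3, K), be = numeric(K),
                 pos = init_lin(Tn, K)),
    blocks = blocks,
    dec = list(
      d4 = init_dcv(K, 8 * B0),
      b9 = list(dc1 = init_dcv(K, 8 * B0), cv1 = init_conv3(8 * B0, 8 * B0)),
      m3 = list(cv1 = init_conv3(16 * B0, 8 * B0),
                cv2 = init_conv3(8 * B0, 8 * B0),
                up = init_dcv(8 * B0, 4 * B0)),
      b6 = list(dc1 = init_dcv(K, 4 * B0), cv1 = init_conv3(4 * B0, 4 * B0),
                dc2 = init_dcv(4 * B0, 4 * B0),
                cv2 = init_conv3(4 * B0, 4 * B0)),
      m2 = list(cv1 = init_conv3(8 * B0, 4 * B0),
                cv2 = init_conv3(4 * B0, 4 * B0),
                up = init_dcv(4 * B0, 2 * B0)),
      b3 = list(dc1 = init_dcv(K, 2 * B0), cv1 = init_conv3(2 * B0, 2 * B0),
                dc2 = init_dcv(2 * B0, 2 * B0),
                cv2 = init_conv3(2 * B0, 2 * B0),
                dc3 = init_dcv(2 * B0, 2 * B0),
                cv3 = init_conv3(2 * B0, 2 * B0)),
      m1 = list(cv1 = init_conv3(4 * B0, 2 * B0),
                cv2 = init_conv3(2 * B0, 2 * B0),
                up = init_dcv(2 * B0, B0)),
      z0 = list(cv1 = init_conv3(3, B0), cv2 = init_conv3(B0, B0)),
      m0 = list(cv1 = init_conv3(2 * B0, B0), cv2 = init_conv3(B0, B0)),
      # head bias starts at the logit of a 1% foreground prior so early
      # training is not spent pushing the background down (standard
      # prior-initialization for heavily imbalanced segmentation)
      head = list(W = init_lin(B0, 1, sd = sqrt(2 / B0)),
                  b = log(0.01 / 0.99))))
  bn <- list(
    b9 = list(cv1 = bn_state0(8 * B0)),
    m3 = list(cv1 = bn_state0(8 * B0), cv2 = bn_state0(8 * B0)),
    b6 = list(cv1 = bn_state0(4 * B0), cv2 = bn_state0(4 * B0)),
    m2 = list(cv1 = bn_state0(4 * B0), cv2 = bn_state0(4 * B0)),
    b3 = list(cv1 = bn_state0(2 * B0), cv2 = bn_state0(2 * B0),
              cv3 = bn_state0(2 * B0)),
    m1 = list(cv1 = bn_state0(2 * B0), cv2 = bn_state0(2 * B0)),
    z0 = list(cv1 = bn_state0(B0), cv2 = bn_state0(B0)),
    m0 = list(cv1 = bn_state0(B0), cv2 = bn_state0(B0)))
  structure(list(cfg = cfg, params = params, bn = bn), class = "unetr_net")
}

#' Count trainable parameters of a network
#'
#' @param net a `unetr_net`.
#' @return integer parameter count.
#' @export
n_parameters <- function(net) {
  stopifnot(inherits(net, "unetr_net"))
  length(unlist(net$params))
}

#' @export
print.unetr_net <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf(paste0("<unetr_net: image %d, P %d, K %d, %d layers, ",
                     "%d heads, base %d, %s parameters>\n"),
              cfg$image_size, cfg$patch_resolution_P, cfg$embed_dim_K,
              cfg$n_transformer_layers, cfg$n_heads,
              cfg$decoder_base_channels,
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

# token gather index: (T*B) x P^2 matrix of flat pixel indices (per channel)
patch_index <- function(S, P, B) {
  g <- S %/% P; Tn <- g * g; N <- S * S
  t <- 0:(Tn - 1); gr <- t %% g; gc <- t %/% g
  j <- 0:(P * P - 1); pr <- j %% P; pc <- j %/% P
  base <- outer(gr * P, pr, "+") + outer(gc * P, pc, "+") * S + 1
  idx <- matrix(0L, Tn * B, P * P)
  for (b in seq_len(B)) idx[((b - 1) * Tn + 1):(b * Tn), ] <-
      base + (b - 1) * N
  idx
}

# Forward pass. x: (S^2 * B) x 3 matrix in [0,1]. Returns logits
# ((S^2 * B) x 1), cache (if requested), and updated bn state.
unetr_forward <- function(net, x, B, training = FALSE, keep_cache = training) {
  cfg <- net$cfg; p <- net$params; bn <- net$bn
  S <- cfg$image_size; P <- cfg$patch_resolution_P
  g <- S %/% P; Tn <- g * g
  K <- cfg$embed_dim_K; nh <- cfg$n_heads; B0 <- cfg$decoder_base_channels
  idx <- patch_index(S, P, B)
  tok <- matrix(0, Tn * B, P * P * 3)
  for (ch in 1:3)
    tok[, ((ch - 1) * P * P + 1):(ch * P * P)] <-
      x[, ch][idx]
  posB <- p$embed$pos[rep(seq_len(Tn), B), , drop = FALSE]
  h <- addrow(tok %*% p$embed$We, p$embed$be) + posB
  zs <- vector("list", 4)
  bcaches <- if (keep_cache) vector("list", cfg$n_transformer_layers) else NULL
  for (l in seq_len(cfg$n_transformer_layers)) {
    bf <- block_fwd(h, p$blocks[[l]], Tn, B, nh)
    h <- bf$y
    if (keep_cache) bcaches[[l]] <- bf$cache
    m <- match(l, cfg$skip_layer_indices)
    if (!is.na(m)) zs[[m]] <- h
  }
  cc <- list()  # decoder caches
  run_cbr <- function(x, pp, stpath, H, W, nm) {
    st <- bn[[stpath[1]]][[stpath[2]]]
    r <- cbr_fwd(x, pp, st, H, W, B, training)
    bn[[stpath[1]]][[stpath[2]]] <<- r$st
    if (keep_cache) cc[[nm]] <<- r$cache
    r$y
  }
  run_dcv <- function(x, pp, H, W, nm) {
    r <- dcv_fwd(x, pp, H, W, B)
    if (keep_cache) cc[[nm]] <<- r$cache
    r$y
  }
  # bottleneck and skips
  f4 <- run_dcv(zs[[4]], p$dec$d4, g, g, "d4")                    # 2g, 8B0
  t9 <- run_dcv(zs[[3]], p$dec$b9$dc1, g, g, "b9.dc1")
  t9 <- run_cbr(t9, p$dec$b9$cv1, c("b9", "cv1"), 2 * g, 2 * g, "b9.cv1")
  m3 <- cbind(f4, t9)
  m3 <- run_cbr(m3, p$dec$m3$cv1, c("m3", "cv1"), 2 * g, 2 * g, "m3.cv1")
  m3 <- run_cbr(m3, p$dec$m3$cv2, c("m3", "cv2"), 2 * g, 2 * g, "m3.cv2")
  f3 <- run_dcv(m3, p$dec$m3$up, 2 * g, 2 * g, "m3.up")           # 4g, 4B0
  t6 <- run_dcv(zs[[2]], p$dec$b6$dc1, g, g, "b6.dc1")
  t6 <- run_cbr(t6, p$dec$b6$cv1, c("b6", "cv1"), 2 * g, 2 * g, "b6.cv1")
  t6 <- run_dcv(t6, p$dec$b6$dc2, 2 * g, 2 * g, "b6.dc2")
  t6 <- run_cbr(t6, p$dec$b6$cv2, c("b6", "cv2"), 4 * g, 4 * g, "b6.cv2")
  m2 <- cbind(f3, t6)
  m2 <- run_cbr(m2, p$dec$m2$cv1, c("m2", "cv1"), 4 * g, 4 * g, "m2.cv1")
  m2 <- run_cbr(m2, p$dec$m2$cv2, c("m2", "cv2"), 4 * g, 4 * g, "m2.cv2")
  f2 <- run_dcv(m2, p$dec$m2$up, 4 * g, 4 * g, "m2.up")           # 8g, 2B0
  t3 <- run_dcv(zs[[1]], p$dec$b3$dc1, g, g, "b3.dc1")
  t3 <- run_cbr(t3, p$dec$b3$cv1, c("b3", "cv1"), 2 * g, 2 * g, "b3.cv1")
  t3 <- run_dcv(t3, p$dec$b3$dc2, 2 * g, 2 * g, "b3.dc2")
  t3 <- run_cbr(t3, p$dec$b3$cv2, c("b3", "cv2"), 4 * g, 4 * g, "b3.cv2")
  t3 <- run_dcv(t3, p$dec$b3$dc3, 4 * g, 4 * g, "b3.dc3")
  t3 <- run_cbr(t3, p$dec$b3$cv3, c("b3", "cv3"), 8 * g, 8 * g, "b3.cv3")
  m1 <- cbind(f2, t3)
  m1 <- run_cbr(m1, p$dec$m1$cv1, c("m1", "cv1"), 8 * g, 8 * g, "m1.cv1")
  m1 <- run_cbr(m1, p$dec$m1$cv2, c("m1", "cv2"), 8 * g, 8 * g, "m1.cv2")
  f1 <- run_dcv(m1, p$dec$m1$up, 8 * g, 8 * g, "m1.up")           # S, B0
  z0 <- run_cbr(x, p$dec$z0$cv1, c("z0", "cv1"), S, S, "z0.cv1")
  z0 <- run_cbr(z0, p$dec$z0$cv2, c("z0", "cv2"), S, S, "z0.cv2")
  m0 <- cbind(f1, z0)
  m0 <- run_cbr(m0, p$dec$m0$cv1, c("m0", "cv1"), S, S, "m0.cv1")
  m0 <- run_cbr(m0, p$dec$m0$cv2, c("m0", "cv2"), S, S, "m0.cv2")
  logits <- addrow(m0 %*% p$dec$head$W, p$dec$head$b)
  cache <- NULL
  if (keep_cache)
    cache <- list(x = x, idx = idx, tok = tok, bcaches = bcaches, cc = cc,
                  m0 = m0, B = B)
  list(logits = logits, cache = cache, bn = bn)
}

# Backward pass: dlogits -> gradient tree mirroring net$params.
unetr_backward <- function(net, cache, dlogits) {
  cfg <- net$cfg; p <- net$params
  S <- cfg$image_size; P <- cfg$patch_resolution_P
  g <- S %/% P; Tn <- g * g
  nh <- cfg$n_heads; B <- cache$B; B0 <- cfg$decoder_base_channels
  cc <- cache$cc
  grads <- rapply(p, function(a) a * 0, how = "replace")

  grads$dec$head$W <- crossprod(cache$m0, dlogits)
  grads$dec$head$b <- colSums(dlogits)
  dm0 <- dlogits %*% t(p$dec$head$W)

  # assign by name so the gradient tree keeps the parameter tree's order
  put_grads <- function(ppath, gl) {
    for (nm in names(gl)) grads[[c("dec", ppath, nm)]] <<- gl[[nm]]
  }
  bwd_cbr <- function(dy, ppath, H, W) {
    pp <- p$dec
    for (nm in ppath) pp <- pp[[nm]]
    r <- cbr_bwd(dy, cc[[paste(ppath, collapse = ".")]], pp, H, W, B)
    put_grads(ppath, r$grads)
    r$dx
  }
  bwd_dcv <- function(dy, ppath, H, W) {
    pp <- p$dec
    for (nm in ppath) pp <- pp[[nm]]
    r <- dcv_bwd(dy, cc[[paste(ppath, collapse = ".")]], pp, H, W, B)
    put_grads(ppath, r$grads)
    r$dx
  }

  dm0 <- bwd_cbr(dm0, c("m0", "cv2"), S, S)
  dm0 <- bwd_cbr(dm0, c("m0", "cv1"), S, S)
  df1 <- dm0[, 1:B0, drop = FALSE]
  dz0 <- dm0[, (B0 + 1):(2 * B0), drop = FALSE]
  dz0 <- bwd_cbr(dz0, c("z0", "cv2"), S, S)
  dx_img <- bwd_cbr(dz0, c("z0", "cv1"), S, S)   # grad wrt input, unused
  dm1 <- bwd_dcv(df1, c("m1", "up"), 8 * g, 8 * g)
  dm1 <- bwd_cbr(dm1, c("m1", "cv2"), 8 * g, 8 * g)
  dm1 <- bwd_cbr(dm1, c("m1", "cv1"), 8 * g, 8 * g)
  df2 <- dm1[, 1:(2 * B0), drop = FALSE]
  dt3 <- dm1[, (2 * B0 + 1):(4 * B0), drop = FALSE]
  dt3 <- bwd_cbr(dt3, c("b3", "cv3"), 8 * g, 8 * g)
  dt3 <- bwd_dcv(dt3, c("b3", "dc3"), 4 * g, 4 * g)
  dt3 <- bwd_cbr(dt3, c("b3", "cv2"), 4 * g, 4 * g)
  dt3 <- bwd_dcv(dt3, c("b3", "dc2"), 2 * g, 2 * g)
  dt3 <- bwd_cbr(dt3, c("b3", "cv1"), 2 * g, 2 * g)
  dz1 <- bwd_dcv(dt3, c("b3", "dc1"), g, g)
  dm2 <- bwd_dcv(df2, c("m2", "up"), 4 * g, 4 * g)
  dm2 <- bwd_cbr(dm2, c("m2", "cv2"), 4 * g, 4 * g)
  dm2 <- bwd_cbr(dm2, c("m2", "cv1"), 4 * g, 4 * g)
  df3 <- dm2[, 1:(4 * B0), drop = FALSE]
  dt6 <- dm2[, (4 * B0 + 1):(8 * B0), drop = FALSE]
  dt6 <- bwd_cbr(dt6, c("b6", "cv2"), 4 * g, 4 * g)
  dt6 <- bwd_dcv(dt6, c("b6", "dc2"), 2 * g, 2 * g)
  dt6 <- bwd_cbr(dt6, c("b6", "cv1"), 2 * g, 2 * g)
  dz2 <- bwd_dcv(dt6, c("b6", "dc1"), g, g)
  dm3 <- bwd_dcv(df3, c("m3", "up"), 2 * g, 2 * g)
  dm3 <- bwd_cbr(dm3, c("m3", "cv2"), 2 * g, 2 * g)
  dm3 <- bwd_cbr(dm3, c("m3", "cv1"), 2 * g, 2 * g)
  df4 <- dm3[, 1:(8 * B0), drop = FALSE]
  dt9 <- dm3[, (8 * B0 + 1):(16 * B0), drop = FALSE]
  dt9 <- bwd_cbr(dt9, c("b9", "cv1"), 2 * g, 2 * g)
  dz3 <- bwd_dcv(dt9, c("b9", "dc1"), g, g)
  dz4 <- bwd_dcv(df4, c("d4"), g, g)

  # transformer: accumulate skip grads at the right depths
  skip_grad <- list(dz1, dz2, dz3, dz4)
  dh <- matrix(0, Tn * B, cfg$embed_dim_K)
  for (l in rev(seq_len(cfg$n_transformer_layers))) {
    m <- match(l, cfg$skip_layer_indices)
    if (!is.na(m)) dh <- dh + skip_grad[[m]]
    bb <- block_bwd(dh, cache$bcaches[[l]], p$blocks[[l]], Tn, B, nh)
    for (nm in names(bb$grads)) grads$blocks[[l]][[nm]] <- bb$grads[[nm]]
    dh <- bb$dx
  }
  grads$embed$We <- crossprod(cache$tok, dh)
  grads$embed$be <- colSums(dh)
  grads$embed$pos <- rowsum(dh, rep(seq_len(Tn), B), reorder = TRUE)
  grads
}

# sigmoid probabilities for a batch of patches (eval mode)
unetr_predict_batch <- function(net, x, B) {
  out <- unetr_forward(net, x, B, training = FALSE, keep_cache = FALSE)
  1 / (1 + exp(-out$logits))
}

#' Save or load a network checkpoint
#'
#' The checkpoint stores weights, batch-norm running statistics, and the
#' configuration (also embedded as a YAML string for inspection outside R).
#'
#' @param net a `unetr_net`.
#' @param path checkpoint file path (`.rds`).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored `unetr_net`.
#' @export
save_checkpoint <- function(net, path) {
  stopifnot(inherits(net, "unetr_net"))
  saveRDS(list(params = net$params, bn = net$bn,
               config = unclass(net$cfg),
               config_yaml = yaml::as.yaml(unclass(net$cfg))), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  stop_if_not(file.exists(path), "checkpoint not found: %s", path)
  ck <- readRDS(path)
  cfg <- do.call(unetr_config, ck$config)
  structure(list(cfg = cfg, params = ck$params, bn = ck$bn),
            class = "unetr_net")
}
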