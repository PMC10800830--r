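# Training loop, cross-validation folds, checkpointing.

#' Training configuration
#'
#' @param epochs complete passes over the training data (default 25).
#' @param batch_size patches per optimization step (default 8).
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param loss a [loss_params()].
#' @param seed RNG seed (weight init and batch shuffling).
#' @param n_folds folds for whole-image cross-validation (default 3).
#' @return A validated `train_config` list.
#' @export
train_config <- function(epochs = 25, batch_size = 8, learning_rate = 1e-4,
                         loss = loss_params(), seed = 1, n_folds = 3) {
  stop_if_not(is_count(epochs), "epochs must be a positive integer")
  stop_if_not(is_count(batch_size), "batch_size must be a positive integer")
  stop_if_not(is_scalar(learning_rate) && learning_rate > 0,
              "learning_rate must be positive")
  stop_if_not(inherits(loss, "loss_params"), "loss must be loss_params()")
  stop_if_not(is_count(n_folds), "n_folds must be a positive integer")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, loss = loss,
                 seed = as.integer(seed), n_folds = as.integer(n_folds)),
            class = "train_config")
}

#' Split sample ids into cross-validation folds
#'
#' Partitions at the whole-image level (no patch of a test image is ever
#' seen in training); fold sizes differ by at most one.
#'
#' @param sample_ids character vector of image identifiers.
#' @param n_folds number of folds.
#' @param seed RNG seed; identical seeds give identical folds.
#' @return list of `n_folds` elements, each `list(train = ids, test = ids)`.
#' @export
make_folds <- function(sample_ids, n_folds = 3, seed = 1) {
  stop_if_not(n_folds <= length(sample_ids),
              "need at least one sample per fold (%d ids, %d folds)",
              length(sample_ids), n_folds)
  perm <- with_seed(seed, sample(sample_ids))
  assignment <- rep_len(seq_len(n_folds), length(perm))
  lapply(seq_len(n_folds), function(k)
    list(train = perm[assignment != k], test = perm[assignment == k]))
}

# Stack a list of patch_pairs into network input (x) and target (y).
stack_batch <- function(pairs) {
  S <- dim(pairs[[1]]$patch)[1]
  x <- do.call(rbind, lapply(pairs, function(p) {
    m <- p$patch
    dim(m) <- c(S * S, 3)
    m
  }))
  y <- do.call(c, lapply(pairs, function(p) as.numeric(p$mask)))
  list(x = x, y = y, B = length(pairs), S = S)
}

#' Train a UNETR on patch pairs
#'
#' Runs exactly `cfg$epochs` passes over the data with Adam and the Focal
#' Tversky loss on sigmoid outputs, optionally re-augmenting every epoch
#' on the fly. Records the mean batch loss per epoch.
#'
#' @param patches list of [patch_pair()] objects (all the same size, which
#'   must equal `net_cfg$image_size`).
#' @param cfg a [train_config()].
#' @param net_cfg a [unetr_config()] describing the network to build, or
#'   `NULL` when `net` is supplied.
#' @param net optionally, an existing `unetr_net` to continue training.
#' @param augment_cfg optional [augment_config()]; when given, every epoch
#'   sees a freshly augmented copy of the training patches.
#' @param verbose print per-epoch mean loss.
#' @return `list(net, loss_history)` with `loss_history` of length
#'   `cfg$epochs`.
#' @export
train_model <- function(patches, cfg = train_config(), net_cfg = NULL,
                        net = NULL, augment_cfg = NULL, verbose = FALSE) {
  stop_if_not(length(patches) >= 1, "empty training set")
  stopifnot(inherits(cfg, "train_config"))
  if (is.null(net)) {
    stopifnot(inherits(net_cfg, "unetr_config"))
    net <- build_unetr(net_cfg, seed = cfg$seed)
  }
  S <- net$cfg$image_size
  for (p in patches)
    stop_if_not(dim(p$patch)[1] == S,
                "patch size %d does not match network image_size %d",
                dim(p$patch)[1], S)
  theta <- unlist(net$params)
  skeleton <- net$params
  opt <- adam_init(length(theta))
  history <- numeric(cfg$epochs)
  with_seed(cfg$seed + 1L, {
    for (ep in seq_len(cfg$epochs)) {
      data <- if (is.null(augment_cfg)) patches else
        lapply(patches, augment_pair, cfg = augment_cfg)
      ord <- sample(length(data))
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      losses <- numeric(length(batches))
      for (i in seq_along(batches)) {
        ba <- stack_batch(data[batches[[i]]])
        fw <- unetr_forward(net, ba$x, ba$B, training = TRUE)
        net$bn <- fw$bn
        probs <- 1 / (1 + exp(-fw$logits))
        L <- focal_tversky_loss(ba$y, probs, cfg$loss)
        if (!is.finite(L))
          stop("non-finite loss at epoch ", ep, ", batch ", i,
               "; aborting training", call. = FALSE)
        losses[i] <- L
        dprob <- focal_tversky_grad(ba$y, probs, cfg$loss)
        dlogits <- matrix(dprob * as.numeric(probs) * (1 - as.numeric(probs)),
                          ncol = 1)
        grads <- unetr_backward(net, fw$cache, dlogits)
        gvec <- unlist(grads)
        st <- adam_step(theta, gvec, opt, cfg$learning_rate)
        theta <- st$theta; opt <- st$state
        net$params <- utils::relist(theta, skeleton)
      }
      history[ep] <- mean(losses)
      if (verbose)
        message(sprintf("epoch %d/%d  mean loss %.4f", ep, cfg$epochs,
                        history[ep]))
    }
  })
  list(net = net, loss_history = history)
}
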