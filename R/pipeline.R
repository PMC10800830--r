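# End-to-end pipeline: generate -> prep -> train -> predict -> postprocess
# -> evaluate, with per-stage error reporting and a JSON run manifest.

#' Pipeline configuration
#'
#' Bundles the per-stage configurations plus paths and the global seed.
#' All randomness (data generation, weight init, shuffling) derives from
#' `seed`, so a rerun with an unchanged config reproduces its outputs.
#'
#' @param out_dir output directory.
#' @param seed global RNG seed.
#' @param n_train_images,n_test_images synthetic images generated for
#'   training and held-out evaluation.
#' @param synth a [synth_config()] (its `seed` field is re-derived per
#'   image from the global seed).
#' @param net a [unetr_config()].
#' @param train a [train_config()].
#' @param infer an [inference_config()].
#' @param prune a [prune_config()].
#' @param augment optional [augment_config()] for on-the-fly training
#'   augmentation (`NULL` disables).
#' @param patch_stride stride for training-patch cropping.
#' @param min_path_len_px minimum extracted boundary-path length.
#' @param skip_train reuse `out_dir/checkpoint.rds` instead of training.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 7, n_train_images = 7,
                            n_test_images = 3, synth = synth_config(),
                            net = unetr_config(), train = train_config(),
                            infer = inference_config(),
                            prune = prune_config(), augment = NULL,
                            patch_stride = 256, min_path_len_px = 50,
                            skip_train = FALSE) {
  stopifnot(inherits(synth, "synth_config"), inherits(net, "unetr_config"),
            inherits(train, "train_config"),
            inherits(infer, "inference_config"),
            inherits(prune, "prune_config"))
  if (!is.null(augment)) stopifnot(inherits(augment, "augment_config"))
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_train_images = as.integer(n_train_images),
                 n_test_images = as.integer(n_test_images),
                 synth = synth, net = net, train = train, infer = infer,
                 prune = prune, augment = augment,
                 patch_stride = as.integer(patch_stride),
                 min_path_len_px = min_path_len_px,
                 skip_train = isTRUE(skip_train)),
            class = "pipeline_config")
}

#' Desk-scale demonstration configuration
#'
#' A scaled-down instantiation that trains a tiny network (K = 32, 4
#' transformer layers, decoder base 4) on ~200 patches from 7 synthetic
#' images and evaluates on 3 held-out images, in minutes on one CPU. Ring
#' geometry is shrunk accordingly (1280 x 512 px canvases, ~400 px rings)
#' while keeping the vessel density of the emulated material (120 vessels
#' per ring).
#'
#' @param out_dir output directory.
#' @param seed global RNG seed.
#' @return A [pipeline_config()].
#' @export
demo_pipeline_config <- function(out_dir, seed = 7) {
  pipeline_config(
    out_dir = out_dir, seed = seed,
    n_train_images = 7, n_test_images = 3,
    synth = synth_config(height_px = 1280, width_px = 512, n_boundaries = 2,
                         mean_ring_width_px = 400, ring_width_cv = 0.15,
                         boundary_waviness_px = 5,
                         fiber_band_halfwidth_px = 4,
                         vessels_per_ring_mean = 120,
                         vessel_radius_range_px = c(4, 10), noise_sd = 6),
    net = unetr_config(image_size = 256, embed_dim_K = 32,
                       n_transformer_layers = 4, n_heads = 4,
                       mlp_hidden_dim = 64, decoder_base_channels = 4),
    train = train_config(epochs = 6, batch_size = 8, learning_rate = 1e-3,
                         seed = seed + 101L),
    infer = inference_config(overlap_fraction = 0.5, tta_enabled = FALSE,
                             threshold = 0.2),
    patch_stride = 128)
}

# small polynomial content hash for the manifest (no external digest
# dependency; stays within exact double/integer arithmetic)
fnv1a <- function(txt) {
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full segmentation pipeline
#'
#' Generates annotated synthetic microsections, crops training patches,
#' trains the network, segments the held-out images, post-processes the
#' masks into boundary paths, and evaluates them against the ground truth.
#' All artifacts (images, checkpoints, probability maps, masks, boundary
#' CSVs, evaluation CSVs, and a JSON manifest) are written under
#' `cfg$out_dir`. A failure in any stage is reported as an error naming
#' that stage.
#'
#' @param cfg a [pipeline_config()].
#' @param verbose print stage progress.
#' @return Invisibly, a list with the trained net, per-image evaluations,
#'   and the overall summary data frame.
#' @export
run_pipeline <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  t_all <- proc.time()[3]
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    r <- tryCatch(force(expr), error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
    if (verbose)
      message(sprintf("[%s] done in %.1f s", name, proc.time()[3] - t0))
    r
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  samples <- stage("generate", {
    n <- cfg$n_train_images + cfg$n_test_images
    lapply(seq_len(n), function(i) {
      sc <- cfg$synth
      sc$seed <- cfg$seed * 1000L + i
      role <- if (i <= cfg$n_train_images) "train" else "test"
      s <- generate_sample(sc, sample_id = sprintf("%s_%02d", role, i))
      write_sample(s, file.path(cfg$out_dir, "data"), config = sc)
      s
    })
  })
  train_samples <- samples[seq_len(cfg$n_train_images)]
  test_samples <- samples[cfg$n_train_images + seq_len(cfg$n_test_images)]

  patches <- stage("prep", {
    ps <- cfg$net$image_size
    unlist(lapply(train_samples, function(s)
      crop_training_patches(s$image, s$mask, patch_size = ps,
                            stride = cfg$patch_stride)),
      recursive = FALSE)
  })

  ckpt <- file.path(cfg$out_dir, "checkpoint.rds")
  fit <- stage("train", {
    if (cfg$skip_train) {
      if (!file.exists(ckpt))
        stop("checkpoint missing for predict-only mode: ", ckpt)
      list(net = load_checkpoint(ckpt), loss_history = numeric(0))
    } else {
      r <- train_model(patches, cfg$train, cfg$net,
                       augment_cfg = cfg$augment, verbose = verbose)
      save_checkpoint(r$net, ckpt)
      write.csv(data.frame(epoch = seq_along(r$loss_history),
                           mean_loss = r$loss_history),
                file.path(cfg$out_dir, "training_log.csv"),
                row.names = FALSE)
      r
    }
  })

  preds <- stage("predict", {
    lapply(test_samples, function(s) {
      p <- predict_image(fit$net, s$image, cfg$infer)
      id <- s$image$sample_id
      tiff::writeTIFF(unclass(p$prob),
                      file.path(cfg$out_dir, paste0(id, "_prob.tif")),
                      bits.per.sample = 32L)
      png::writePNG(unclass(p$mask) * 1.0,
                    file.path(cfg$out_dir, paste0(id, "_mask.png")))
      p
    })
  })

  pred_paths <- stage("postprocess", {
    lapply(seq_along(preds), function(i) {
      g <- skeletonize_mask(preds[[i]]$mask)
      g <- dse_prune(g, cfg$prune)
      paths <- extract_boundary_paths(g, cfg$min_path_len_px)
      id <- test_samples[[i]]$image$sample_id
      write_boundaries(paths,
                       file.path(cfg$out_dir, paste0(id, "_boundaries.csv")))
      paths
    })
  })

  evals <- stage("evaluate", {
    lapply(seq_along(test_samples), function(i) {
      s <- test_samples[[i]]
      ev <- evaluate_segmentation(s$boundaries, pred_paths[[i]], s$vessels,
                                  s$image$resolution_um_per_px)
      ev$sample_id <- s$image$sample_id
      ev$n_true <- length(s$boundaries)
      ev
    })
  })

  per_ring <- do.call(rbind, lapply(evals, function(e) {
    if (nrow(e$per_ring) == 0) return(NULL)
    cbind(sample_id = e$sample_id, e$per_ring)
  }))
  summary_df <- data.frame(
    n_true_boundaries = sum(vapply(evals, `[[`, numeric(1), "n_true")),
    n_matched = sum(vapply(evals, `[[`, numeric(1), "n_matched")),
    n_manual_only = sum(vapply(evals, `[[`, numeric(1), "n_manual_only")),
    n_predicted_only = sum(vapply(evals, `[[`, numeric(1),
                                  "n_predicted_only")),
    mean_center_distance_px = if (is.null(per_ring)) NA_real_
      else mean(per_ring$center_distance_px),
    mean_center_distance_um = if (is.null(per_ring)) NA_real_
      else mean(per_ring$center_distance_um),
    mean_vessel_mismatch = if (is.null(per_ring)) NA_real_
      else mean(per_ring$vessel_mismatch, na.rm = TRUE))
  if (!is.null(per_ring))
    write.csv(per_ring, file.path(cfg$out_dir, "evaluation_per_ring.csv"),
              row.names = FALSE)
  write.csv(summary_df, file.path(cfg$out_dir, "evaluation_summary.csv"),
            row.names = FALSE)

  cfg_yaml <- yaml::as.yaml(rapply(unclass(cfg), unclass, how = "replace"))
  manifest <- list(
    config_hash = fnv1a(cfg_yaml),
    seed = cfg$seed,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("ringseg")),
    elapsed_s = round(proc.time()[3] - t_all, 1),
    final_train_loss = if (length(fit$loss_history))
      fit$loss_history[length(fit$loss_history)] else NA,
    summary = as.list(summary_df))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(net = fit$net, loss_history = fit$loss_history,
                 evals = evals, per_ring = per_ring, summary = summary_df))
}
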