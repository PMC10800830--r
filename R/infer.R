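# Whole-image inference: overlap-tile splitting, dihedral test-time
# augmentation, max aggregation, min-max normalization, thresholding.

#' Inference configuration
#'
#' @param patch_size square tile side fed to the network (256).
#' @param overlap_fraction fractional overlap between adjacent tiles in
#'   `[0, 1)`; 0.9 gives the stride `round(256 * 0.1) = 26` px.
#' @param tta_enabled apply the 8-fold dihedral test-time augmentation.
#' @param threshold probability threshold deciding boundary membership
#'   after normalization (default 0.2).
#' @param aggregate how overlapping tiles are combined per pixel:
#'   `"max"` (mirroring the TTA max rule) or `"mean"`.
#' @return A validated `inference_config` list.
#' @export
inference_config <- function(patch_size = 256, overlap_fraction = 0.9,
                             tta_enabled = TRUE, threshold = 0.2,
                             aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  stop_if_not(is_count(patch_size), "patch_size must be a positive integer")
  stop_if_not(is_scalar(overlap_fraction) && overlap_fraction >= 0 &&
                overlap_fraction < 1, "overlap_fraction must lie in [0, 1)")
  stop_if_not(is_scalar(threshold) && threshold > 0 && threshold < 1,
              "threshold must lie in (0, 1)")
  structure(list(patch_size = as.integer(patch_size),
                 overlap_fraction = overlap_fraction,
                 tta_enabled = isTRUE(tta_enabled), threshold = threshold,
                 aggregate = aggregate),
            class = "inference_config")
}

#' Plan overlap-tile origins for a large image
#'
#' Origins advance by `stride = max(1, round(patch_size * (1 -
#' overlap_fraction)))` in both axes; the final origin per axis is clamped
#' to `dim - patch_size` so tiles never exceed bounds and every pixel is
#' covered by at least one tile.
#'
#' @param height,width image size in pixels (both `>= patch_size`).
#' @param patch_size square tile side.
#' @param overlap_fraction fractional overlap in `[0, 1)`.
#' @return integer matrix with columns `row`, `col`: unique 0-based tile
#'   origins, row-major.
#' @export
tile_plan <- function(height, width, patch_size = 256,
                      overlap_fraction = 0.9) {
  stop_if_not(height >= patch_size && width >= patch_size,
              "image (%d x %d) smaller than patch_size %d",
              height, width, patch_size)
  stride <- max(1L, as.integer(round(patch_size * (1 - overlap_fraction))))
  axis <- function(n) {
    o <- seq(0L, n - patch_size, by = stride)
    if (o[length(o)] != n - patch_size) o <- c(o, n - patch_size)
    as.integer(o)
  }
  or <- axis(height); oc <- axis(width)
  cbind(row = rep(or, each = length(oc)), col = rep(oc, times = length(or)))
}

# Dihedral group D4: transform id k in 0..7 decomposes as k = r + 4*f with
# r counterclockwise quarter-turns and f horizontal (left-right) flip,
# applied flip-first: op_k(x) = rot90^r(hflip^f(x)).

rot90_ccw <- function(m) t(m)[ncol(m):1, , drop = FALSE]
rot90_cw <- function(m) t(m[nrow(m):1, , drop = FALSE])
hflip <- function(m) m[, ncol(m):1, drop = FALSE]

apply_plane <- function(m, k) {
  r <- k %% 4L; f <- k %/% 4L
  if (f == 1) m <- hflip(m)
  for (i in seq_len(r)) m <- rot90_ccw(m)
  m
}

invert_plane <- function(m, k) {
  r <- k %% 4L; f <- k %/% 4L
  for (i in seq_len(r)) m <- rot90_cw(m)
  if (f == 1) m <- hflip(m)
  m
}

apply_dihedral <- function(x, k) {
  if (length(dim(x)) == 3) {
    out <- array(0, dim = dim(x))
    for (ch in seq_len(dim(x)[3])) out[, , ch] <- apply_plane(x[, , ch], k)
    out
  } else apply_plane(x, k)
}

#' Dihedral orbit of a square patch
#'
#' Returns the eight images of `patch` under the dihedral group of order 4
#' (four rotations, with and without horizontal flip). Element `k + 1` of
#' the result is the transform with id `k` in `0..7`;
#' [inverse_dihedral()] undoes each transform exactly.
#'
#' @param patch square matrix or `S x S x C` array.
#' @return list of 8 transformed patches.
#' @export
dihedral_orbit <- function(patch) {
  d <- dim(patch)
  stop_if_not(d[1] == d[2], "dihedral transforms need a square patch")
  lapply(0:7, function(k) apply_dihedral(patch, k))
}

#' @rdname dihedral_orbit
#' @param map square matrix or array previously transformed with id
#'   `transform_id`.
#' @param transform_id dihedral transform id in `0..7`.
#' @export
inverse_dihedral <- function(map, transform_id) {
  d <- dim(map)
  stop_if_not(d[1] == d[2], "dihedral transforms need a square patch")
  stop_if_not(transform_id %in% 0:7, "transform_id must be in 0..7")
  if (length(d) == 3) {
    out <- array(0, dim = d)
    for (ch in seq_len(d[3])) out[, , ch] <- invert_plane(map[, , ch],
                                                          transform_id)
    out
  } else invert_plane(map, transform_id)
}

# forward one or more square patches (list of S x S x 3 arrays in [0,1])
predict_patches <- function(net, patch_list) {
  S <- net$cfg$image_size
  x <- do.call(rbind, lapply(patch_list, function(p) {
    dim(p) <- c(S * S, 3)
    p
  }))
  pr <- unetr_predict_batch(net, x, length(patch_list))
  lapply(seq_along(patch_list), function(b)
    matrix(pr[((b - 1) * S * S + 1):(b * S * S)], S, S))
}

#' Predict one tile with dihedral test-time augmentation
#'
#' Runs the network on the eight dihedral versions of the patch, maps each
#' output back through the inverse transform, and takes the per-pixel
#' maximum of the aligned probability maps.
#'
#' @param net a trained `unetr_net`.
#' @param patch `S x S x 3` array in `[0, 1]`, `S = net$cfg$image_size`.
#' @param tta if `FALSE`, a plain single forward pass.
#' @return `S x S` probability matrix.
#' @export
tta_predict <- function(net, patch, tta = TRUE) {
  if (!tta) return(predict_patches(net, list(patch))[[1]])
  orbit <- dihedral_orbit(patch)
  outs <- predict_patches(net, orbit)
  aligned <- lapply(0:7, function(k) invert_plane(outs[[k + 1]], k))
  Reduce(pmax, aligned)
}

# reflection-pad an H x W x 3 array to at least (ph x pw)
reflect_pad_image <- function(px, ph, pw) {
  H <- dim(px)[1]; W <- dim(px)[2]
  ri <- reflect_index(seq_len(max(H, ph)), H)
  ci <- reflect_index(seq_len(max(W, pw)), W)
  px[ri, ci, , drop = FALSE]
}

#' Segment a whole microsection image
#'
#' Tiles the image per [tile_plan()], predicts each tile (with optional
#' dihedral TTA), aggregates overlapping tiles per pixel (max by default),
#' min-max normalizes the aggregated map to `[0, 1]` (an all-constant map
#' becomes 0), and thresholds it into a binary boundary mask. Images
#' smaller than the patch are reflection-padded and cropped back.
#'
#' @param net a trained `unetr_net`.
#' @param image a [microsection_image()] (or `H x W x 3` array, 0--255).
#' @param cfg an [inference_config()].
#' @return `list(prob, mask)`: a [probability_map()] and a [binary_mask()].
#' @export
predict_image <- function(net, image, cfg = inference_config()) {
  px <- if (inherits(image, "microsection_image")) image$pixels else image
  H0 <- dim(px)[1]; W0 <- dim(px)[2]
  ps <- cfg$patch_size
  stop_if_not(ps == net$cfg$image_size,
              "patch_size %d does not match the network's image_size %d",
              ps, net$cfg$image_size)
  if (H0 < ps || W0 < ps) px <- reflect_pad_image(px, ps, ps)
  H <- dim(px)[1]; W <- dim(px)[2]
  xnorm <- normalize_patch(px)
  plan <- tile_plan(H, W, ps, cfg$overlap_fraction)
  agg <- matrix(if (cfg$aggregate == "max") -Inf else 0, H, W)
  cnt <- if (cfg$aggregate == "mean") matrix(0L, H, W) else NULL
  # batch plain tiles through the network in groups; TTA goes tile by tile
  group <- if (cfg$tta_enabled) 1L else 8L
  i <- 1L
  while (i <= nrow(plan)) {
    js <- i:min(i + group - 1L, nrow(plan))
    tiles <- lapply(js, function(j) {
      r <- plan[j, 1]; c <- plan[j, 2]
      xnorm[(r + 1):(r + ps), (c + 1):(c + ps), , drop = FALSE]
    })
    preds <- if (cfg$tta_enabled)
      list(tta_predict(net, tiles[[1]], tta = TRUE))
    else predict_patches(net, tiles)
    for (q in seq_along(js)) {
      r <- plan[js[q], 1]; c <- plan[js[q], 2]
      rows <- (r + 1):(r + ps); cols <- (c + 1):(c + ps)
      if (cfg$aggregate == "max") {
        agg[rows, cols] <- pmax(agg[rows, cols], preds[[q]])
      } else {
        agg[rows, cols] <- agg[rows, cols] + preds[[q]]
        cnt[rows, cols] <- cnt[rows, cols] + 1L
      }
    }
    i <- i + length(js)
  }
  if (cfg$aggregate == "mean") agg <- agg / pmax(cnt, 1L)
  agg <- agg[seq_len(H0), seq_len(W0), drop = FALSE]  # undo padding
  rng <- range(agg)
  prob <- if (rng[2] > rng[1]) (agg - rng[1]) / (rng[2] - rng[1])
          else matrix(0, H0, W0)
  list(prob = probability_map(prob),
       mask = binary_mask((prob > cfg$threshold) * 1L))
}
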