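# Training-patch construction: cropping, augmentation, normalization.

#' A training patch with its paired mask
#'
#' @param patch square `S x S x 3` array of reals in `[0, 1]`.
#' @param mask `S x S` 0/1 matrix, cropped with the identical origin.
#' @param origin 0-based `(row, col)` of the patch in its source image.
#' @param sample_id identifier of the source image.
#' @return An object of class `patch_pair`.
#' @export
patch_pair <- function(patch, mask, origin = c(0, 0), sample_id = "sample") {
  d <- dim(patch)
  stop_if_not(length(d) == 3 && d[1] == d[2] && d[3] == 3,
              "patch must be a square S x S x 3 array")
  stop_if_not(all(patch >= 0 & patch <= 1), "patch values must lie in [0, 1]")
  stop_if_not(all(dim(mask) == d[1:2]), "mask shape must match the patch")
  stop_if_not(all(mask %in% c(0, 1)), "mask must be binary")
  structure(list(patch = patch, mask = binary_mask(mask),
                 origin = as.integer(origin),
                 sample_id = as.character(sample_id)),
            class = "patch_pair")
}

#' Normalize an 8-bit patch to the unit interval
#'
#' @param patch array/matrix of 8-bit intensities (0--255).
#' @return The same shape with each value divided by 255.
#' @export
normalize_patch <- function(patch) {
  stop_if_not(all(patch >= 0 & patch <= 255),
              "normalize_patch expects 8-bit input in [0, 255]")
  patch / 255
}

#' Crop an image and its mask into training patches
#'
#' Patches tile the image on a regular grid with the given stride; the last
#' row/col origin is clamped so patches never exceed the image, and every
#' pixel is covered by at least one patch. Patch intensities are normalized
#' to `[0, 1]`; masks are cropped with identical origins.
#'
#' @param image a [microsection_image()] (or `H x W x 3` array in 0--255).
#' @param mask a [binary_mask()] of the same height/width.
#' @param patch_size square patch side (default 256).
#' @param stride grid stride in pixels (default `patch_size`).
#' @return list of [patch_pair()] objects, row-major over the grid.
#' @export
crop_training_patches <- function(image, mask, patch_size = 256,
                                  stride = patch_size) {
  px <- if (inherits(image, "microsection_image")) image$pixels else image
  sid <- if (inherits(image, "microsection_image")) image$sample_id else "sample"
  H <- dim(px)[1]; W <- dim(px)[2]
  stop_if_not(all(dim(mask) == c(H, W)), "image and mask shapes differ")
  stop_if_not(H >= patch_size && W >= patch_size,
              "image (%d x %d) smaller than patch_size %d", H, W, patch_size)
  stop_if_not(is_count(stride), "stride must be a positive integer")
  origins_1d <- function(n) {
    o <- seq(0L, n - patch_size, by = stride)
    if (o[length(o)] != n - patch_size) o <- c(o, n - patch_size)
    o
  }
  out <- list()
  for (r in origins_1d(H)) for (c in origins_1d(W)) {
    rows <- (r + 1):(r + patch_size); cols <- (c + 1):(c + patch_size)
    out[[length(out) + 1]] <- patch_pair(
      normalize_patch(px[rows, cols, , drop = FALSE]),
      mask[rows, cols], origin = c(r, c), sample_id = sid)
  }
  out
}

#' Augmentation configuration
#'
#' Each augmentation is applied independently with its own probability:
#' horizontal (left-to-right) flip, rotation by an angle drawn uniformly in
#' `rotate_degrees`, and Gaussian blur with kernel side drawn from the odd
#' integers within `blur_kernel_range` (sigma derived from the kernel side
#' by the usual `0.3 * ((k - 1) / 2 - 1) + 0.8` convention). Geometric
#' transforms apply to patch and mask alike; blur applies to the patch only.
#'
#' @param p_hflip,p_rotate,p_blur application probabilities in `[0, 1]`.
#' @param rotate_degrees `(min, max)` rotation angle range in degrees.
#' @param blur_kernel_range `(min, max)` Gaussian kernel sides.
#' @param seed RNG seed used by [augment_patches()].
#' @return A validated `augment_config` list.
#' @export
augment_config <- function(p_hflip = 0.5, p_rotate = 0.5,
                           rotate_degrees = c(-20, 20), p_blur = 0.5,
                           blur_kernel_range = c(3, 10), seed = 1) {
  for (p in c(p_hflip, p_rotate, p_blur))
    stop_if_not(is_scalar(p) && p >= 0 && p <= 1,
                "probabilities must lie in [0, 1]")
  stop_if_not(length(rotate_degrees) == 2 &&
                rotate_degrees[1] <= rotate_degrees[2],
              "rotate_degrees must be (min, max)")
  stop_if_not(length(blur_kernel_range) == 2 &&
                blur_kernel_range[1] <= blur_kernel_range[2] &&
                blur_kernel_range[1] >= 3,
              "blur_kernel_range must be (min, max) with min >= 3")
  structure(list(p_hflip = p_hflip, p_rotate = p_rotate,
                 rotate_degrees = as.numeric(rotate_degrees),
                 p_blur = p_blur,
                 blur_kernel_range = as.numeric(blur_kernel_range),
                 seed = as.integer(seed)),
            class = "augment_config")
}

# Reflect a (possibly fractional) 1-based index into [1, n].
reflect_index <- function(i, n) {
  if (n == 1) return(rep(1, length(i)))
  i2 <- abs(i - 1) %% (2 * (n - 1))
  ifelse(i2 > n - 1, 2 * (n - 1) - i2, i2) + 1
}

# Rotate a matrix by `deg` degrees about its center. interp = "bilinear"
# (reflection-padded) or "nearest".
rotate_plane <- function(m, deg, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  n <- nrow(m); stopifnot(ncol(m) == n)
  th <- deg * pi / 180
  ctr <- (n + 1) / 2
  r <- matrix(seq_len(n), n, n) - ctr
  c <- matrix(seq_len(n), n, n, byrow = TRUE) - ctr
  sr <- ctr + cos(th) * r - sin(th) * c
  sc <- ctr + sin(th) * r + cos(th) * c
  if (interp == "nearest") {
    ri <- reflect_index(round(sr), n); ci <- reflect_index(round(sc), n)
    out <- matrix(m[cbind(as.vector(ri), as.vector(ci))], n, n)
  } else {
    r0 <- floor(sr); c0 <- floor(sc)
    fr <- sr - r0; fc <- sc - c0
    g <- function(ri, ci)
      matrix(m[cbind(as.vector(reflect_index(ri, n)),
                     as.vector(reflect_index(ci, n)))], n, n)
    out <- g(r0, c0) * (1 - fr) * (1 - fc) + g(r0 + 1, c0) * fr * (1 - fc) +
      g(r0, c0 + 1) * (1 - fr) * fc + g(r0 + 1, c0 + 1) * fr * fc
  }
  out
}

# Separable Gaussian blur with reflection padding; k = odd kernel side.
gaussian_blur_plane <- function(m, k) {
  sigma <- 0.3 * ((k - 1) / 2 - 1) + 0.8
  h <- (k - 1) %/% 2
  ker <- dnorm(-h:h, sd = sigma); ker <- ker / sum(ker)
  n1 <- nrow(m); n2 <- ncol(m)
  ridx <- reflect_index(seq(1 - h, n1 + h), n1)
  cidx <- reflect_index(seq(1 - h, n2 + h), n2)
  mp <- m[ridx, , drop = FALSE]
  m1 <- vapply(seq_len(n1), function(i)
    as.numeric(ker %*% mp[i:(i + 2 * h), , drop = FALSE]), numeric(n2))
  m1 <- t(m1)
  mp <- m1[, cidx, drop = FALSE]
  m2 <- vapply(seq_len(n2), function(j)
    as.numeric(mp[, j:(j + 2 * h), drop = FALSE] %*% ker), numeric(n1))
  m2
}

#' Randomly augment one patch pair
#'
#' Draws from the current RNG stream; wrap in `set.seed()` (or use
#' [augment_patches()]) for reproducibility. Geometric transforms (flip,
#' rotation) are applied identically to patch and mask; the mask is rotated
#' with nearest-neighbour resampling and re-thresholded at 0.5 so it stays
#' binary; blur touches the patch only. Degenerate draws are the identity.
#'
#' @param pair a [patch_pair()].
#' @param cfg an [augment_config()].
#' @return The augmented [patch_pair()].
#' @export
augment_pair <- function(pair, cfg = augment_config()) {
  stopifnot(inherits(pair, "patch_pair"), inherits(cfg, "augment_config"))
  patch <- pair$patch; mask <- unclass(pair$mask)
  if (runif(1) < cfg$p_hflip) {
    W <- dim(patch)[2]
    patch <- patch[, W:1, , drop = FALSE]
    mask <- mask[, W:1, drop = FALSE]
  }
  if (runif(1) < cfg$p_rotate) {
    deg <- runif(1, cfg$rotate_degrees[1], cfg$rotate_degrees[2])
    for (ch in 1:3) patch[, , ch] <- rotate_plane(patch[, , ch], deg)
    mask <- (rotate_plane(mask, deg, "nearest") >= 0.5) * 1L
    patch <- clamp(patch, 0, 1)
  }
  if (runif(1) < cfg$p_blur) {
    ks <- cfg$blur_kernel_range
    odd <- seq(ceiling(ks[1] / 2) * 2 - 1, ks[2], by = 2)
    odd <- odd[odd >= 3]
    k <- odd[sample.int(length(odd), 1)]
    for (ch in 1:3) patch[, , ch] <- gaussian_blur_plane(patch[, , ch], k)
    patch <- clamp(patch, 0, 1)
  }
  patch_pair(patch, mask, pair$origin, pair$sample_id)
}

#' Augment a list of patch pairs reproducibly
#'
#' @param pairs list of [patch_pair()] objects.
#' @param cfg an [augment_config()]; its `seed` fixes the draws.
#' @return list of augmented pairs, same length and order.
#' @export
augment_patches <- function(pairs, cfg = augment_config()) {
  with_seed(cfg$seed, lapply(pairs, augment_pair, cfg = cfg))
}
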